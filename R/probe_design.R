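#' Tile candidate probes across one target region
#'
#' Candidate starts run from `target$start - flank_allowance`, stepped by
#' `tile_step`, up to the last start whose probe end stays within
#' `target$end + flank_allowance`; one candidate is emitted per allowed
#' length (`seq(probe_len_min, probe_len_max, probe_len_step)`). Candidates
#' containing N, or falling outside the chromosome, are dropped.
#'
#' @param target one-row `region_set` (or list with `chrom`, `start`, `end`).
#' @param genome a [Biostrings::DNAStringSet].
#' @param params a [design_params()] object.
#' @return data.frame of candidates: `chrom`, `start`, `length`, `sequence`.
#' @export
tile_candidates <- function(target, genome, params = design_params()) {
    chrom <- as.character(target$chrom[1])
    clen <- Biostrings::width(genome)[match(chrom, names(genome))]
    if (is.na(clen)) stop("target chromosome '", chrom, "' not in genome")
    span_start <- max(0L, target$start[1] - params$flank_allowance)
    span_end <- min(clen, target$end[1] + params$flank_allowance)
    lens <- seq(params$probe_len_min, params$probe_len_max,
                by = params$probe_len_step)
    if (span_end - span_start < params$probe_len_min) {
        warning("target ", chrom, ":", target$start[1], "-", target$end[1],
                " plus flanks shorter than minimum probe length; no candidates")
        return(data.frame(chrom = character(), start = integer(),
                          length = integer(), sequence = character(),
                          stringsAsFactors = FALSE))
    }
    out <- list()
    text <- as.character(genome[[chrom]])
    for (L in lens) {
        if (span_end - L < span_start) next
        starts <- seq.int(span_start, span_end - L, by = params$tile_step)
        seqs <- substring(text, starts + 1L, starts + L)
        out[[length(out) + 1L]] <-
            data.frame(chrom = chrom, start = starts, length = L,
                       sequence = seqs, stringsAsFactors = FALSE)
    }
    cands <- do.call(rbind, out)
    cands <- cands[!grepl("[^ACGT]", cands$sequence), , drop = FALSE]
    cands <- cands[order(cands$start, cands$length), , drop = FALSE]
    rownames(cands) <- NULL
    cands
}

#' Combined probe score (lower is better)
#'
#' `w_rep * log10(1 + repetitiveness) + w_uni * max(0, close_matches - 1) +
#'  w_tm * |tm - tm_target| + w_comp * composition_penalty`.
#' Eligibility (repetitive / non-unique flags) is handled separately: a
#' flagged probe is ineligible regardless of its score.
#'
#' @param repetitiveness mean k-mer count.
#' @param close_matches genome-wide close-match locus count.
#' @param tm melting temperature, degrees C.
#' @param comp composition penalty.
#' @param params a [design_params()] object.
#' @return Numeric score vector.
#' @export
probe_score <- function(repetitiveness, close_matches, tm, comp,
                        params = design_params()) {
    if (anyNA(repetitiveness) || anyNA(tm) || anyNA(comp))
        stop("unscored candidate: component scores must be populated")
    w <- params$score_weights
    cm <- ifelse(is.na(close_matches), 0, close_matches)
    w[["rep"]] * log10(1 + repetitiveness) +
        w[["uni"]] * pmax(0, cm - 1) +
        w[["tm"]] * abs(tm - params$tm_target) +
        w[["comp"]] * comp
}

# Score a tiled candidate set: repetitiveness first (repetitive candidates
# are removed from further characterization, so close matches are only
# computed for non-repetitive ones), then uniqueness, Tm, composition.
.score_candidates <- function(cands, genome, index, params) {
    n <- nrow(cands)
    if (n == 0) {
        cands$repetitiveness <- numeric(0); cands$close_matches <- integer(0)
        cands$tm <- numeric(0); cands$composition_penalty <- numeric(0)
        cands$repetitive <- logical(0); cands$nonunique <- logical(0)
        cands$passed <- logical(0); cands$score <- numeric(0)
        return(cands)
    }
    cands$repetitiveness <- .repetitiveness_batch(cands$sequence, index)
    cands$repetitive <- cands$repetitiveness > params$repetitive_threshold
    cands$close_matches <- NA_integer_
    nonrep <- which(!cands$repetitive)
    if (length(nonrep)) {
        cm <- .close_matches_batch(cands[nonrep, , drop = FALSE], genome, params)
        if (!params$count_origin_locus) cm <- pmax(0L, cm - 1L)
        cands$close_matches[nonrep] <- cm
    }
    cands$nonunique <- !is.na(cands$close_matches) &
        cands$close_matches > params$max_close_matches
    cands$tm <- vapply(cands$sequence, melting_temperature, numeric(1),
                       USE.NAMES = FALSE)
    cands$composition_penalty <- vapply(cands$sequence, composition_penalty,
                                        numeric(1), w_gc = params$w_gc,
                                        w_homo = params$w_homo,
                                        USE.NAMES = FALSE)
    cands$passed <- !cands$repetitive & !cands$nonunique
    cands$score <- NA_real_
    if (any(cands$passed))
        cands$score[cands$passed] <- probe_score(
            cands$repetitiveness[cands$passed],
            cands$close_matches[cands$passed],
            cands$tm[cands$passed],
            cands$composition_penalty[cands$passed], params)
    cands
}

#' Select probes for one target by windowed best-in-window scoring
#'
#' A window of `window_len` bases starts at `target$start -
#' flank_allowance`; among eligible (passed) candidates whose start lies in
#' the window, the `probes_per_window` lowest-scoring are shortlisted and
#' the single best selected (ties broken by leftmost start, then shortest
#' length). The window then advances by `window_advance` bases until it
#' reaches `target$end + flank_allowance`. Duplicate selections collapse.
#'
#' @param target one-row `region_set`.
#' @param cands scored candidates (from [tile_candidates()] via
#'   `.score_candidates`, i.e. with `passed` and `score` columns).
#' @param params a [design_params()] object.
#' @return List with `probes` (selected candidate rows) and `log` (one-row
#'   data.frame: windows scanned, candidates, selected).
#' @export
select_probes <- function(target, cands, params = design_params()) {
    w0 <- target$start[1] - params$flank_allowance
    w_stop <- target$end[1] + params$flank_allowance
    sel <- integer(0)
    n_win <- 0L
    W <- w0
    while (W < w_stop) {
        n_win <- n_win + 1L
        in_win <- which(cands$passed &
                        cands$start >= W & cands$start < W + params$window_len)
        if (length(in_win)) {
            ord <- in_win[order(cands$score[in_win], cands$start[in_win],
                                cands$length[in_win])]
            short <- utils::head(ord, params$probes_per_window)
            sel <- c(sel, short[1])
        }
        W <- W + params$window_advance
    }
    sel <- unique(sel)
    probes <- cands[sel, , drop = FALSE]
    rownames(probes) <- NULL
    log <- data.frame(chrom = target$chrom[1], start = target$start[1],
                      end = target$end[1], n_candidates = nrow(cands),
                      n_eligible = sum(cands$passed), n_windows = n_win,
                      n_selected = nrow(probes), stringsAsFactors = FALSE)
    list(probes = probes, log = log)
}

#' Classify target bases as directly, indirectly or not covered
#'
#' A target base is *direct* when it lies under a selected probe,
#' *indirect* when it is within `indirect_reach` bases of a probe terminus
#' but not under one, and *uncovered* otherwise.
#'
#' @param probes data.frame of probes with `chrom`, `start`, `length` (e.g.
#'   the `probes` element of [design_exome()]).
#' @param targets a `region_set`.
#' @param indirect_reach reach in bases (default 100).
#' @return A `coverage_report`: list with `direct_bases`, `indirect_bases`,
#'   `uncovered_bases`, `total_bases` and a `per_target` data.frame.
#' @export
coverage_report <- function(probes, targets, indirect_reach = 100L) {
    pt <- data.frame(chrom = targets$chrom, start = targets$start,
                     end = targets$end,
                     direct = integer(nrow(targets)),
                     indirect = integer(nrow(targets)),
                     uncovered = targets$end - targets$start,
                     stringsAsFactors = FALSE)
    if (nrow(probes) > 0 && nrow(targets) > 0) {
        for (i in seq_len(nrow(targets))) {
            p <- probes[probes$chrom == targets$chrom[i], , drop = FALSE]
            width <- targets$end[i] - targets$start[i]
            if (nrow(p) == 0) next
            tgt <- IRanges::IRanges(targets$start[i] + 1L, targets$end[i])
            pr <- IRanges::reduce(IRanges::IRanges(p$start + 1L,
                                                   p$start + p$length))
            direct <- IRanges::intersect(tgt, pr)
            near <- IRanges::reduce(IRanges::IRanges(
                pmax(1L, BiocGenerics::start(pr) - indirect_reach),
                BiocGenerics::end(pr) + indirect_reach))
            indir <- IRanges::setdiff(IRanges::intersect(tgt, near), direct)
            pt$direct[i] <- sum(IRanges::width(direct))
            pt$indirect[i] <- sum(IRanges::width(indir))
            pt$uncovered[i] <- width - pt$direct[i] - pt$indirect[i]
        }
    }
    structure(list(direct_bases = sum(pt$direct),
                   indirect_bases = sum(pt$indirect),
                   uncovered_bases = sum(pt$uncovered),
                   total_bases = total_bases(targets),
                   indirect_reach = as.integer(indirect_reach),
                   per_target = pt),
              class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
    cat("coverage_report over", x$total_bases, "target bases:\n")
    cat(sprintf("  direct   %9d (%.1f%%)\n", x$direct_bases,
                100 * x$direct_bases / max(1, x$total_bases)))
    cat(sprintf("  indirect %9d (%.1f%%)  [reach %d]\n", x$indirect_bases,
                100 * x$indirect_bases / max(1, x$total_bases),
                x$indirect_reach))
    cat(sprintf("  uncovered%9d (%.1f%%)\n", x$uncovered_bases,
                100 * x$uncovered_bases / max(1, x$total_bases)))
    invisible(x)
}

#' Design capture probes for a whole annotation
#'
#' Orchestrates the full design: consolidate features into targets, build
#' the genome k-mer index, then per target tile, filter (repetitiveness,
#' uniqueness), score (Tm, composition) and select probes in sliding
#' windows; finally classify target-base coverage.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param features feature data.frame from [load_features()] (or an already
#'   consolidated `region_set`).
#' @param params a [design_params()] object.
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>.probes.bed`, `<prefix>.probes.fasta`, `<prefix>.targets.bed`,
#'   `<prefix>.coverage.tsv` and `<prefix>.design.log`.
#' @return A `probe_set`: list with `probes` (selected probes with all four
#'   component scores), `targets`, `coverage`, `selection_log`, `params`.
#' @export
design_exome <- function(genome, features, params = design_params(),
                         out_prefix = NULL) {
    targets <- if (inherits(features, "region_set")) features
               else consolidate_targets(features)
    index <- build_kmer_index(genome, params$k, params$canonical_kmers)
    probes <- list(); logs <- list()
    for (i in seq_len(nrow(targets))) {
        tgt <- targets[i, , drop = FALSE]
        cands <- suppressWarnings(tile_candidates(tgt, genome, params))
        cands <- .score_candidates(cands, genome, index, params)
        res <- select_probes(tgt, cands, params)
        probes[[i]] <- res$probes
        logs[[i]] <- res$log
    }
    probes <- if (length(probes)) do.call(rbind, probes) else
        data.frame(chrom = character(), start = integer(), length = integer(),
                   sequence = character(), stringsAsFactors = FALSE)
    if (nrow(probes)) {
        probes <- unique(probes)
        probes <- probes[order(probes$chrom, probes$start, probes$length), ,
                         drop = FALSE]
        rownames(probes) <- NULL
    }
    logs <- if (length(logs)) do.call(rbind, logs) else NULL
    cov <- coverage_report(probes, targets, params$indirect_reach)
    ps <- structure(list(probes = probes, targets = targets, coverage = cov,
                         selection_log = logs, params = params),
                    class = "probe_set")
    if (!is.null(out_prefix)) write_probe_set(ps, out_prefix)
    ps
}

#' @export
print.probe_set <- function(x, ...) {
    cat("probe_set:", nrow(x$probes), "probes over", nrow(x$targets),
        "target region(s)\n")
    print(x$coverage)
    invisible(x)
}

#' Write a probe set's output files
#'
#' @param ps a `probe_set` from [design_exome()].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_probe_set <- function(ps, prefix) {
    p <- ps$probes
    con <- file(paste0(prefix, ".probes.bed"), "wb"); on.exit(close(con))
    writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
    if (nrow(p))
        writeLines(paste(p$chrom, p$start, p$start + p$length,
                         paste0(p$chrom, ":", p$start, "-", p$start + p$length),
                         round(p$score * 100), ".", sep = "\t"), con)
    fa <- character(0)
    if (nrow(p))
        fa <- as.vector(rbind(paste0(">", p$chrom, ":", p$start, "-",
                                     p$start + p$length), p$sequence))
    con2 <- file(paste0(prefix, ".probes.fasta"), "wb")
    writeLines(fa, con2); close(con2)
    write_bed(ps$targets, paste0(prefix, ".targets.bed"))
    cov <- ps$coverage$per_target
    con3 <- file(paste0(prefix, ".coverage.tsv"), "wb")
    writeLines(c("#chrom\tstart\tend\tdirect\tindirect\tuncovered",
                 if (nrow(cov)) paste(cov$chrom, cov$start, cov$end,
                                      cov$direct, cov$indirect, cov$uncovered,
                                      sep = "\t")), con3)
    close(con3)
    con4 <- file(paste0(prefix, ".design.log"), "wb")
    writeLines(c(utils::capture.output(print(ps$params)),
                 sprintf("targets=%d total_bases=%d probes=%d",
                         nrow(ps$targets), total_bases(ps$targets),
                         nrow(ps$probes)),
                 sprintf("direct=%d indirect=%d uncovered=%d",
                         ps$coverage$direct_bases, ps$coverage$indirect_bases,
                         ps$coverage$uncovered_bases)), con4)
    close(con4)
    invisible(prefix)
}
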
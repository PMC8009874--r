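# Close-match uniqueness: a probe is non-unique when too many genome loci
# carry an approximate copy of any of its close_match_len-base windows.

# guaranteed pigeonhole seed length for len bases / max_edits edits
.seed_len_for <- function(len, max_edits) max(1L, len %/% (max_edits + 1L))

# all close-match window sequences of a probe (NULL-safe)
.probe_windows <- function(probe_seq, len) {
    L <- nchar(probe_seq)
    if (L < len) stop("probe (", L, " bases) shorter than close_match_len = ", len)
    w <- substring(probe_seq, 1:(L - len + 1L), len:L)
    w[!grepl("[^ACGT]", w)]
}

# ends (0-based exclusive, per chromosome & strand) -> merged loci count
.merge_loci <- function(hits) {
    # hits: data.frame(chrom, strand, end); intervals [end-len, end) merged
    if (nrow(hits) == 0) return(hits[0, c("chrom", "strand", "start", "end")])
    out <- do.call(rbind, lapply(split(hits, paste(hits$chrom, hits$strand)),
        function(h) {
            ir <- IRanges::reduce(IRanges::IRanges(pmax(0L, h$end - h$len) + 1L,
                                                   h$end))
            data.frame(chrom = h$chrom[1], strand = h$strand[1],
                       start = BiocGenerics::start(ir) - 1L,
                       end = BiocGenerics::end(ir),
                       stringsAsFactors = FALSE)
        }))
    rownames(out) <- NULL
    out[order(out$chrom, out$strand, out$start), , drop = FALSE]
}

#' Close-match loci of a probe
#'
#' Finds every genome locus (either strand) at which some
#' `close_match_len`-base window of the probe aligns with at most
#' `close_match_max_edits` edits, using exact-seed candidate generation
#' (pigeonhole-guaranteed seed length) with banded edit-distance
#' verification. Overlapping hits on the same strand are merged into one
#' locus. Minus-strand matches are located by querying the
#' reverse-complemented windows against the forward genome.
#'
#' @param probe_seq probe sequence.
#' @param genome a [Biostrings::DNAStringSet].
#' @param params a [design_params()] object (uses `close_match_len` and
#'   `close_match_max_edits`).
#' @return A data.frame of merged loci: `chrom`, `strand`, `start`, `end`
#'   (0-based half-open, forward-strand coordinates).
#' @export
close_match_loci <- function(probe_seq, genome, params = design_params()) {
    len <- params$close_match_len
    k <- params$close_match_max_edits
    seed <- .seed_len_for(len, k)
    wins <- .probe_windows(probe_seq, len)
    hits <- list()
    if (length(wins)) {
        wins_rc <- .revcomp_chr(wins)
        for (chrom in names(genome)) {
            text <- as.character(genome[[chrom]])
            for (st in c("+", "-")) {
                qs <- if (st == "+") wins else wins_rc
                ends <- unique(unlist(.cm_seed_ends(qs, text, k, seed),
                                      use.names = FALSE))
                if (length(ends))
                    hits[[length(hits) + 1L]] <-
                        data.frame(chrom = chrom, strand = st, end = ends,
                                   len = len, stringsAsFactors = FALSE)
            }
        }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else
        data.frame(chrom = character(), strand = character(),
                   end = integer(), len = integer(), stringsAsFactors = FALSE)
    .merge_loci(hits)
}

#' Count close-match loci of a probe
#'
#' @inheritParams close_match_loci
#' @return Number of merged close-match loci genome-wide (the probe's own
#'   origin locus is included).
#' @export
count_close_matches <- function(probe_seq, genome, params = design_params()) {
    nrow(close_match_loci(probe_seq, genome, params))
}

# Batched close-match counting for many candidates sharing a genome.
# Candidates at nearby starts share most of their windows, so windows are
# deduplicated by sequence before querying, then hits are re-attributed.
# Loci are counted by run-splitting sorted hit ends per (chrom, strand):
# intervals [end-len, end) merge iff consecutive ends differ by <= len.
# cands: data.frame(chrom, start, length, sequence). Returns integer counts.
.close_matches_batch <- function(cands, genome, params) {
    len <- params$close_match_len
    k <- params$close_match_max_edits
    seed <- .seed_len_for(len, k)
    n <- nrow(cands)
    if (n == 0) return(integer(0))
    win_of <- lapply(seq_len(n), function(i)
        tryCatch(.probe_windows(cands$sequence[i], len),
                 error = function(e) character()))
    uniq <- unique(unlist(win_of, use.names = FALSE))
    if (!length(uniq)) return(rep(0L, n))
    uniq_rc <- .revcomp_chr(uniq)
    # per unique window: hit keys group_code * M + end, where group_code
    # encodes (chromosome, strand)
    M <- max(Biostrings::width(genome)) + len + 2
    keys <- rep(list(numeric(0)), length(uniq))
    for (ci in seq_along(genome)) {
        text <- as.character(genome[[ci]])
        hf <- .cm_seed_ends(uniq, text, k, seed)
        hr <- .cm_seed_ends(uniq_rc, text, k, seed)
        gf <- (2 * ci) * M; gr <- (2 * ci + 1) * M
        for (j in seq_along(uniq)) {
            kj <- c(if (length(hf[[j]])) gf + hf[[j]],
                    if (length(hr[[j]])) gr + hr[[j]])
            if (length(kj)) keys[[j]] <- c(keys[[j]], kj)
        }
    }
    vapply(win_of, function(w) {
        kk <- sort(unique(unlist(keys[match(w, uniq)], use.names = FALSE)))
        if (!length(kk)) return(0L)
        if (length(kk) == 1L) return(1L)
        grp <- kk %/% M
        e <- kk %% M
        sum(diff(grp) != 0 | diff(e) > len) + 1L
    }, integer(1))
}
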
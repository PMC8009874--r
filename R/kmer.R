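.revcomp_chr <- function(x) {
    # vectorised reverse complement on character vectors
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.kmers_of <- function(seq_chr, k) {
    n <- nchar(seq_chr)
    if (n < k) return(character())
    substring(seq_chr, 1:(n - k + 1L), k:n)
}

#' Build a genome-wide k-mer occurrence index
#'
#' Counts every N-free k-mer over all chromosomes. With
#' `canonical = TRUE` (the default) a k-mer and its reverse complement are
#' collapsed to the lexicographically smaller of the two before counting,
#' reflecting the strand symmetry of hybridization capture.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param k k-mer length (default 15).
#' @param canonical collapse strands to canonical form.
#' @return A `kmer_index`: list with `k`, `canonical` and `counts` (a named
#'   integer vector; k-mers containing N are absent; every stored count is
#'   at least 1).
#' @export
build_kmer_index <- function(genome, k = 15L, canonical = TRUE) {
    k <- as.integer(k)
    stopifnot(k >= 1L, length(genome) > 0L)
    all_k <- unlist(lapply(as.character(genome), .kmers_of, k = k),
                    use.names = FALSE)
    all_k <- all_k[!grepl("[^ACGT]", all_k)]
    if (!length(all_k)) {
        warning("no valid ", k, "-mers in genome (k too large or all N?)")
        counts <- integer(0)
    } else {
        if (canonical) all_k <- pmin(all_k, .revcomp_chr(all_k))
        tb <- table(all_k)
        counts <- setNames(as.integer(tb), names(tb))
    }
    structure(list(k = k, canonical = canonical, counts = counts),
              class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
    cat("kmer_index: k=", x$k, ", ", length(x$counts), " distinct ",
        if (x$canonical) "canonical " else "", "k-mers, total count ",
        sum(x$counts), "\n", sep = "")
    invisible(x)
}

#' Mean k-mer count of a probe (repetitiveness)
#'
#' Slides a k-base window across the probe and averages the genome-wide
#' occurrence count of each window's k-mer. Windows containing N, or absent
#' from the index, contribute 0.
#'
#' @param probe_seq probe sequence (single character string).
#' @param index a `kmer_index` from [build_kmer_index()].
#' @return Mean count over the `nchar(probe_seq) - k + 1` windows.
#' @export
probe_repetitiveness <- function(probe_seq, index) {
    k <- index$k
    L <- nchar(probe_seq)
    if (L < k) stop("probe (", L, " bases) shorter than k = ", k)
    km <- .kmers_of(probe_seq, k)
    valid <- !grepl("[^ACGT]", km)
    counts <- numeric(length(km))
    if (any(valid)) {
        key <- km[valid]
        if (index$canonical) key <- pmin(key, .revcomp_chr(key))
        hit <- index$counts[key]
        hit[is.na(hit)] <- 0L
        counts[valid] <- hit
    }
    mean(counts)
}

# Batched repetitiveness over many candidate sequences: one canonicalisation
# pass over the pooled unique k-mers, then per-candidate means. Agrees with
# probe_repetitiveness() exactly.
.repetitiveness_batch <- function(seqs, index) {
    k <- index$k
    km_of <- lapply(seqs, .kmers_of, k = k)
    nwin <- lengths(km_of)
    if (any(nwin == 0))
        stop("candidate shorter than k = ", k)
    all_km <- unlist(km_of, use.names = FALSE)
    u <- unique(all_km)
    uc <- numeric(length(u))
    valid <- !grepl("[^ACGT]", u)
    if (any(valid)) {
        key <- u[valid]
        if (index$canonical) key <- pmin(key, .revcomp_chr(key))
        hit <- index$counts[key]
        hit[is.na(hit)] <- 0L
        uc[valid] <- hit
    }
    per_win <- uc[match(all_km, u)]
    grp <- rep.int(seq_along(seqs), nwin)
    as.numeric(tapply(per_win, grp, mean))
}
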
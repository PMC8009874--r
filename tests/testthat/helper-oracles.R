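# Independent oracles and small in-code fixtures shared across tests.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

revcomp_str <- function(s) {
    # deliberately independent of the package's Biostrings-based helper
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# brute-force k-mer recount: plain double loop, own canonicalisation
oracle_kmer_counts <- function(seqs, k, canonical = TRUE) {
    counts <- new.env(hash = TRUE)
    for (s in seqs) {
        n <- nchar(s)
        if (n < k) next
        for (i in 1:(n - k + 1)) {
            km <- substr(s, i, i + k - 1)
            if (grepl("[^ACGT]", km)) next
            if (canonical) {
                rc <- revcomp_str(km)
                if (rc < km) km <- rc
            }
            counts[[km]] <- (if (is.null(counts[[km]])) 0L else counts[[km]]) + 1L
        }
    }
    out <- unlist(as.list(counts))
    out[order(names(out))]
}

# brute-force close-match count: exhaustive Sellers DP over every offset of
# every window on both strands, then plain interval merging per strand
oracle_close_match_count <- function(probe, genome, len = 30, max_edits = 5) {
    total <- 0L
    wins <- substring(probe, 1:(nchar(probe) - len + 1), len:nchar(probe))
    wins_rc <- vapply(wins, revcomp_str, "", USE.NAMES = FALSE)
    for (ch in names(genome)) {
        text <- as.character(genome[[ch]])
        for (qs in list(wins, wins_rc)) {
            ends <- sort(unique(unlist(
                exocap:::.cm_scan_ends(qs, text, max_edits))))
            if (!length(ends)) next
            merged <- 1L
            for (i in seq_along(ends)[-1])
                if (ends[i] - ends[i - 1] > len) merged <- merged + 1L
            total <- total + merged
        }
    }
    total
}

# tiny two-chromosome random genome used by several suites
make_toy_genome <- function(seed = 42, n1 = 3000, n2 = 1500) {
    set.seed(seed)
    g <- Biostrings::DNAStringSet(c(c1 = rand_dna(n1), c2 = rand_dna(n2)))
    g
}

region_df <- function(chrom, start, end, gene_ids = "") {
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(end), gene_ids = gene_ids,
               stringsAsFactors = FALSE)
}

# minimal record table in the load_vcf() layout
make_records <- function(chrom, pos, ref, alt, gt = NULL, ...) {
    df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                     alt = alt, stringsAsFactors = FALSE)
    df$biallelic <- !grepl(",", df$alt)
    df$vtype <- ifelse(!df$biallelic, "other",
                ifelse(nchar(df$ref) == 1 & nchar(df$alt) == 1 &
                       df$ref != df$alt, "SNV",
                ifelse(nchar(df$ref) != nchar(df$alt), "indel", "other")))
    extra <- list(...)
    for (key in c("QD", "FS", "SOR", "MQ", "ReadPosRankSum", "MQRankSum"))
        df[[key]] <- if (key %in% names(extra)) extra[[key]] else NA_real_
    if (!is.null(gt)) for (s in colnames(gt)) df[[paste0("gt_", s)]] <- gt[, s]
    df
}
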
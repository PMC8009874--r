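#' Load a genome from FASTA
#'
#' Reads every record, uppercases the sequence, and maps IUPAC ambiguity
#' codes other than N to N (with a warning giving the number of replaced
#' bases). Plain and bgzip/gzip FASTA are accepted.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] over the alphabet {A,C,G,T,N}, named
#'   by the first whitespace-delimited token of each header.
#' @export
load_genome <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- readLines(path, warn = FALSE)
    if (!any(startsWith(raw, ">"))) {
        warning("FASTA file '", path, "' contains no records")
        return(Biostrings::DNAStringSet())
    }
    g <- Biostrings::readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    if (anyDuplicated(names(g)))
        stop("duplicate sequence names in ", path, ": ",
             paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
    s <- toupper(as.character(g))
    cleaned <- gsub("[^ACGTN]", "N", s)
    n_repl <- sum(nchar(s)) - sum(mapply(function(a, b) {
        sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    }, s, cleaned)) # counts positions changed
    if (n_repl > 0)
        warning(n_repl, " ambiguous base(s) mapped to N")
    out <- Biostrings::DNAStringSet(cleaned)
    names(out) <- names(g)
    out
}

.gene_id_of <- function(mcols_df) {
    pick <- function(col) {
        if (!col %in% names(mcols_df)) return(NULL)
        v <- mcols_df[[col]]
        if (is(v, "CharacterList") || is.list(v))
            v <- vapply(v, function(x) if (length(x)) as.character(x[[1]])
                        else NA_character_, character(1))
        as.character(v)
    }
    out <- rep(NA_character_, nrow(mcols_df))
    for (col in c("gene_id", "gene", "Parent", "ID", "Name")) {
        v <- pick(col)
        if (!is.null(v)) out <- ifelse(is.na(out) | out == "", v, out)
    }
    out[is.na(out)] <- ""
    out
}

#' Load features from GFF3/GTF
#'
#' Coordinates are converted from the 1-based inclusive GFF/GTF convention
#' to the package-wide 0-based half-open convention at parse time.
#'
#' @param path GFF3 or GTF file (format detected from the extension).
#' @param kinds feature types to keep (matched against column 3).
#' @param genome optional genome ([Biostrings::DNAStringSet] or a named
#'   vector of chromosome lengths); when given, features on unknown
#'   chromosomes are dropped with a warning and features extending past the
#'   chromosome end raise an error.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `kind`, `gene_id`.
#' @export
load_features <- function(path, kinds = "CDS", genome = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     kind = as.character(gr$type),
                     gene_id = .gene_id_of(as.data.frame(S4Vectors::mcols(gr))),
                     stringsAsFactors = FALSE)
    df$strand[df$strand == "*"] <- "."
    df <- df[df$kind %in% kinds, , drop = FALSE]
    if (!is.null(genome)) {
        lens <- if (is(genome, "DNAStringSet"))
            setNames(Biostrings::width(genome), names(genome)) else genome
        unknown <- !(df$chrom %in% names(lens))
        if (any(unknown)) {
            warning(sum(unknown), " feature(s) on unknown chromosome(s) ",
                    "dropped: ", paste(unique(df$chrom[unknown]), collapse = ", "))
            df <- df[!unknown, , drop = FALSE]
        }
        bad <- df$end > lens[df$chrom] | df$start < 0L
        if (any(bad))
            stop(sum(bad), " feature(s) extend beyond chromosome bounds ",
                 "(first at ", df$chrom[bad][1], ":", df$start[bad][1], "-",
                 df$end[bad][1], ")")
    }
    rownames(df) <- NULL
    df
}

.new_region_set <- function(df) {
    df <- df[, c("chrom", "start", "end", "gene_ids"), drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("region_set", "data.frame")
    df
}

#' Total bases in a region set
#' @param rs a `region_set`.
#' @return Integer sum of region widths.
#' @export
total_bases <- function(rs) sum(rs$end - rs$start)

# core union/merge; input df needs chrom,start,end and optionally gene_ids
.consolidate <- function(df) {
    if (nrow(df) == 0)
        return(.new_region_set(data.frame(chrom = character(),
                                          start = integer(), end = integer(),
                                          gene_ids = character(),
                                          stringsAsFactors = FALSE)))
    if (is.null(df$gene_ids)) df$gene_ids <- ""
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end))
    GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
    red <- GenomicRanges::reduce(GenomicRanges::sort(gr, ignore.strand = TRUE),
                                 with.revmap = TRUE, min.gapwidth = 1L)
    ids <- vapply(red$revmap, function(ix) {
        g <- unlist(strsplit(df$gene_ids[ix], ",", fixed = TRUE))
        g <- sort(unique(g[g != "" & !is.na(g)]))
        paste(g, collapse = ",")
    }, character(1))
    .new_region_set(data.frame(chrom = as.character(GenomeInfoDb::seqnames(red)),
                               start = BiocGenerics::start(red) - 1L,
                               end = BiocGenerics::end(red),
                               gene_ids = ids, stringsAsFactors = FALSE))
}

#' Consolidate features into non-overlapping target regions
#'
#' Takes the strand-agnostic union of feature intervals; overlapping and
#' book-ended (adjacent) intervals are merged, and each merged region keeps
#' the union of the contributing gene identifiers.
#'
#' @param features a data.frame as returned by [load_features()].
#' @return A `region_set`: a data.frame with columns `chrom`, `start`,
#'   `end`, `gene_ids` (comma-joined), sorted by (chrom, start), with
#'   non-overlapping, non-adjacent regions.
#' @export
consolidate_targets <- function(features) {
    if (nrow(features) == 0) return(.consolidate(features[0, , drop = FALSE]))
    df <- data.frame(chrom = features$chrom, start = features$start,
                     end = features$end,
                     gene_ids = if (!is.null(features$gene_id))
                         features$gene_id else features$gene_ids,
                     stringsAsFactors = FALSE)
    .consolidate(df)
}

#' Grow or shrink target regions
#'
#' Each region is extended (positive `pad`) or trimmed (negative `pad`) by
#' `pad` bases on both sides, clipped to chromosome bounds, and the result
#' re-consolidated (growth can make neighbours overlap). Regions that would
#' vanish under a negative pad are dropped with a warning.
#'
#' @param rs a `region_set`.
#' @param pad signed number of bases.
#' @param chrom_lengths optional named vector of chromosome lengths (or a
#'   [Biostrings::DNAStringSet]) for right-edge clipping.
#' @return A `region_set`.
#' @export
adjust_regions <- function(rs, pad, chrom_lengths = NULL) {
    if (nrow(rs) == 0) return(rs)
    pad <- as.integer(pad)
    df <- as.data.frame(rs)
    if (pad < 0) {
        gone <- (df$end - df$start) <= 2L * abs(pad)
        if (any(gone)) {
            warning(sum(gone), " region(s) vanished under pad ", pad,
                    " and were dropped")
            df <- df[!gone, , drop = FALSE]
        }
    }
    if (nrow(df) == 0) return(.consolidate(df))
    df$start <- pmax(0L, df$start - pad)
    df$end <- df$end + pad
    if (!is.null(chrom_lengths)) {
        lens <- if (is(chrom_lengths, "DNAStringSet"))
            setNames(Biostrings::width(chrom_lengths), names(chrom_lengths))
        else chrom_lengths
        df$end <- pmin(df$end, as.integer(lens[df$chrom]))
    }
    .consolidate(df)
}

#' Write a region set to BED6
#'
#' Tab-separated, LF-terminated, with one `#`-prefixed header line. The name
#' column holds the comma-joined gene ids (or "."), score is 0 and strand
#' is ".".
#'
#' @param rs a `region_set`.
#' @param path output file.
#' @export
write_bed <- function(rs, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con, sep = "\n")
    if (nrow(rs)) {
        nm <- ifelse(rs$gene_ids == "", ".", rs$gene_ids)
        writeLines(paste(rs$chrom, rs$start, rs$end, nm, 0L, ".",
                         sep = "\t"), con, sep = "\n")
    }
    invisible(path)
}

#' Read a BED6 region set written by [write_bed()]
#' @param path BED file.
#' @return A `region_set`.
#' @export
read_bed <- function(path) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    if (!length(ln))
        return(.consolidate(data.frame(chrom = character(), start = integer(),
                                       end = integer(), gene_ids = character(),
                                       stringsAsFactors = FALSE)))
    f <- strsplit(ln, "\t", fixed = TRUE)
    df <- data.frame(chrom = vapply(f, `[`, "", 1),
                     start = as.integer(vapply(f, `[`, "", 2)),
                     end = as.integer(vapply(f, `[`, "", 3)),
                     gene_ids = vapply(f, `[`, "", 4),
                     stringsAsFactors = FALSE)
    df$gene_ids[df$gene_ids == "."] <- ""
    .new_region_set(df)
}

#' @export
print.region_set <- function(x, ...) {
    cat("region_set: ", nrow(x), " region(s), ", total_bases(x),
        " bases\n", sep = "")
    if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
    invisible(x)
}

# region_set -> GRanges (1-based internal)
.rs_granges <- function(rs) {
    GenomicRanges::GRanges(rs$chrom, IRanges::IRanges(rs$start + 1L, rs$end))
}
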
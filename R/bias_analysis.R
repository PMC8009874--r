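#' Per-gene variant counts by platform and individual
#'
#' Assigns every classified site to a gene via the annotation table, then
#' counts per gene: sites per platform, and per individual per platform the
#' number of sites at which the individual carries at least one alternate
#' allele (carrier counting; set `dose = TRUE` to sum allele doses
#' instead). Sites with no gene assignment are accumulated in a reserved
#' "intergenic" bucket excluded from gene tables.
#'
#' @param pair a `platform_pair` (records should already be filtered and
#'   target-restricted as desired).
#' @param annotations data.frame with `chrom`, `pos`, `ref`, `alt`, `gene`
#'   (and optionally `consequence`, `impact`).
#' @param features optional feature data.frame from [load_features()] used
#'   to derive per-gene chromosome and consolidated coding length.
#' @param dose use allele-dose counting for individuals instead of carrier
#'   counting.
#' @return A `gene_count_matrix`: list with `site` (data.frame gene,
#'   count_a, count_b), `indiv_a`/`indiv_b` (gene x sample matrices),
#'   `genes` (gene, chrom, cds_bases), `samples`, `labels`, `intergenic`.
#' @export
per_gene_counts <- function(pair, annotations, features = NULL, dose = FALSE) {
    akey <- .var_key(annotations)
    side <- function(records) {
        ix <- match(.var_key(records), akey)
        gene <- ifelse(is.na(ix), NA_character_, annotations$gene[ix])
        gene[is.na(gene) | gene == ""] <- NA_character_
        list(records = records, gene = gene)
    }
    sa <- side(pair$a); sb <- side(pair$b)
    genes <- sort(unique(c(sa$gene, sb$gene)))
    genes <- genes[!is.na(genes)]
    cols <- union(.gt_cols(pair$a), .gt_cols(pair$b))
    samples <- sub("^gt_", "", cols)
    count_sites <- function(s) {
        tb <- table(factor(s$gene, levels = genes))
        setNames(as.integer(tb), genes)
    }
    indiv_mat <- function(s) {
        m <- matrix(0L, length(genes), length(samples),
                    dimnames = list(genes, samples))
        gt <- as.matrix(s$records[, paste0("gt_", samples), drop = FALSE])
        carrier <- if (dose) gt else (gt >= 1L) * 1L
        carrier[is.na(carrier)] <- 0L
        keep <- !is.na(s$gene)
        if (any(keep)) {
            agg <- rowsum(carrier[keep, , drop = FALSE], s$gene[keep])
            m[rownames(agg), ] <- agg
        }
        m
    }
    gene_meta <- data.frame(gene = genes, chrom = NA_character_,
                            cds_bases = NA_integer_, stringsAsFactors = FALSE)
    # chromosome per gene from the variants themselves
    gchrom <- tapply(c(sa$records$chrom, sb$records$chrom),
                     factor(c(sa$gene, sb$gene), levels = genes),
                     function(x) x[1])
    gene_meta$chrom <- as.character(gchrom[genes])
    if (!is.null(features)) {
        f <- features[features$gene_id %in% genes, , drop = FALSE]
        if (nrow(f)) {
            cds <- vapply(split(f, f$gene_id), function(d)
                total_bases(consolidate_targets(d)), numeric(1))
            gene_meta$cds_bases <- as.integer(cds[gene_meta$gene])
            fchrom <- vapply(split(f, f$gene_id), function(d) d$chrom[1],
                             character(1))
            known <- !is.na(fchrom[gene_meta$gene])
            gene_meta$chrom[known] <- fchrom[gene_meta$gene][known]
        }
    }
    structure(list(site = data.frame(gene = genes,
                                     count_a = count_sites(sa),
                                     count_b = count_sites(sb),
                                     stringsAsFactors = FALSE),
                   indiv_a = indiv_mat(sa), indiv_b = indiv_mat(sb),
                   genes = gene_meta, samples = samples,
                   labels = c(a = pair$label_a, b = pair$label_b),
                   intergenic = c(a = sum(is.na(sa$gene)),
                                  b = sum(is.na(sb$gene)))),
              class = "gene_count_matrix")
}

#' Gene-wise platform bias
#'
#' Per gene: the signed site-count difference (platform b minus platform a,
#' so genes with more platform-b variants are positive), the expected count
#' (mean of the two), and total variants per kb of consolidated coding
#' sequence. Outliers are the `n_top` genes with the largest positive
#' differences (ties broken by gene id).
#'
#' @param m a `gene_count_matrix`.
#' @param n_top number of outlier genes to report (default 50).
#' @return List with `table` (gene, count_a, count_b, difference, expected,
#'   snvs_per_kb) and `outliers` (the top rows).
#' @export
platform_bias <- function(m, n_top = 50L) {
    d <- m$site
    tab <- data.frame(gene = d$gene, count_a = d$count_a, count_b = d$count_b,
                      difference = d$count_b - d$count_a,
                      expected = (d$count_a + d$count_b) / 2,
                      snvs_per_kb = 1000 * (d$count_a + d$count_b) /
                          m$genes$cds_bases[match(d$gene, m$genes$gene)],
                      stringsAsFactors = FALSE)
    ord <- order(-tab$difference, tab$gene)
    outliers <- utils::head(tab[ord, , drop = FALSE], n_top)
    rownames(tab) <- rownames(outliers) <- NULL
    list(table = tab, outliers = outliers)
}

.split_sex <- function(m, sex_map) {
    sx <- setNames(toupper(sex_map$sex), sex_map$sample_id)[m$samples]
    unlabeled <- is.na(sx) | !(sx %in% c("M", "F"))
    if (any(unlabeled))
        warning(sum(unlabeled), " individual(s) without M/F sex label ",
                "excluded: ", paste(m$samples[unlabeled], collapse = ", "))
    list(males = m$samples[!unlabeled & sx == "M"],
         females = m$samples[!unlabeled & sx == "F"])
}

#' Per-gene sex fold change in variant detection
#'
#' For each gene and platform: `log2((mean_male + 1) / (mean_female + 1))`
#' where the means are per-individual variant counts. Positive values mean
#' more variants detected in males.
#'
#' @param m a `gene_count_matrix`.
#' @param sex_map data.frame with `sample_id` and `sex` in {M, F, U};
#'   unlabeled individuals are excluded with a warning.
#' @return data.frame with `gene`, `fold_a`, `fold_b` (NA when either sex
#'   has no labeled individuals).
#' @export
sex_bias_per_gene <- function(m, sex_map) {
    sx <- .split_sex(m, sex_map)
    fold <- function(mat) {
        if (!length(sx$males) || !length(sx$females)) {
            message("zero males or zero females: sex fold change undefined")
            return(rep(NA_real_, nrow(mat)))
        }
        mm <- rowMeans(mat[, sx$males, drop = FALSE])
        mf <- rowMeans(mat[, sx$females, drop = FALSE])
        log2((mm + 1) / (mf + 1))
    }
    data.frame(gene = rownames(m$indiv_a),
               fold_a = fold(m$indiv_a), fold_b = fold(m$indiv_b),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Sex-difference statistics from a pair of means
#'
#' The absolute difference of the two means and the percentage difference
#' expressed as a fraction of the male mean, both rounded to 2 decimals.
#'
#' @param mean_male,mean_female mean variant counts per individual
#'   (vectorised).
#' @return data.frame with `difference` and `pct_of_male`.
#' @export
sex_difference_stats <- function(mean_male, mean_female) {
    d <- abs(mean_male - mean_female)
    data.frame(difference = round(d, 2),
               pct_of_male = round(100 * d / mean_male, 2))
}

#' Sex-difference summary by gene grouping, platform and chromosome class
#'
#' For each gene grouping, platform and chromosome class (autosome vs X):
#' the mean per-individual variant count for males and for females over the
#' genes in the grouping, their absolute difference, and the percentage
#' difference as a fraction of the male mean.
#'
#' @param m a `gene_count_matrix`.
#' @param sex_map data.frame with `sample_id`, `sex`.
#' @param gene_groupings named list of gene-id vectors (default: one
#'   grouping "all" containing every gene). Unknown genes raise an error.
#' @param x_chrom chromosome name treated as X (default "chrX").
#' @return data.frame with `grouping`, `platform`, `chrom_class`,
#'   `mean_male`, `mean_female`, `difference`, `pct_of_male`.
#' @export
sex_difference_summary <- function(m, sex_map,
                                   gene_groupings = list(all = m$genes$gene),
                                   x_chrom = "chrX") {
    sx <- .split_sex(m, sex_map)
    if (!length(sx$males) || !length(sx$females))
        stop("need at least one labeled male and one labeled female")
    out <- list()
    for (gname in names(gene_groupings)) {
        gg <- gene_groupings[[gname]]
        unknown <- setdiff(gg, m$genes$gene)
        if (length(unknown))
            stop("grouping '", gname, "' references unknown gene(s): ",
                 paste(unknown, collapse = ", "))
        for (side in c("a", "b")) {
            mat <- m[[paste0("indiv_", side)]]
            for (cls in c("autosome", "X")) {
                on_x <- m$genes$chrom == x_chrom
                gsel <- intersect(gg, m$genes$gene[if (cls == "X") on_x
                                                   else !on_x])
                per_ind <- if (length(gsel))
                    colSums(mat[gsel, , drop = FALSE]) else
                    setNames(numeric(length(m$samples)), m$samples)
                mm <- mean(per_ind[sx$males]); mf <- mean(per_ind[sx$females])
                st <- sex_difference_stats(mm, mf)
                out[[length(out) + 1L]] <- data.frame(
                    grouping = gname, platform = m$labels[[side]],
                    chrom_class = cls, mean_male = round(mm, 2),
                    mean_female = round(mf, 2),
                    difference = st$difference, pct_of_male = st$pct_of_male,
                    stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, out)
}
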
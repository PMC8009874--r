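# Variant key shared by classification, annotation joins and truth tables.
.var_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

# per-sample alternate-allele dose from GT strings ("0/1", "1|1", "./.")
.gt_dose <- function(gt_mat) {
    v <- as.vector(gt_mat)
    spl <- strsplit(v, "[/|]")
    d <- vapply(spl, function(z) {
        if (!length(z) || anyNA(z) || any(z == "."))
            NA_integer_ else sum(z == "1")
    }, integer(1))
    matrix(d, nrow = nrow(gt_mat), dimnames = dimnames(gt_mat))
}

#' Load a VCF into a flat record table
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), typing each record as SNV, indel
#' or other, flagging biallelic status, extracting the six hard-filter INFO
#' statistics (missing keys give NA) and per-sample alternate-allele doses.
#'
#' @param path VCF file (plain or gzipped).
#' @param sample_subset optional character vector of sample names to keep.
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `vtype` ("SNV"/"indel"/"other"), `biallelic`, `QD`, `FS`, `SOR`, `MQ`,
#'   `ReadPosRankSum`, `MQRankSum`, and one `gt_<sample>` dose column
#'   (0/1/2/NA) per sample.
#' @export
load_vcf <- function(path, sample_subset = NULL) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = toupper(fix$REF), alt = toupper(fix$ALT),
                     stringsAsFactors = FALSE)
    df$alt[is.na(df$alt)] <- "."
    df$biallelic <- !grepl(",", df$alt) & df$alt != "."
    df$vtype <- ifelse(!df$biallelic, "other",
                ifelse(nchar(df$ref) == 1 & nchar(df$alt) == 1 &
                       df$ref != df$alt &
                       df$ref %in% c("A", "C", "G", "T") &
                       df$alt %in% c("A", "C", "G", "T"), "SNV",
                ifelse(nchar(df$ref) != nchar(df$alt), "indel", "other")))
    for (key in c("QD", "FS", "SOR", "MQ", "ReadPosRankSum", "MQRankSum"))
        df[[key]] <- suppressWarnings(
            as.numeric(vcfR::extract.info(vcf, element = key)))
    gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                   error = function(e)
                       stop("VCF has no GT field: ", conditionMessage(e)))
    dose <- .gt_dose(gt)
    if (!is.null(sample_subset)) {
        missing <- setdiff(sample_subset, colnames(dose))
        if (length(missing))
            stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
        dose <- dose[, sample_subset, drop = FALSE]
    }
    for (s in colnames(dose)) df[[paste0("gt_", s)]] <- dose[, s]
    df
}

.gt_cols <- function(records) grep("^gt_", names(records), value = TRUE)

#' Default GATK-style hard-filter thresholds
#'
#' SNVs fail on QD < 2, FS > 60, SOR > 3, ReadPosRankSum < -8, MQ < 40 or
#' MQRankSum < -12.5; indels fail on QD < 2, FS > 200, SOR > 10 or
#' ReadPosRankSum < -20. A record fails when ANY type-appropriate rule
#' matches.
#'
#' @return Named list with `snv` and `indel` rule sets; each rule is
#'   `c(op, threshold)` keyed by INFO field.
#' @export
hard_filter_thresholds <- function() {
    list(snv = list(QD = c("<", 2.0), FS = c(">", 60.0), SOR = c(">", 3.0),
                    ReadPosRankSum = c("<", -8.0), MQ = c("<", 40.0),
                    MQRankSum = c("<", -12.5)),
         indel = list(QD = c("<", 2.0), FS = c(">", 200.0),
                      SOR = c(">", 10.0), ReadPosRankSum = c("<", -20.0)))
}

#' Tag records pass/fail under hard-filter rules
#'
#' Nothing is deleted: a logical `filter_pass` column (and a `fail_reasons`
#' string) is added. A missing statistic makes its rule inapplicable (the
#' record cannot fail on it). SNV rules apply to SNVs; indel rules apply to
#' all non-SNV records.
#'
#' @param records record table from [load_vcf()].
#' @param thresholds rule sets as from [hard_filter_thresholds()].
#' @return `records` with `filter_pass` and `fail_reasons` columns; the
#'   per-rule failure counts are attached as attribute `rule_counts`.
#' @export
apply_hard_filters <- function(records, thresholds = hard_filter_thresholds()) {
    n <- nrow(records)
    fail <- matrix(FALSE, n, 0)
    reasons <- rep("", n)
    rule_counts <- c()
    for (cls in c("snv", "indel")) {
        sel <- if (cls == "snv") records$vtype == "SNV" else
            records$vtype != "SNV"
        for (field in names(thresholds[[cls]])) {
            rule <- thresholds[[cls]][[field]]
            thr <- as.numeric(rule[2])
            x <- records[[field]]
            hit <- sel & !is.na(x) &
                (if (rule[1] == "<") x < thr else x > thr)
            tag <- paste0(cls, ":", field, rule[1], thr)
            rule_counts[tag] <- sum(hit)
            reasons[hit] <- paste0(reasons[hit],
                                   ifelse(reasons[hit] == "", "", ";"),
                                   paste0(field, rule[1], thr))
            fail <- cbind(fail, hit)
        }
    }
    records$filter_pass <- rowSums(fail) == 0
    records$fail_reasons <- reasons
    attr(records, "rule_counts") <- rule_counts
    records
}

#' Restrict records to (trimmed) target regions
#'
#' With the default `flank_trim = 2`, variants flanking the targets by up
#' to 2 bases are removed: a record is kept only when its position lies
#' strictly inside a target region shrunk by `flank_trim` bases per side.
#' A negative `flank_trim` keeps variants up to that many bases outside the
#' targets instead.
#'
#' @param records record table.
#' @param targets a `region_set`.
#' @param flank_trim bases trimmed from each target end (default 2).
#' @return The kept records.
#' @export
restrict_to_targets <- function(records, targets, flank_trim = 2L) {
    if (nrow(records) == 0 || nrow(targets) == 0)
        return(records[0, , drop = FALSE])
    trim <- as.integer(flank_trim)
    s <- targets$start + trim
    e <- targets$end - trim
    ok <- e > s
    if (!any(ok)) return(records[0, , drop = FALSE])
    subj <- GenomicRanges::GRanges(targets$chrom[ok],
                                   IRanges::IRanges(s[ok] + 1L, e[ok]))
    qry <- GenomicRanges::GRanges(records$chrom,
                                  IRanges::IRanges(records$pos, records$pos))
    keep <- GenomicRanges::countOverlaps(qry, subj) > 0
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rule_counts") <- attr(records, "rule_counts")
    out
}

#' Classify paired platform call sets as common or exclusive
#'
#' A variant is *common* when the other platform has a record at the same
#' position with the same reference and alternate alleles; otherwise it is
#' exclusive to its platform. Classification is performed before any
#' filtering (filters are then applied per platform), so common counts may
#' differ slightly between platforms downstream.
#'
#' @param records_a,records_b record tables for the two platforms.
#' @param label_a,label_b platform labels.
#' @return A `platform_pair`: list with `a`, `b` (each with a `class`
#'   column, "common"/"exclusive") and the labels.
#' @export
classify_shared <- function(records_a, records_b,
                            label_a = "WES", label_b = "WGS") {
    ka <- .var_key(records_a); kb <- .var_key(records_b)
    records_a$class <- ifelse(ka %in% kb, "common", "exclusive")
    records_b$class <- ifelse(kb %in% ka, "common", "exclusive")
    structure(list(a = records_a, b = records_b,
                   label_a = label_a, label_b = label_b),
              class = "platform_pair")
}

#' @export
print.platform_pair <- function(x, ...) {
    for (side in c("a", "b")) {
        r <- x[[side]]
        cat(sprintf("%s: %d records, %d common, %d exclusive\n",
                    x[[paste0("label_", side)]], nrow(r),
                    sum(r$class == "common"), sum(r$class == "exclusive")))
    }
    invisible(x)
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; every other single-base substitution is
#' a transversion. Only SNV records contribute.
#'
#' @param records record table (only rows with `vtype == "SNV"` are used).
#' @return Ti count divided by Tv count; `NA` (undefined) when there are no
#'   transversions.
#' @export
titv_ratio <- function(records) {
    s <- records[records$vtype == "SNV", , drop = FALSE]
    if (nrow(s) == 0) return(NA_real_)
    ti_pairs <- c("A:G", "G:A", "C:T", "T:C")
    is_ti <- paste(s$ref, s$alt, sep = ":") %in% ti_pairs
    ti <- sum(is_ti); tv <- sum(!is_ti)
    if (tv == 0) {
        message("no transversions: Ti/Tv undefined")
        return(NA_real_)
    }
    ti / tv
}

#' Allele-count spectrum
#'
#' The allele count (AC) of a site is the number of alternate alleles
#' summed over all samples' genotypes. Returns the histogram over sites
#' with AC >= 1; sites at AC 0 are reported separately.
#'
#' @param records record table with `gt_` dose columns.
#' @return An `ac_spectrum`: list with `spectrum` (named integer vector,
#'   names = AC), `n_ac0`, and `ac` (per-site counts).
#' @export
allele_count_spectrum <- function(records) {
    cols <- .gt_cols(records)
    if (!length(cols)) stop("records carry no genotype columns")
    ac <- rowSums(as.matrix(records[, cols, drop = FALSE]), na.rm = TRUE)
    tb <- table(ac[ac >= 1])
    structure(list(spectrum = setNames(as.integer(tb), names(tb)),
                   n_ac0 = sum(ac == 0), ac = ac),
              class = "ac_spectrum")
}

#' @export
print.ac_spectrum <- function(x, ...) {
    cat("allele-count spectrum (", sum(x$spectrum), " sites; ", x$n_ac0,
        " at AC=0)\n", sep = "")
    print(x$spectrum)
    invisible(x)
}

#' Common/exclusive percentages of a table row
#'
#' @param common,exclusive counts (vectorised).
#' @return data.frame with `total`, `pct_common`, `pct_exclusive`
#'   (percentages of the row total, rounded to 1 decimal).
#' @export
concordance_pct <- function(common, exclusive) {
    total <- common + exclusive
    data.frame(total = total,
               pct_common = round(100 * common / total, 1),
               pct_exclusive = round(100 * exclusive / total, 1))
}

#' Consequence table for a platform pair
#'
#' Per (impact, consequence) category and platform: counts of common and
#' platform-exclusive variants among biallelic, filter-passing records of
#' the requested type, with percentages of the row total. "All" rollup rows
#' are added per impact and overall. Records that cannot be joined to an
#' annotation are excluded.
#'
#' @param pair a `platform_pair` whose record tables carry `filter_pass`
#'   (see [apply_hard_filters()]).
#' @param annotations data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `impact`.
#' @param vtype which variant type to tabulate ("SNV" or "indel").
#' @return data.frame with columns `platform`, `impact`, `consequence`,
#'   `common`, `exclusive`, `total`, `pct_common`, `pct_exclusive`.
#' @export
consequence_table <- function(pair, annotations, vtype = "SNV") {
    akey <- .var_key(annotations)
    one <- function(records, label) {
        r <- records[records$vtype == vtype & records$biallelic &
                     records$filter_pass, , drop = FALSE]
        ix <- match(.var_key(r), akey)
        r <- r[!is.na(ix), , drop = FALSE]
        ann <- annotations[ix[!is.na(ix)], , drop = FALSE]
        if (nrow(r) == 0) return(NULL)
        grp <- data.frame(impact = tolower(ann$impact),
                          consequence = ann$consequence,
                          common = r$class == "common")
        agg <- function(d, imp, cons) {
            cm <- sum(d$common); ex <- sum(!d$common)
            cbind(data.frame(platform = label, impact = imp,
                             consequence = cons, common = cm, exclusive = ex,
                             stringsAsFactors = FALSE),
                  concordance_pct(cm, ex))
        }
        rows <- do.call(rbind, lapply(
            split(grp, list(grp$impact, grp$consequence), drop = TRUE),
            function(d) agg(d, d$impact[1], d$consequence[1])))
        rollup <- do.call(rbind, lapply(split(grp, grp$impact, drop = TRUE),
            function(d) agg(d, d$impact[1], "All")))
        overall <- agg(grp, "All", "All")
        out <- rbind(rows, rollup, overall)
        out[out$total > 0, , drop = FALSE]
    }
    out <- rbind(one(pair$a, pair$label_a), one(pair$b, pair$label_b))
    if (is.null(out)) return(out)
    imp_order <- c("high", "moderate", "low", "modifier", "All")
    out <- out[order(out$platform, match(out$impact, imp_order),
                     out$consequence == "All", out$consequence), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
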
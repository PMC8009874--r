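# Seeded synthetic fixtures: toy genomes with repeat families and paralog
# clusters, multi-exon annotations, and paired platform call sets with
# controlled sharing, error spikes and sex-linked structure.

# one named RNG stream per component, so changing one spec field perturbs
# only its own stream
.substream <- function(seed, name) {
    set.seed((as.integer(seed) * 97L +
              sum(utf8ToInt(name)) * 10007L) %% 2147483647L)
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Specification of a synthetic fixture
#'
#' Defaults describe a small three-chromosome genome (two autosomes, one
#' X-like chromosome), a tandem repeat family dense enough to trip the
#' repetitiveness filter, a cluster of near-identical paralogs that confuse
#' close-match uniqueness, and a ten-individual paired call-set cohort with
#' a controlled shared fraction, singleton error spikes on both platforms,
#' and a male-only platform-b peak on the X at allele count 4 (matching a
#' four-male cohort in which every male is heterozygous).
#'
#' @param seed integer seed; every stochastic component derives its own
#'   stream from it.
#' @param chrom_length autosome/X length in bases.
#' @param n_genes total genes (including the paralog cluster).
#' @param exons_per_gene,exon_length,intron_length gene architecture.
#' @param repeat_unit,repeat_copies tandem repeat family embedded in the
#'   second autosome.
#' @param paralog_genes,paralog_divergence size of the paralog cluster on
#'   the first autosome and its per-base substitution divergence.
#' @param n_samples,n_males cohort composition (males are the first
#'   `n_males` samples).
#' @param shared_fraction fraction of sites common to both platforms.
#' @param exclusive_rate_a,exclusive_rate_b platform-exclusive singleton
#'   rates per target kb.
#' @param shared_rate optional shared-site rate per target kb; when NULL the
#'   shared count is derived from `shared_fraction` and the realised
#'   exclusive counts.
#' @param ti_prob_common,ti_prob_exclusive transition probability of shared
#'   and exclusive SNVs (0.797 and 0.603 give Ti/Tv of about 3.92 and 1.52).
#' @param indel_fraction fraction of shared/exclusive sites emitted as
#'   biallelic indels rather than SNVs.
#' @param male_only_x_genes number of X genes given male-only platform-b
#'   exclusive sites (emulating degraded-Y gametologs).
#' @param male_x_sites_per_gene sites per such gene.
#' @param male_ac_peak target allele count of those sites.
#' @param filter_fail_fraction per-rule probability that a record's INFO
#'   statistic is drawn in the failing range.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         chrom_length = 12000L,
                         n_genes = 18L,
                         exons_per_gene = 4L,
                         exon_length = 100L,
                         intron_length = 80L,
                         repeat_unit = 60L,
                         repeat_copies = 150L,
                         paralog_genes = 5L,
                         paralog_divergence = 0.02,
                         n_samples = 10L,
                         n_males = 4L,
                         shared_fraction = 0.9,
                         exclusive_rate_a = 2,
                         exclusive_rate_b = 5,
                         shared_rate = NULL,
                         ti_prob_common = 0.797,
                         ti_prob_exclusive = 0.603,
                         indel_fraction = 0.1,
                         male_only_x_genes = 3L,
                         male_x_sites_per_gene = 15L,
                         male_ac_peak = 4L,
                         filter_fail_fraction = 0.02) {
    sp <- as.list(environment())
    stopifnot(sp$shared_fraction >= 0, sp$shared_fraction <= 1,
              sp$ti_prob_common >= 0, sp$ti_prob_common <= 1,
              sp$ti_prob_exclusive >= 0, sp$ti_prob_exclusive <= 1,
              sp$indel_fraction >= 0, sp$indel_fraction < 1,
              sp$filter_fail_fraction >= 0, sp$filter_fail_fraction <= 1,
              sp$n_males <= sp$n_samples, sp$n_males >= 0,
              sp$paralog_genes <= sp$n_genes,
              sp$exclusive_rate_a >= 0, sp$exclusive_rate_b >= 0)
    class(sp) <- "fixture_spec"
    sp
}

# gene coordinate layout; paralogs first on chrA1, repeat block on chrA2
.fixture_layout <- function(sp) {
    gene_span <- sp$exons_per_gene * sp$exon_length +
        (sp$exons_per_gene - 1L) * sp$intron_length
    gap <- 150L
    rep_len <- sp$repeat_unit * sp$repeat_copies
    rest <- sp$n_genes - sp$paralog_genes
    n_a2 <- rest %/% 3L
    n_x <- rest - 2L * (rest %/% 3L)
    n_a1 <- sp$paralog_genes + (rest %/% 3L)
    if (sp$male_only_x_genes > n_x)
        stop("male_only_x_genes (", sp$male_only_x_genes,
             ") exceeds X gene count (", n_x, ")")
    chrom_of <- c(rep("chrA1", n_a1), rep("chrA2", n_a2), rep("chrX", n_x))
    lens <- c(chrA1 = sp$chrom_length,
              chrA2 = max(sp$chrom_length,
                          300L + rep_len + gap +
                              n_a2 * (gene_span + gap) + 300L),
              chrX = sp$chrom_length)
    offset <- c(chrA1 = 300L, chrA2 = 300L + rep_len + gap, chrX = 300L)
    genes <- data.frame(gene = sprintf("g%03d", seq_len(sp$n_genes)),
                        chrom = chrom_of, start = NA_integer_,
                        end = NA_integer_,
                        class = "regular", stringsAsFactors = FALSE)
    genes$class[seq_len(sp$paralog_genes)] <- "paralog"
    on_x <- which(genes$chrom == "chrX")
    genes$class[on_x[seq_len(sp$male_only_x_genes)]] <- "x_male_biased"
    for (ch in unique(chrom_of)) {
        ix <- which(chrom_of == ch)
        starts <- offset[[ch]] + (seq_along(ix) - 1L) * (gene_span + gap)
        genes$start[ix] <- starts
        genes$end[ix] <- starts + gene_span
        if (length(ix) && max(genes$end[ix]) + 300L > lens[[ch]])
            stop("infeasible packing: genes exceed chromosome ", ch,
                 " (need ", max(genes$end[ix]) + 300L, " bases, have ",
                 lens[[ch]], ")")
    }
    list(genes = genes, chrom_lengths = lens, gene_span = gene_span,
         repeat_block = c(start = 300L, end = 300L + rep_len))
}

#' Simulate a toy reference genome and annotation
#'
#' Uniform-random background sequence with one embedded tandem repeat
#' family, one cluster of near-identical paralogous gene copies, and
#' non-overlapping multi-exon genes; fully deterministic under the spec's
#' seed.
#'
#' @param sp a [fixture_spec()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `features`
#'   (data.frame as from [load_features()], kinds gene/exon/CDS) and
#'   `layout` (per-gene coordinates and class: regular, paralog,
#'   x_male_biased).
#' @export
simulate_reference <- function(sp) {
    lay <- .fixture_layout(sp)
    .substream(sp$seed, "genome")
    seqs <- lapply(lay$chrom_lengths, .rand_dna)
    # tandem repeat family on chrA2
    unit <- .rand_dna(sp$repeat_unit)
    block <- strrep(unit, sp$repeat_copies)
    s2 <- seqs[["chrA2"]]
    substr(s2, lay$repeat_block[["start"]] + 1L,
           lay$repeat_block[["end"]]) <- block
    seqs[["chrA2"]] <- s2
    # paralog cluster: one template gene span copied with divergence
    .substream(sp$seed, "paralogs")
    par <- lay$genes[lay$genes$class == "paralog", , drop = FALSE]
    if (nrow(par)) {
        template <- .rand_dna(lay$gene_span)
        s1 <- seqs[["chrA1"]]
        for (i in seq_len(nrow(par))) {
            copy <- strsplit(template, "")[[1]]
            nmut <- rbinom(1, length(copy), sp$paralog_divergence)
            if (nmut > 0) {
                at <- sample(length(copy), nmut)
                copy[at] <- vapply(copy[at], function(b)
                    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
            }
            substr(s1, par$start[i] + 1L, par$end[i]) <-
                paste(copy, collapse = "")
        }
        seqs[["chrA1"]] <- s1
    }
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(lay$chrom_lengths)
    # exon/CDS features
    feats <- list()
    for (i in seq_len(nrow(lay$genes))) {
        g <- lay$genes[i, ]
        ex_starts <- g$start +
            (seq_len(sp$exons_per_gene) - 1L) *
            (sp$exon_length + sp$intron_length)
        feats[[i]] <- rbind(
            data.frame(chrom = g$chrom, start = g$start, end = g$end,
                       strand = "+", kind = "gene", gene_id = g$gene,
                       stringsAsFactors = FALSE),
            data.frame(chrom = g$chrom, start = ex_starts,
                       end = ex_starts + sp$exon_length, strand = "+",
                       kind = "exon", gene_id = g$gene,
                       stringsAsFactors = FALSE),
            data.frame(chrom = g$chrom, start = ex_starts,
                       end = ex_starts + sp$exon_length, strand = "+",
                       kind = "CDS", gene_id = g$gene,
                       stringsAsFactors = FALSE))
    }
    list(genome = genome, features = do.call(rbind, feats),
         layout = lay$genes)
}

#' Write a simulated reference to FASTA + GFF3
#'
#' @param ref output of [simulate_reference()].
#' @param dir output directory (created if needed).
#' @return Named character vector of paths (`fasta`, `gff3`).
#' @export
write_reference <- function(ref, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    con <- file(fa, "wb")
    for (nm in names(ref$genome)) {
        writeLines(paste0(">", nm), con)
        s <- as.character(ref$genome[[nm]])
        writeLines(substring(s, seq(1, nchar(s), 70),
                             pmin(nchar(s), seq(70, nchar(s) + 69, 70))), con)
    }
    close(con)
    gff <- file.path(dir, "genes.gff3")
    f <- ref$features
    ids <- paste0(tolower(f$kind), ":", f$gene_id, ":", f$start)
    con <- file(gff, "wb")
    writeLines(c("##gff-version 3",
                 paste(f$chrom, "exocap_sim", f$kind, f$start + 1L, f$end,
                       ".", f$strand, ".",
                       paste0("ID=", ids, ";gene_id=", f$gene_id),
                       sep = "\t")), con)
    close(con)
    c(fasta = fa, gff3 = gff)
}

.TI_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

# draw alt alleles for SNVs with the given transition probability
.draw_alts <- function(refs, ti_prob) {
    n <- length(refs)
    is_ti <- runif(n) < ti_prob
    alts <- character(n)
    alts[is_ti] <- .TI_PARTNER[refs[is_ti]]
    if (any(!is_ti))
        alts[!is_ti] <- vapply(refs[!is_ti], function(b)
            sample(.TV_PARTNERS[[b]], 1), "")
    alts
}

# INFO statistics: passing draws by default, per-rule failing draws with
# probability frac; fields outside the type's rule set always pass
.draw_stats <- function(vtype, frac) {
    pass <- c(QD = runif(1, 15, 35), FS = runif(1, 0, 10),
              SOR = runif(1, 0.3, 2.5), MQ = runif(1, 50, 60),
              ReadPosRankSum = runif(1, -2, 2), MQRankSum = runif(1, -2, 2))
    rules <- hard_filter_thresholds()[[if (vtype == "SNV") "snv" else "indel"]]
    fail_range <- list(
        snv = list(QD = c(0, 1.99), FS = c(60.01, 120), SOR = c(3.01, 9),
                   ReadPosRankSum = c(-15, -8.01), MQ = c(0, 39.9),
                   MQRankSum = c(-20, -12.51)),
        indel = list(QD = c(0, 1.99), FS = c(200.01, 400),
                     SOR = c(10.01, 20), ReadPosRankSum = c(-30, -20.01)))
    fr <- fail_range[[if (vtype == "SNV") "snv" else "indel"]]
    for (field in names(rules))
        if (runif(1) < frac)
            pass[[field]] <- runif(1, fr[[field]][1], fr[[field]][2])
    pass
}

#' Simulate a paired platform call set over a reference
#'
#' Places shared sites (common to both platforms) and platform-exclusive
#' singleton sites in the consolidated CDS targets, adds male-only
#' platform-b exclusive sites in designated X genes with allele counts at
#' the configured peak, draws genotypes and hard-filter INFO statistics,
#' and assembles the consequence annotation, sex map and a per-site truth
#' table. Optionally writes `a.vcf`, `b.vcf`, `ann.tsv`, `sex.tsv`,
#' `truth.tsv` to `dir`.
#'
#' @param sp a [fixture_spec()].
#' @param ref output of [simulate_reference()] (regenerated from `sp` when
#'   NULL).
#' @param dir optional output directory.
#' @return List with `sites_a`, `sites_b` (record tables in the
#'   [load_vcf()] layout), `truth`, `annotation`, `sex_map`, `targets`, and
#'   `paths` when `dir` is given.
#' @export
simulate_platform_pair <- function(sp, ref = NULL, dir = NULL) {
    if (is.null(ref)) ref <- simulate_reference(sp)
    targets <- consolidate_targets(
        ref$features[ref$features$kind == "CDS", , drop = FALSE])
    kb <- total_bases(targets) / 1000
    # position pool over all target bases
    pool <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i)
        data.frame(chrom = targets$chrom[i],
                   pos = (targets$start[i] + 1L):targets$end[i],
                   stringsAsFactors = FALSE)))
    .substream(sp$seed, "sites")
    n_ea <- rpois(1, sp$exclusive_rate_a * kb)
    n_eb <- rpois(1, sp$exclusive_rate_b * kb)
    f <- sp$shared_fraction
    n_sh <- if (!is.null(sp$shared_rate)) rpois(1, sp$shared_rate * kb)
            else if (f >= 1) { n_ea <- 0L; n_eb <- 0L; rpois(1, 25 * kb) }
            else round(f / (1 - f) * (n_ea + n_eb))
    # male-only X sites for platform b, in the designated genes' CDS
    mx_genes <- ref$layout$gene[ref$layout$class == "x_male_biased"]
    mx <- NULL
    if (length(mx_genes) && sp$male_x_sites_per_gene > 0) {
        cds <- ref$features[ref$features$kind == "CDS" &
                            ref$features$gene_id %in% mx_genes, , drop = FALSE]
        mx <- do.call(rbind, lapply(mx_genes, function(g) {
            d <- cds[cds$gene_id == g, , drop = FALSE]
            gpool <- unlist(mapply(function(s, e) (s + 1L):e,
                                   d$start, d$end, SIMPLIFY = FALSE))
            data.frame(chrom = d$chrom[1],
                       pos = sort(sample(gpool, sp$male_x_sites_per_gene)),
                       gene = g, stringsAsFactors = FALSE)
        }))
    }
    mx_key <- if (is.null(mx)) character() else paste(mx$chrom, mx$pos)
    pool <- pool[!(paste(pool$chrom, pool$pos) %in% mx_key), , drop = FALSE]
    n_main <- n_sh + n_ea + n_eb
    if (n_main > nrow(pool)) {
        warning("requested ", n_main, " sites but only ", nrow(pool),
                " target bases available; capping")
        n_sh <- round(n_sh * nrow(pool) / n_main)
        n_ea <- round(n_ea * nrow(pool) / n_main)
        n_eb <- round(n_eb * nrow(pool) / n_main)
        n_main <- n_sh + n_ea + n_eb
    }
    picked <- pool[sample(nrow(pool), n_main), , drop = FALSE]
    origin <- rep(c("shared", "error_a", "error_b"), c(n_sh, n_ea, n_eb))
    sites <- data.frame(chrom = picked$chrom, pos = picked$pos,
                        origin = origin, stringsAsFactors = FALSE)
    if (!is.null(mx))
        sites <- rbind(sites, data.frame(chrom = mx$chrom, pos = mx$pos,
                                         origin = "male_x",
                                         stringsAsFactors = FALSE))
    ord <- order(match(sites$chrom, names(ref$genome)), sites$pos)
    sites <- sites[ord, , drop = FALSE]
    n <- nrow(sites)
    # alleles
    .substream(sp$seed, "alleles")
    base_at <- function(chrom, pos, len = 1L)
        substr(as.character(ref$genome[[chrom]]), pos, pos + len - 1L)
    refs1 <- mapply(base_at, sites$chrom, sites$pos, USE.NAMES = FALSE)
    is_indel <- sites$origin != "male_x" & runif(n) < sp$indel_fraction
    sites$ref <- refs1
    sites$alt <- NA_character_
    for (cls in c("shared", "error_a", "error_b", "male_x")) {
        ix <- which(sites$origin == cls & !is_indel)
        if (!length(ix)) next
        p <- if (cls == "shared") sp$ti_prob_common else sp$ti_prob_exclusive
        sites$alt[ix] <- .draw_alts(sites$ref[ix], p)
    }
    ii <- which(is_indel)
    for (i in ii) {
        if (runif(1) < 0.5) { # insertion
            sites$alt[i] <- paste0(sites$ref[i],
                                   .rand_dna(sample(1:3, 1)))
        } else {              # deletion
            L <- sample(2:4, 1)
            sites$ref[i] <- base_at(sites$chrom[i], sites$pos[i], L)
            sites$alt[i] <- substr(sites$ref[i], 1, 1)
        }
    }
    sites$vtype <- ifelse(nchar(sites$ref) == 1 & nchar(sites$alt) == 1,
                          "SNV", "indel")
    # genotypes
    .substream(sp$seed, "genotypes")
    samples <- sprintf("S%02d", seq_len(sp$n_samples))
    males <- samples[seq_len(sp$n_males)]
    dose <- matrix(0L, n, sp$n_samples, dimnames = list(NULL, samples))
    for (i in seq_len(n)) {
        if (sites$origin[i] == "shared") {
            af <- runif(1, 0.05, 0.5)
            dose[i, ] <- rbinom(sp$n_samples, 2, af)
        } else if (sites$origin[i] == "male_x") {
            ac <- min(sp$male_ac_peak, 2L * sp$n_males)
            hom <- max(0L, ac - sp$n_males)
            carriers <- sample(males, min(length(males), ac))
            dose[i, carriers] <- 1L
            if (hom > 0) dose[i, sample(carriers, hom)] <- 2L
        } else {
            dose[i, sample(samples, 1)] <- 1L
        }
    }
    # INFO stats per platform
    .substream(sp$seed, "stats")
    stats_for <- function(in_platform) {
        m <- matrix(NA_real_, n, 6,
                    dimnames = list(NULL, c("QD", "FS", "SOR", "MQ",
                                            "ReadPosRankSum", "MQRankSum")))
        for (i in which(in_platform))
            m[i, ] <- .draw_stats(sites$vtype[i],
                                  sp$filter_fail_fraction)[colnames(m)]
        m
    }
    in_a <- sites$origin %in% c("shared", "error_a")
    in_b <- sites$origin %in% c("shared", "error_b", "male_x")
    st_a <- stats_for(in_a)
    st_b <- stats_for(in_b)
    # annotation: gene assignment from the layout, consequence sampled
    .substream(sp$seed, "annotation")
    gene_of <- function(chrom, pos) {
        g <- ref$layout
        hit <- which(g$chrom == chrom & g$start < pos & pos <= g$end)
        if (length(hit)) g$gene[hit[1]] else ""
    }
    sites$gene <- mapply(gene_of, sites$chrom, sites$pos, USE.NAMES = FALSE)
    cons_pool <- list(
        SNV = list(high = c("stop_gained", "splice_acceptor", "splice_donor",
                            "start_lost", "stop_lost"),
                   moderate = "missense",
                   low = c("synonymous", "splice_region", "3_prime_UTR",
                           "5_prime_UTR")),
        indel = list(high = c("frameshift", "splice_acceptor", "splice_donor"),
                     moderate = c("inframe_deletion", "inframe_insertion"),
                     low = c("splice_region", "3_prime_UTR")))
    imp <- sample(c("high", "moderate", "low"), n, replace = TRUE,
                  prob = c(0.01, 0.30, 0.69))
    sites$impact <- imp
    sites$consequence <- vapply(seq_len(n), function(i) {
        pool_i <- cons_pool[[sites$vtype[i]]][[imp[i]]]
        if (length(pool_i) == 1) pool_i else sample(pool_i, 1)
    }, "")
    # assemble per-platform record tables
    build <- function(in_platform, st) {
        r <- sites[in_platform, c("chrom", "pos", "ref", "alt", "vtype"),
                   drop = FALSE]
        r$biallelic <- TRUE
        for (cn in colnames(st)) r[[cn]] <- st[in_platform, cn]
        for (s in samples) r[[paste0("gt_", s)]] <- dose[in_platform, s]
        rownames(r) <- NULL
        r
    }
    sites_a <- build(in_a, st_a)
    sites_b <- build(in_b, st_b)
    truth <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        ref = sites$ref, alt = sites$alt,
                        class = ifelse(sites$origin == "shared", "common",
                                ifelse(in_a, "exclusive_a", "exclusive_b")),
                        origin = sites$origin, gene = sites$gene,
                        stringsAsFactors = FALSE)
    annotation <- sites[, c("chrom", "pos", "ref", "alt", "gene",
                            "consequence", "impact")]
    rownames(annotation) <- NULL
    sex_map <- data.frame(sample_id = samples,
                          sex = ifelse(samples %in% males, "M", "F"),
                          stringsAsFactors = FALSE)
    out <- list(sites_a = sites_a, sites_b = sites_b, truth = truth,
                annotation = annotation, sex_map = sex_map,
                targets = targets)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        pa <- file.path(dir, "a.vcf"); pb <- file.path(dir, "b.vcf")
        .write_vcf(sites_a, ref$genome, samples, pa)
        .write_vcf(sites_b, ref$genome, samples, pb)
        tsv <- function(d, p) write.table(d, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
        tsv(annotation, file.path(dir, "ann.tsv"))
        tsv(sex_map, file.path(dir, "sex.tsv"))
        tsv(truth, file.path(dir, "truth.tsv"))
        write_bed(targets, file.path(dir, "targets.bed"))
        out$paths <- c(vcf_a = pa, vcf_b = pb,
                       ann = file.path(dir, "ann.tsv"),
                       sex = file.path(dir, "sex.tsv"),
                       truth = file.path(dir, "truth.tsv"),
                       targets = file.path(dir, "targets.bed"))
    }
    out
}

# minimal deterministic VCF 4.2 writer for simulated record tables
.write_vcf <- function(records, genome, samples, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##contig=<ID=", names(genome), ",length=",
                        Biostrings::width(genome), ">"),
                 paste0("##INFO=<ID=", c("QD", "FS", "SOR", "MQ",
                                         "ReadPosRankSum", "MQRankSum"),
                        ",Number=1,Type=Float,Description=\"site stat\">"),
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", samples),
                       collapse = "\t")), con)
    if (nrow(records)) {
        info <- apply(records[, c("QD", "FS", "SOR", "MQ", "ReadPosRankSum",
                                  "MQRankSum")], 1, function(x)
            paste(paste0(names(x), "=", sprintf("%.2f", x)), collapse = ";"))
        gt_str <- sapply(records[, paste0("gt_", samples), drop = FALSE],
                         function(d) c("0/0", "0/1", "1/1")[d + 1L])
        if (is.null(dim(gt_str)))
            gt_str <- matrix(gt_str, nrow = nrow(records))
        writeLines(paste(records$chrom, records$pos, ".", records$ref,
                         records$alt, ".", ".", info, "GT",
                         apply(gt_str, 1, paste, collapse = "\t"),
                         sep = "\t"), con)
    }
    invisible(path)
}
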
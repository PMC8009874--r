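test_that("simulated references are deterministic and structurally correct", {
    sp <- fixture_spec(seed = 11)
    r1 <- simulate_reference(sp)
    r2 <- simulate_reference(sp)
    expect_identical(as.character(r1$genome), as.character(r2$genome))
    expect_identical(r1$features, r2$features)
    # byte-identical files under the same seed
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    p1 <- write_reference(r1, d1); p2 <- write_reference(r2, d2)
    expect_identical(readLines(p1[["fasta"]]), readLines(p2[["fasta"]]))
    expect_identical(readLines(p1[["gff3"]]), readLines(p2[["gff3"]]))
    # a different seed perturbs the genome
    r3 <- simulate_reference(fixture_spec(seed = 12))
    expect_false(identical(as.character(r1$genome),
                           as.character(r3$genome)))
    # genes exist, non-overlapping, on declared chromosomes
    lay <- r1$layout
    expect_equal(nrow(lay), sp$n_genes)
    for (ch in unique(lay$chrom)) {
        g <- lay[lay$chrom == ch, ]
        g <- g[order(g$start), ]
        if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
    expect_equal(sum(lay$class == "x_male_biased"), sp$male_only_x_genes)
    # infeasible packing errors out
    expect_error(simulate_reference(fixture_spec(seed = 1, chrom_length = 900)),
                 "infeasible")
})

test_that("the embedded repeat family saturates the k-mer index", {
    sp <- fixture_spec(seed = 13)
    ref <- simulate_reference(sp)
    idx <- build_kmer_index(ref$genome, 15)
    # 15-mers of the repeat unit occur >= copy number times
    block <- substr(as.character(ref$genome[["chrA2"]]), 301, 300 + 120)
    probe <- substr(block, 1, 50)
    expect_gt(probe_repetitiveness(probe, idx), sp$repeat_copies - 1)
})

test_that("zero-divergence paralogs produce cluster-sized close-match counts", {
    sp <- fixture_spec(seed = 14, paralog_divergence = 0, n_genes = 10,
                       paralog_genes = 3, chrom_length = 8000)
    ref <- simulate_reference(sp)
    par <- ref$layout[ref$layout$class == "paralog", ]
    probe <- substr(as.character(ref$genome[["chrA1"]]),
                    par$start[1] + 101, par$start[1] + 160)
    cm <- count_close_matches(probe, ref$genome, design_params())
    expect_gte(cm, nrow(par))
    expect_equal(cm, oracle_close_match_count(probe, ref$genome))
})

test_that("simulated call sets agree with their truth table and round-trip
           through VCF with identical content", {
    sp <- fixture_spec(seed = 15)
    ref <- simulate_reference(sp)
    d <- withr::local_tempdir()
    sim <- simulate_platform_pair(sp, ref, dir = d)
    # classification recovers the truth exactly (positions non-colliding)
    pair <- classify_shared(sim$sites_a, sim$sites_b)
    truth_a <- sim$truth[sim$truth$class != "exclusive_b", ]
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
    expect_identical(key(pair$a), key(truth_a))
    expect_identical(pair$a$class == "common", truth_a$class == "common")
    truth_b <- sim$truth[sim$truth$class != "exclusive_a", ]
    expect_identical(pair$b$class == "common", truth_b$class == "common")

    # VCF round trip: no warnings, identical records and genotypes
    expect_no_warning(ra <- load_vcf(sim$paths[["vcf_a"]]))
    cols <- c("chrom", "pos", "ref", "alt", "vtype", "biallelic",
              exocap:::.gt_cols(sim$sites_a))
    expect_equal(ra[, cols], sim$sites_a[, cols])
    expect_equal(ra$QD, sim$sites_a$QD, tolerance = 0.005 + 1e-9)

    # rerun under the same seed is byte-identical
    d2 <- withr::local_tempdir()
    simulate_platform_pair(sp, ref, dir = d2)
    for (f in c("a.vcf", "b.vcf", "ann.tsv", "sex.tsv", "truth.tsv"))
        expect_identical(readLines(file.path(d, f)),
                         readLines(file.path(d2, f)))
})

test_that("boundary spec: full sharing yields zero exclusives", {
    sp <- fixture_spec(seed = 16, shared_fraction = 1, exclusive_rate_a = 0,
                       exclusive_rate_b = 0, male_only_x_genes = 0L)
    sim <- simulate_platform_pair(sp)
    pair <- classify_shared(sim$sites_a, sim$sites_b)
    expect_true(all(pair$a$class == "common"))
    expect_true(all(pair$b$class == "common"))
})

test_that("exclusive sites are singletons and male-X sites peak at AC 4", {
    sp <- fixture_spec(seed = 17)
    ref <- simulate_reference(sp)
    sim <- simulate_platform_pair(sp, ref)
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
    tr <- sim$truth
    err_b <- sim$sites_b[key(sim$sites_b) %in%
                         key(tr[tr$origin == "error_b", ]), ]
    expect_true(all(allele_count_spectrum(err_b)$ac == 1))
    mx <- sim$sites_b[key(sim$sites_b) %in%
                      key(tr[tr$origin == "male_x", ]), ]
    expect_true(all(allele_count_spectrum(mx)$ac == sp$male_ac_peak))
    # male-X sites are restricted to the designated genes
    expect_setequal(unique(tr$gene[tr$origin == "male_x"]),
                    ref$layout$gene[ref$layout$class == "x_male_biased"])
})

test_that("male-only X variants dominate sex fold change and platform bias
           when the shared background is sparse", {
    # low shared background so the engineered male-only signal (15 sites per
    # gene, all four males carriers) more than doubles the male mean
    sp <- fixture_spec(seed = 19, shared_rate = 20)
    ref <- simulate_reference(sp)
    sim <- simulate_platform_pair(sp, ref)
    pair <- classify_shared(sim$sites_a, sim$sites_b)
    m <- per_gene_counts(pair, sim$annotation, features = ref$features)
    truth_genes <- sort(ref$layout$gene[ref$layout$class == "x_male_biased"])
    sb <- sex_bias_per_gene(m, sim$sex_map)
    expect_setequal(sb$gene[!is.na(sb$fold_b) & sb$fold_b > 1], truth_genes)
    # the extra sites are platform-b exclusive, so the same genes head the
    # platform-bias outlier list
    pb <- platform_bias(m, n_top = length(truth_genes))
    expect_setequal(pb$outliers$gene, truth_genes)
    # and the X shows a large male-vs-female percentage difference
    sm <- sex_difference_summary(m, sim$sex_map, x_chrom = "chrX")
    xb <- sm[sm$platform == "WGS" & sm$chrom_class == "X", ]
    expect_gt(xb$pct_of_male, 50)
})

test_that("injected filter failures recover their configured fraction", {
    sp <- fixture_spec(seed = 18, chrom_length = 30000, n_genes = 45,
                       shared_rate = 60, filter_fail_fraction = 0.05)
    sim <- simulate_platform_pair(sp)
    f <- apply_hard_filters(sim$sites_a)
    rc <- attr(f, "rule_counts")
    n_snv <- sum(f$vtype == "SNV")
    frac <- 0.05
    se <- sqrt(frac * (1 - frac) / n_snv)
    for (rule in grep("^snv", names(rc), value = TRUE))
        expect_lt(abs(rc[[rule]] / n_snv - frac), 3 * se + 1e-9)
})
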
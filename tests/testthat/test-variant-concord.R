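test_that("load_vcf types records and extracts stats and genotypes", {
    vcf <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=c1,length=1000>",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"x\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
        "c1\t10\t.\tA\tG\t.\t.\tQD=25.0\tGT\t0/1\t0/0",
        "c1\t20\t.\tA\tG,T\t.\t.\tQD=12.0\tGT\t1/2\t0/0",
        "c1\t30\t.\tAT\tA\t.\t.\t.\tGT\t1/1\t./.",
        "c1\t40\t.\tC\tCGG\t.\t.\tQD=9.0\tGT\t0/1\t0/1"), vcf)
    r <- load_vcf(vcf)
    expect_equal(r$vtype, c("SNV", "other", "indel", "indel"))
    expect_equal(r$biallelic, c(TRUE, FALSE, TRUE, TRUE))
    expect_equal(r$QD, c(25, 12, NA, 9))
    expect_true(all(is.na(r$FS)))
    expect_equal(r$gt_S1, c(1L, 1L, 2L, 1L))  # "1/2" carries one allele-1 copy
    expect_equal(r$gt_S2, c(0L, 0L, NA, 1L))
    r1 <- load_vcf(vcf, sample_subset = "S2")
    expect_equal(exocap:::.gt_cols(r1), "gt_S2")
    expect_error(load_vcf(vcf, sample_subset = "S9"), "not in VCF")
})

test_that("hard filters fail on any type-appropriate rule; missing stats pass", {
    p <- make_records("c1", c(10, 20, 30, 40, 50),
                      ref = c("A", "A", "A", "AT", "A"),
                      alt = c("G", "G", "G", "A", "G"),
                      QD = c(1.9, 25, 25, 25, NA),
                      FS = c(1, 100, 1, 250, NA))
    f <- apply_hard_filters(p)
    # SNV with QD = 1.9 fails QD < 2
    expect_false(f$filter_pass[1])
    # SNV with FS = 100 fails the SNV rule (FS > 60) ...
    expect_false(f$filter_pass[2])
    # ... but an indel with FS = 250 fails only the indel rule (FS > 200)
    expect_false(f$filter_pass[4])
    # clean SNV passes; all-missing stats pass
    expect_true(f$filter_pass[3])
    expect_true(f$filter_pass[5])
    # the same FS = 100 under indel thresholds would pass
    ind <- make_records("c1", 60, "AT", "A", FS = 100)
    expect_true(apply_hard_filters(ind)$filter_pass)
    expect_match(f$fail_reasons[1], "QD<2")
})

test_that("target restriction trims a 2-base flank zone by default", {
    targets <- consolidate_targets(
        data.frame(chrom = "c1", start = 100L, end = 200L, gene_id = "g"))
    r <- make_records("c1", c(150, 103, 198, 102, 199, 250), "A", "G")
    kept <- restrict_to_targets(r, targets)
    # center and trimmed-interior edges kept; 2-base flank zones removed
    expect_equal(kept$pos, c(150L, 103L, 198L))
    kept0 <- restrict_to_targets(r, targets, flank_trim = 0)
    expect_equal(kept0$pos, c(150L, 103L, 198L, 102L, 199L))
    # flank_trim = 0 keeps a superset of flank_trim = 2
    expect_true(all(kept$pos %in% kept0$pos))
})

test_that("classification matches on exact alleles and is symmetric", {
    a <- make_records("c1", c(10, 20, 30), c("A", "A", "C"), c("G", "G", "T"))
    b <- make_records("c1", c(10, 20, 40), c("A", "A", "C"), c("G", "T", "T"))
    pair <- classify_shared(a, b)
    expect_equal(pair$a$class, c("common", "exclusive", "exclusive"))
    expect_equal(pair$b$class, c("common", "exclusive", "exclusive"))
    # swap platforms: exclusives swap, common set identical
    swapped <- classify_shared(b, a)
    expect_equal(swapped$a$class, pair$b$class)
    expect_equal(swapped$b$class, pair$a$class)
    common_ab <- pair$a[pair$a$class == "common", c("chrom", "pos", "ref", "alt")]
    common_ba <- swapped$b[swapped$b$class == "common",
                           c("chrom", "pos", "ref", "alt")]
    expect_equal(common_ab, common_ba)
})

test_that("Ti/Tv follows the transition definition and the sampling oracle", {
    r <- make_records("c1", 1:4, c("A", "C", "G", "A"), c("G", "T", "A", "C"))
    expect_equal(titv_ratio(r), 3.0)
    tv_only <- make_records("c1", 1:4, c("A", "A", "G", "G"),
                            c("C", "T", "C", "T"))
    expect_equal(titv_ratio(tv_only), 0.0)
    ti_only <- make_records("c1", 1:2, c("A", "C"), c("G", "T"))
    expect_message(res <- titv_ratio(ti_only), "undefined")
    expect_true(is.na(res))

    # binomial sampling oracle: p = 0.797 -> ratio 3.92 within 3 s.e.
    set.seed(401)
    n <- 10000
    is_ti <- runif(n) < 0.797
    refs <- sample(c("A", "C", "G", "T"), n, TRUE)
    ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
    tv_partner <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
    alts <- ifelse(is_ti, ti_partner[refs],
                   vapply(refs, function(b) sample(tv_partner[[b]], 1), ""))
    r <- make_records("c1", seq_len(n), refs, alts)
    se_p <- sqrt(0.797 * 0.203 / n)
    se_ratio <- se_p / (1 - 0.797)^2    # delta method on p/(1-p)
    expect_lt(abs(titv_ratio(r) - 3.92), 3 * se_ratio)
})

test_that("allele-count spectrum counts alt alleles over samples", {
    gt <- rbind(c(1L, 0L, 0L), c(2L, 0L, 0L), c(1L, 1L, 2L), c(0L, 0L, 0L))
    colnames(gt) <- c("S1", "S2", "S3")
    r <- make_records("c1", 1:4, "A", "G", gt = gt)
    sp <- allele_count_spectrum(r)
    expect_equal(sp$spectrum, c(`1` = 1L, `2` = 1L, `4` = 1L))
    expect_equal(sp$n_ac0, 1L)
    # conservation: histogram total equals number of AC >= 1 sites
    expect_equal(sum(sp$spectrum), sum(sp$ac >= 1))
})

test_that("consequence tables reproduce published worked-example rows", {
    # high-impact SNVs: 569 common + 13 exclusive -> 97.8% / 2.2%
    pc <- concordance_pct(569, 13)
    expect_equal(pc$total, 582)
    expect_equal(pc$pct_common, 97.8)
    expect_equal(pc$pct_exclusive, 2.2)
    # platform overall: 143745 common of 145939 -> 98.5%
    expect_equal(concordance_pct(143745, 2194)$pct_common, 98.5)

    # full table construction on a small pair
    a <- make_records("c1", 1:6, "A", "G")
    a$filter_pass <- TRUE
    b <- make_records("c1", c(1:4, 10, 11), "A", "G")
    b$filter_pass <- TRUE
    ann <- data.frame(chrom = "c1", pos = c(1:6, 10, 11), ref = "A",
                      alt = "G", gene = "g1",
                      consequence = c("missense", "missense", "synonymous",
                                      "synonymous", "stop_gained",
                                      "stop_gained", "missense", "missense"),
                      impact = c("moderate", "moderate", "low", "low", "high",
                                 "high", "moderate", "moderate"),
                      stringsAsFactors = FALSE)
    pair <- classify_shared(a, b)
    tab <- consequence_table(pair, ann, vtype = "SNV")
    expect_true(all(tab$common + tab$exclusive == tab$total))
    expect_true(all(abs(tab$pct_common + tab$pct_exclusive - 100) <= 0.1))
    wes_missense <- tab[tab$platform == "WES" & tab$consequence == "missense", ]
    expect_equal(c(wes_missense$common, wes_missense$exclusive), c(2L, 0L))
    wes_all <- tab[tab$platform == "WES" & tab$impact == "All", ]
    expect_equal(wes_all$total, 6L)
    # records with no annotation are excluded
    a2 <- make_records("c1", c(1, 99), "A", "G")
    a2$filter_pass <- TRUE
    pair2 <- classify_shared(a2, b)
    tab2 <- consequence_table(pair2, ann, vtype = "SNV")
    expect_equal(tab2[tab2$platform == "WES" & tab2$impact == "All", "total"], 1L)
})
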
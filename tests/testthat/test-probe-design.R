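# small deterministic genome with one gene-sized target
setup_design <- function(seed = 301, n = 3000) {
    set.seed(seed)
    g <- Biostrings::DNAStringSet(c(c1 = rand_dna(n)))
    g
}

test_that("tiling enumerates starts and lengths within the flank bounds", {
    g <- setup_design()
    p <- design_params(probe_len_min = 50, probe_len_max = 50,
                       probe_len_step = 10)
    tgt <- region_df("c1", 100, 150)
    cands <- tile_candidates(tgt, g, p)
    # starts 70, 75, ..., 130 -> 13 candidates
    expect_equal(nrow(cands), 13L)
    expect_equal(cands$start, seq(70L, 130L, 5L))
    expect_true(all(nchar(cands$sequence) == 50L))

    # 10-base target: 70-base span, 5 starts
    cands2 <- tile_candidates(region_df("c1", 500, 510), g, p)
    expect_equal(nrow(cands2), 5L)
    expect_equal(cands2$start, seq(470L, 490L, 5L))

    # too small with no flanks -> empty with warning
    p0 <- design_params(flank_allowance = 0)
    expect_warning(c3 <- tile_candidates(region_df("c1", 500, 540), g, p0),
                   "shorter than minimum")
    expect_equal(nrow(c3), 0L)

    # multiple lengths enumerated per start
    p2 <- design_params()
    cands4 <- tile_candidates(region_df("c1", 1000, 1200), g, p2)
    expect_setequal(unique(cands4$length), seq(50L, 100L, 10L))
    expect_true(all(cands4$start >= 970L))
    expect_true(all(cands4$start + cands4$length <= 1230L))
})

test_that("probe score has the stated closed form and monotonicity", {
    p <- design_params()
    # unique on-target probe: only the repetitiveness term remains
    expect_equal(probe_score(1, 1, p$tm_target, 0, p), log10(2))
    # more close matches score worse
    expect_lt(probe_score(1, 1, p$tm_target, 0, p),
              probe_score(1, 3, p$tm_target, 0, p))
    # Tm deviation is weighted by 0.2 by default
    expect_equal(probe_score(1, 1, p$tm_target + 10, 0, p),
                 log10(2) + 0.2 * 10)
    expect_error(probe_score(NA, 1, 70, 0, p), "unscored")
})

test_that("eligibility flags follow the thresholds and selection skips them", {
    g <- setup_design(seed = 302)
    p <- design_params()
    idx <- build_kmer_index(g, p$k)
    tgt <- region_df("c1", 1000, 1050)
    cands <- tile_candidates(tgt, g, p)
    scored <- exocap:::.score_candidates(cands, g, idx, p)
    expect_true(all(scored$repetitive == (scored$repetitiveness > 100)))
    expect_true(all(scored$nonunique[!scored$repetitive] ==
                    (scored$close_matches[!scored$repetitive] > 5)))
    expect_true(all(scored$passed == (!scored$repetitive & !scored$nonunique)))
    # random-genome probes are unique: all eligible
    expect_true(all(scored$passed))

    # raising thresholds never decreases eligibility
    stricter <- sum(scored$repetitiveness <= 1 & scored$close_matches <= 1)
    expect_lte(stricter, sum(scored$passed))
})

test_that("windowed selection walks the span and applies the tie rule", {
    g <- setup_design(seed = 303)
    p <- design_params()
    idx <- build_kmer_index(g, p$k)
    # 200-base target, flank 30 -> windows at offsets 0, 40, ..., 240: 7
    tgt <- region_df("c1", 1000, 1200)
    cands <- exocap:::.score_candidates(tile_candidates(tgt, g, p), g, idx, p)
    res <- select_probes(tgt, cands, p)
    expect_equal(res$log$n_windows, 7L)
    expect_lte(nrow(res$probes), 7L)
    expect_gte(nrow(res$probes), 1L)
    # flank bounds: probes stay within [start - 30, end + 30)
    expect_true(all(res$probes$start >= 1000 - 30))
    expect_true(all(res$probes$start + res$probes$length <= 1200 + 30))

    # equal scores -> leftmost start, then shortest length wins
    fake <- cands
    fake$score[fake$passed] <- 1
    res2 <- select_probes(tgt, fake, p)
    first_win <- fake[fake$passed & fake$start < (1000 - 30 + p$window_len), ]
    expect_equal(res2$probes$start[1], min(first_win$start))
    expect_equal(res2$probes$length[1],
                 min(first_win$length[first_win$start == min(first_win$start)]))

    # all candidates ineligible -> zero probes, logged
    none <- cands
    none$passed <- FALSE
    res3 <- select_probes(tgt, none, p)
    expect_equal(nrow(res3$probes), 0L)
    expect_equal(res3$log$n_selected, 0L)
})

test_that("coverage report classifies direct, indirect and uncovered bases", {
    targets <- consolidate_targets(
        data.frame(chrom = "c1", start = 100L, end = 150L, gene_id = "g1"))
    probe_exact <- data.frame(chrom = "c1", start = 100L, length = 50L)
    cov <- coverage_report(probe_exact, targets, indirect_reach = 100)
    expect_equal(c(cov$direct_bases, cov$indirect_bases, cov$uncovered_bases),
                 c(50L, 0L, 0L))

    # probe ends 10 bases short of the target end -> 10 indirect bases
    probe_short <- data.frame(chrom = "c1", start = 90L, length = 50L)
    cov2 <- coverage_report(probe_short, targets, indirect_reach = 100)
    expect_equal(c(cov2$direct_bases, cov2$indirect_bases), c(40L, 10L))

    # no probes -> everything uncovered
    cov3 <- coverage_report(probe_exact[0, ], targets)
    expect_equal(cov3$uncovered_bases, 50L)

    # partition always sums to the total
    expect_equal(cov2$direct_bases + cov2$indirect_bases +
                 cov2$uncovered_bases, total_bases(targets))
})

test_that("design_exome covers unique exons, skips repetitive ones, and is
           deterministic", {
    set.seed(304)
    unit <- rand_dna(60)
    left <- rand_dna(600)
    genome <- Biostrings::DNAStringSet(c(
        c1 = paste0(left, strrep(unit, 150), rand_dna(600))))
    # one unique exon in the left flank, one exon inside the repeat block
    feats <- data.frame(chrom = "c1", start = c(200L, 650L + 4000L),
                        end = c(300L, 650L + 4100L), strand = "+",
                        kind = "CDS", gene_id = c("gU", "gR"),
                        stringsAsFactors = FALSE)
    ps <- design_exome(genome, feats, design_params())
    by_tgt <- ps$selection_log
    expect_gte(by_tgt$n_selected[by_tgt$start == 200], 1L)
    expect_equal(by_tgt$n_selected[by_tgt$start == 4650], 0L)
    # every selected probe is eligible and within flank bounds
    expect_true(all(ps$probes$passed))
    # rerun is byte-identical
    d1 <- withr::local_tempdir()
    write_probe_set(ps, file.path(d1, "run1"))
    ps2 <- design_exome(genome, feats, design_params())
    write_probe_set(ps2, file.path(d1, "run2"))
    for (suffix in c(".probes.bed", ".probes.fasta", ".targets.bed",
                     ".coverage.tsv", ".design.log"))
        expect_identical(readLines(file.path(d1, paste0("run1", suffix))),
                         readLines(file.path(d1, paste0("run2", suffix))))
    # empty annotation -> empty design
    ps0 <- design_exome(genome, feats[0, ], design_params())
    expect_equal(nrow(ps0$probes), 0L)
    expect_equal(ps0$coverage$total_bases, 0L)
})

test_that("windowed cover implies direct or indirect coverage when the reach
           spans the window advance", {
    g <- setup_design(seed = 305, n = 4000)
    p <- design_params()
    feats <- data.frame(chrom = "c1", start = c(500L, 1500L, 2500L),
                        end = c(650L, 1750L, 2590L), strand = "+",
                        kind = "CDS", gene_id = c("g1", "g2", "g3"),
                        stringsAsFactors = FALSE)
    ps <- design_exome(g, feats, p)
    # random genome: everything eligible, so with reach >= window advance the
    # whole target should be directly or indirectly covered
    expect_gte(p$indirect_reach, p$window_advance)
    expect_equal(ps$coverage$uncovered_bases, 0L)
})
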
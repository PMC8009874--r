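#' Probe design parameters
#'
#' Bundles every tunable constant of the capture design algorithm. Defaults
#' reproduce the published design recipe: 15-mer repetitiveness with a mean
#' count cutoff of 100, close matches defined as 30 bases with up to 5
#' edits and at most 5 genome-wide placements, probes of 50-100 bases tiled
#' at a 5-base step, scoring up to 4 probes per 20-base window with the
#' window advanced 40 bases, and probes allowed to start/end up to 30 bases
#' outside the target.
#'
#' @param k k-mer length for the repetitiveness index (bases).
#' @param repetitive_threshold mean k-mer count above which a probe is
#'   flagged repetitive and excluded.
#' @param close_match_len length of the approximate-match window (bases).
#' @param close_match_max_edits maximum insertions/deletions/substitutions
#'   allowed in a close match.
#' @param max_close_matches maximum genome-wide close-match loci allowed for
#'   an eligible probe (the probe's own origin locus counts when
#'   `count_origin_locus` is `TRUE`).
#' @param probe_len_min,probe_len_max,probe_len_step candidate probe lengths
#'   enumerated per start position: `seq(probe_len_min, probe_len_max,
#'   probe_len_step)`. The default step of 10 trades exhaustive length
#'   enumeration for speed; set `probe_len_step = 5` (or 1) for a denser
#'   grid.
#' @param tile_step spacing of candidate start positions (bases).
#' @param window_len selection window length (bases).
#' @param window_advance how far the selection window moves between rounds.
#' @param probes_per_window number of lowest-scoring candidates shortlisted
#'   per window before the single best is chosen (1-4).
#' @param flank_allowance how far a probe may start before the target's 5'
#'   end or extend past its 3' end (bases).
#' @param tm_target target melting temperature (degrees C) used in scoring.
#' @param score_weights named numeric weights `rep`, `uni`, `tm`, `comp` for
#'   the four score components.
#' @param w_gc,w_homo weights of the GC-deviation and homopolymer-excess
#'   terms of the composition penalty.
#' @param canonical_kmers count k-mers in canonical (strand-collapsed) form;
#'   set `FALSE` for forward-strand-only counting.
#' @param count_origin_locus whether a probe's own genomic locus counts
#'   toward `max_close_matches`.
#' @param indirect_reach distance (bases) from a probe terminus within which
#'   an uncovered target base is reported as indirectly covered.
#' @return An object of class `design_params` (a validated list).
#' @export
design_params <- function(k = 15L,
                          repetitive_threshold = 100,
                          close_match_len = 30L,
                          close_match_max_edits = 5L,
                          max_close_matches = 5L,
                          probe_len_min = 50L,
                          probe_len_max = 100L,
                          probe_len_step = 10L,
                          tile_step = 5L,
                          window_len = 20L,
                          window_advance = 40L,
                          probes_per_window = 4L,
                          flank_allowance = 30L,
                          tm_target = 75,
                          score_weights = c(rep = 1, uni = 1, tm = 0.2, comp = 1),
                          w_gc = 1,
                          w_homo = 0.1,
                          canonical_kmers = TRUE,
                          count_origin_locus = TRUE,
                          indirect_reach = 100L) {
    p <- list(k = as.integer(k),
              repetitive_threshold = repetitive_threshold,
              close_match_len = as.integer(close_match_len),
              close_match_max_edits = as.integer(close_match_max_edits),
              max_close_matches = as.integer(max_close_matches),
              probe_len_min = as.integer(probe_len_min),
              probe_len_max = as.integer(probe_len_max),
              probe_len_step = as.integer(probe_len_step),
              tile_step = as.integer(tile_step),
              window_len = as.integer(window_len),
              window_advance = as.integer(window_advance),
              probes_per_window = as.integer(probes_per_window),
              flank_allowance = as.integer(flank_allowance),
              tm_target = tm_target,
              score_weights = score_weights,
              w_gc = w_gc, w_homo = w_homo,
              canonical_kmers = isTRUE(canonical_kmers),
              count_origin_locus = isTRUE(count_origin_locus),
              indirect_reach = as.integer(indirect_reach))
    stopifnot(p$k >= 1L,
              p$probe_len_min <= p$probe_len_max,
              p$probe_len_min >= 1L,
              p$probe_len_step >= 1L,
              p$tile_step >= 1L,
              p$window_len >= 1L,
              p$window_advance >= 1L,
              p$probes_per_window >= 1L, p$probes_per_window <= 4L,
              p$flank_allowance >= 0L,
              p$close_match_len >= 1L,
              p$close_match_max_edits >= 0L,
              all(c("rep", "uni", "tm", "comp") %in% names(p$score_weights)))
    class(p) <- "design_params"
    p
}

#' @export
print.design_params <- function(x, ...) {
    cat("Probe design parameters:\n")
    for (nm in setdiff(names(x), "score_weights"))
        cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ",")))
    cat(sprintf("  %-22s %s\n", "score_weights",
                paste(sprintf("%s=%g", names(x$score_weights),
                              x$score_weights), collapse = " ")))
    invisible(x)
}
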
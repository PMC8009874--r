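# Nearest-neighbor duplex thermodynamics (unified parameter set,
# SantaLucia PNAS 1998): dH in kcal/mol, dS in cal/(mol K).
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

#' Melting temperature of a probe (nearest-neighbor model)
#'
#' Duplex melting temperature from nearest-neighbor thermodynamics with the
#' unified DNA parameter set, entropic salt correction
#' `0.368 * (N - 1) * ln([Na+])`, and the two-state formula
#' `Tm = 1000 * dH / (dS + R * ln(CT/4)) - 273.15` for non-self-
#' complementary duplexes with equal strand concentrations (`CT/4`
#' equals half the per-strand concentration).
#'
#' @param seq DNA sequence over {A,C,G,T} (single string, length >= 2).
#' @param na_molar monovalent cation concentration in mol/L (default
#'   0.05, i.e. 50 mM).
#' @param strand_conc per-strand concentration in mol/L (default 2.5e-10,
#'   i.e. 250 pM).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, na_molar = 0.05, strand_conc = 2.5e-10) {
    seq <- toupper(seq)
    n <- nchar(seq)
    if (n < 2) stop("sequence must have at least 2 bases")
    if (grepl("[^ACGT]", seq))
        stop("sequence contains bases outside {A,C,G,T}")
    steps <- substring(seq, 1:(n - 1L), 2:n)
    first <- substr(seq, 1, 1); last <- substr(seq, n, n)
    dH <- sum(.NN_DH[steps]) + .INIT_DH[[first]] + .INIT_DH[[last]]
    dS <- sum(.NN_DS[steps]) + .INIT_DS[[first]] + .INIT_DS[[last]]
    dS <- dS + 0.368 * (n - 1) * log(na_molar)
    R <- 1.987
    1000 * dH / (dS + R * log(strand_conc / 2)) - 273.15
}

#' Sequence composition penalty
#'
#' Penalises deviation from balanced base composition and long
#' homopolymer runs:
#' `w_gc * |GC - 0.5| + w_homo * max(0, longest_homopolymer - 5)`.
#' Both terms are invariant under reverse complement.
#'
#' @param seq DNA sequence over {A,C,G,T}.
#' @param w_gc,w_homo term weights (defaults from [design_params()]).
#' @return Non-negative penalty.
#' @export
composition_penalty <- function(seq, w_gc = 1, w_homo = 0.1) {
    seq <- toupper(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    gc <- mean(ch %in% c("G", "C"))
    runmax <- max(rle(ch)$lengths)
    w_gc * abs(gc - 0.5) + w_homo * max(0, runmax - 5)
}
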
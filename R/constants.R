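# Monoisotopic mass constants (Da). Isotope deltas are the standard
# 13C-12C, 15N-14N and 2H-1H mass differences; label deltas below are
# derived from them and can be overridden through silac_scheme().
PROTON_MASS <- 1.0072765
WATER_MONO <- 18.0105646
C13_DELTA <- 1.0033548
N15_DELTA <- 0.9970349
H2_DELTA <- 1.0062767

# Standard monoisotopic residue masses for the 20 proteinogenic amino acids.
RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Three-plex SILAC label scheme
#'
#' Mass shifts per labelled residue for the K0R0 (light), K4R6 (medium) and
#' K8R10 (heavy) channels. `lys_delta`/`arg_delta` are the monoisotopic mass
#' added to each Lys/Arg; `pro_delta` is the shift a proline inherits when
#' labelled arginine is metabolically converted to proline (13C5 for the
#' medium channel, 13C5 15N1 for the heavy channel), used to search for
#' Arg-to-Pro satellite peaks.
#'
#' K4 is 2H4-Lys, K8 is 13C6 15N2-Lys, R6 is 13C6-Arg and R10 is
#' 13C6 15N4-Arg, so e.g. `R10 = 6 * 1.0033548 + 4 * 0.9970349`.
#'
#' @return A tibble with columns `channel`, `lys_delta`, `arg_delta`,
#'   `pro_delta` (all Da).
#' @export
#' @examples
#' silac_scheme()
silac_scheme <- function() {
  tibble::tibble(
    channel = c("light", "medium", "heavy"),
    lys_delta = c(0, 4 * H2_DELTA, 6 * C13_DELTA + 2 * N15_DELTA),
    arg_delta = c(0, 6 * C13_DELTA, 6 * C13_DELTA + 4 * N15_DELTA),
    pro_delta = c(0, 5 * C13_DELTA, 5 * C13_DELTA + 1 * N15_DELTA)
  )
}

scheme_row <- function(channel, scheme = silac_scheme()) {
  channel <- match.arg(channel, scheme$channel)
  scheme[scheme$channel == channel, , drop = FALSE]
}
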
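#' Describe a peptide for label-mass arithmetic
#'
#' Parses an uppercase single-letter amino-acid sequence and counts the
#' residues that matter for SILAC mass logic: lysines and arginines (which
#' carry the label) and prolines (which can inherit label through
#' Arg-to-Pro conversion).
#'
#' @param sequence Character vector of peptide sequences (uppercase
#'   single-letter codes).
#' @param charge Integer vector of charge states (recycled), `>= 1`.
#' @return A tibble with columns `sequence`, `charge`, `length`, `n_lys`,
#'   `n_arg`, `n_pro`.
#' @export
#' @examples
#' peptide_spec("GVVDSEDLPLNISR", charge = 1)
peptide_spec <- function(sequence, charge = 2L) {
  stopifnot(is.character(sequence), length(sequence) >= 1)
  charge <- vctrs_recycle_int(charge, length(sequence), "charge")
  if (any(charge < 1)) abort("`charge` must be >= 1.")
  bad <- stringr::str_detect(sequence, sprintf("[^%s]", paste(names(RESIDUE_MONO), collapse = "")))
  if (any(bad)) {
    abort(sprintf(
      "invalid sequence(s) with non-amino-acid characters: %s",
      paste(sequence[bad], collapse = ", ")
    ))
  }
  tibble::tibble(
    sequence = sequence,
    charge = charge,
    length = nchar(sequence),
    n_lys = stringr::str_count(sequence, "K"),
    n_arg = stringr::str_count(sequence, "R"),
    n_pro = stringr::str_count(sequence, "P")
  )
}

vctrs_recycle_int <- function(x, n, name) {
  x <- as.integer(x)
  if (length(x) == 1) x <- rep(x, n)
  if (length(x) != n) abort(sprintf("`%s` must have length 1 or %d.", name, n))
  x
}

#' Label mass shift of a peptide in a given channel
#'
#' Total monoisotopic mass added to a peptide by the channel's Lys/Arg
#' labels: `n_lys * lys_delta + n_arg * arg_delta`. The light channel shifts
#' by exactly 0.
#'
#' @param spec A tibble from [peptide_spec()] (one or more rows).
#' @param channel One of `"light"`, `"medium"`, `"heavy"`.
#' @param scheme Label scheme, see [silac_scheme()].
#' @return Numeric vector of mass shifts (Da), one per row of `spec`.
#' @export
#' @examples
#' channel_mass_shift(peptide_spec("GVVDSEDLPLNISR"), "medium")
channel_mass_shift <- function(spec, channel, scheme = silac_scheme()) {
  row <- scheme_row(channel, scheme)
  spec$n_lys * row$lys_delta + spec$n_arg * row$arg_delta
}

#' Neutral monoisotopic mass and m/z of a peptide in a channel
#'
#' Mass convention: m/z = (neutral monoisotopic mass + charge * proton) /
#' charge, with the neutral mass the sum of residue masses plus water plus
#' the channel label shift.
#'
#' @inheritParams channel_mass_shift
#' @return Numeric vector of m/z values (Th).
#' @export
peptide_mz <- function(spec, channel = "light", scheme = silac_scheme()) {
  residue_mass <- vapply(
    strsplit(spec$sequence, ""),
    function(aa) sum(RESIDUE_MONO[aa]),
    numeric(1)
  )
  neutral <- residue_mass + WATER_MONO + channel_mass_shift(spec, channel, scheme)
  (neutral + spec$charge * PROTON_MASS) / spec$charge
}

#' Expected m/z spacing between two label channels
#'
#' The m/z distance between the two isotopic forms of a peptide:
#' `(shift(heavier) - shift(lighter)) / charge`. Identical channels give 0.
#'
#' @inheritParams channel_mass_shift
#' @param channel_pair Character vector of two channel names.
#' @return Numeric vector of spacings (Th), one per row of `spec`.
#' @export
#' @examples
#' expected_mz_spacing(peptide_spec("VNQIGSVTESLQACK", 2), c("light", "medium"))
expected_mz_spacing <- function(spec, channel_pair, scheme = silac_scheme()) {
  stopifnot(length(channel_pair) == 2)
  s1 <- channel_mass_shift(spec, channel_pair[1], scheme)
  s2 <- channel_mass_shift(spec, channel_pair[2], scheme)
  abs(s2 - s1) / spec$charge
}

#' Detect light/medium/heavy triplets in a centroided peak list
#'
#' Scans a peak list for triplets of peaks spaced by the expected
#' medium-light and heavy-light m/z shifts of the peptide at its charge.
#' Every candidate whose two spacings both fall within `tolerance_ppm` of
#' the expectation (ppm relative to the expected partner m/z) is scored by
#' the combined absolute ppm error; overlapping candidates are resolved
#' greedily, smallest combined error first, with each peak used at most
#' once.
#'
#' @param peaks A tibble/data frame with columns `mz` (ascending) and
#'   `intensity`.
#' @param spec One-row tibble from [peptide_spec()].
#' @param tolerance_ppm Mass tolerance in parts per million (> 0).
#' @param scheme Label scheme, see [silac_scheme()].
#' @return A tibble with one row per triplet, columns `light_mz`,
#'   `medium_mz`, `heavy_mz`, `light_int`, `medium_int`, `heavy_int`,
#'   `charge`, `mass_error_ppm` (largest per-channel deviation), sorted by
#'   `light_mz`.
#' @export
detect_triplets <- function(peaks, spec, tolerance_ppm = 10, scheme = silac_scheme()) {
  stopifnot(nrow(spec) == 1, tolerance_ppm > 0)
  peaks <- validate_peaklist(peaks)
  empty <- tibble::tibble(
    light_mz = numeric(), medium_mz = numeric(), heavy_mz = numeric(),
    light_int = numeric(), medium_int = numeric(), heavy_int = numeric(),
    charge = integer(), mass_error_ppm = numeric()
  )
  if (nrow(peaks) < 3) return(empty)

  d_m <- expected_mz_spacing(spec, c("light", "medium"), scheme)
  d_h <- expected_mz_spacing(spec, c("light", "heavy"), scheme)

  cands <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    exp_m <- peaks$mz[i] + d_m
    exp_h <- peaks$mz[i] + d_h
    ppm_m <- (peaks$mz - exp_m) / exp_m * 1e6
    ppm_h <- (peaks$mz - exp_h) / exp_h * 1e6
    j <- which(abs(ppm_m) <= tolerance_ppm)
    k <- which(abs(ppm_h) <= tolerance_ppm)
    if (!length(j) || !length(k)) return(NULL)
    grid <- expand.grid(j = j, k = k)
    tibble::tibble(
      i = i, j = grid$j, k = grid$k,
      err = abs(ppm_m[grid$j]) + abs(ppm_h[grid$k]),
      max_err = pmax(abs(ppm_m[grid$j]), abs(ppm_h[grid$k]))
    )
  })
  if (!nrow(cands)) return(empty)

  cands <- dplyr::arrange(cands, .data$err)
  used <- logical(nrow(peaks))
  keep <- logical(nrow(cands))
  for (r in seq_len(nrow(cands))) {
    idx <- c(cands$i[r], cands$j[r], cands$k[r])
    if (!any(used[idx])) {
      keep[r] <- TRUE
      used[idx] <- TRUE
    }
  }
  cands <- cands[keep, , drop = FALSE]
  out <- tibble::tibble(
    light_mz = peaks$mz[cands$i],
    medium_mz = peaks$mz[cands$j],
    heavy_mz = peaks$mz[cands$k],
    light_int = peaks$intensity[cands$i],
    medium_int = peaks$intensity[cands$j],
    heavy_int = peaks$intensity[cands$k],
    charge = spec$charge,
    mass_error_ppm = cands$max_err
  )
  dplyr::arrange(out, .data$light_mz)
}

validate_peaklist <- function(peaks) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) == 0) return(tibble::as_tibble(peaks[, c("mz", "intensity")]))
  if (is.unsorted(peaks$mz, strictly = FALSE)) {
    abort("`peaks$mz` must be sorted ascending.")
  }
  if (any(peaks$intensity < 0)) abort("peak intensities must be >= 0.")
  tibble::as_tibble(peaks[, c("mz", "intensity")])
}

#' Label incorporation efficiency
#'
#' Fraction of a peptide's signal carrying the label,
#' `labeled / (light + labeled)`. Complete metabolic incorporation gives 1;
#' the usual quality bar for SILAC quantification is > 0.98.
#'
#' @param light_int,labeled_int Non-negative intensities of the unlabelled
#'   (light) and labelled (medium or heavy) forms; vectorized.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' incorporation_efficiency(2, 98)
incorporation_efficiency <- function(light_int, labeled_int) {
  if (any(light_int < 0 | labeled_int < 0)) abort("intensities must be >= 0.")
  total <- light_int + labeled_int
  if (any(total == 0)) abort("undefined efficiency: both intensities are zero.")
  labeled_int / total
}

#' Check for Arg-to-Pro conversion satellite peaks
#'
#' Labelled arginine can be metabolically converted to proline, which adds
#' satellite peaks shifted by the per-proline conversion delta of the
#' channel (`+ k * pro_delta / charge` for k prolines). This searches for
#' such satellites relative to the peptide's main channel peak and flags
#' conversion when any satellite exceeds `satellite_threshold` times the
#' main-peak intensity.
#'
#' @inheritParams detect_triplets
#' @param channel `"medium"` or `"heavy"`.
#' @param satellite_threshold Intensity fraction of the main peak above
#'   which conversion is flagged (default 0.05).
#' @return One-row tibble with `channel`, `main_mz`, `main_intensity`,
#'   `satellite_fraction`, `converted`. A peptide without prolines is
#'   vacuously clean (`converted = FALSE`, fraction 0).
#' @export
check_arg_pro_conversion <- function(peaks, spec, channel = c("medium", "heavy"),
                                     tolerance_ppm = 10, satellite_threshold = 0.05,
                                     scheme = silac_scheme()) {
  channel <- match.arg(channel)
  stopifnot(nrow(spec) == 1)
  peaks <- validate_peaklist(peaks)
  main_mz <- peptide_mz(spec, channel, scheme)

  clean <- function(frac, mmz = main_mz, mint = NA_real_) {
    tibble::tibble(
      channel = channel, main_mz = mmz, main_intensity = mint,
      satellite_fraction = frac, converted = frac > satellite_threshold
    )
  }
  if (spec$n_pro == 0) return(clean(0))

  main_i <- nearest_within_ppm(peaks$mz, main_mz, tolerance_ppm)
  if (is.na(main_i)) {
    abort(sprintf("main %s-channel peak not found near m/z %.4f.", channel, main_mz))
  }
  pro_delta <- scheme_row(channel, scheme)$pro_delta
  sat_frac <- 0
  for (k in seq_len(spec$n_pro)) {
    sat_mz <- peaks$mz[main_i] + k * pro_delta / spec$charge
    sat_i <- nearest_within_ppm(peaks$mz, sat_mz, tolerance_ppm)
    if (!is.na(sat_i)) {
      sat_frac <- max(sat_frac, peaks$intensity[sat_i] / peaks$intensity[main_i])
    }
  }
  clean(sat_frac, peaks$mz[main_i], peaks$intensity[main_i])
}

nearest_within_ppm <- function(mz, target, tolerance_ppm) {
  ppm <- abs(mz - target) / target * 1e6
  i <- which.min(ppm)
  if (length(i) && ppm[i] <= tolerance_ppm) i else NA_integer_
}
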
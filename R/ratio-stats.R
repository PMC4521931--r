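#' Base-2 logarithm of a SILAC ratio
#'
#' @param r Positive ratio(s); `NA` passes through.
#' @return `log2(r)`.
#' @export
log2_ratio <- function(r) {
  if (any(r <= 0, na.rm = TRUE)) abort("ratios must be > 0 for log2 transform.")
  log2(r)
}

#' Fit normalization parameters of a log2-ratio population
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' set of log2 ratios; these define the z-score standardization of the
#' data set.
#'
#' @param log2_values Numeric vector of log2 ratios (`NA` dropped); at
#'   least 2 defined values required.
#' @param channel Label stored alongside the fit (e.g. `"M/L"`).
#' @return An object of class `silac_norm`: a one-row tibble with
#'   `channel`, `mean_log2`, `sd_log2`, `n`.
#' @export
#' @examples
#' fit_norm_params(c(-1, 0, 1))
fit_norm_params <- function(log2_values, channel = "global") {
  x <- log2_values[!is.na(log2_values)]
  if (length(x) < 2) abort("insufficient data: need >= 2 log2 values to fit parameters.")
  out <- tibble::tibble(
    channel = channel, mean_log2 = mean(x), sd_log2 = sd(x), n = length(x)
  )
  if (out$sd_log2 == 0) {
    warn("degenerate population: sd_log2 is 0; z-scores are undefined.")
  }
  class(out) <- c("silac_norm", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.silac_norm <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "silac_norm")
  out
}

#' @exportS3Method generics::glance
glance.silac_norm <- function(x, ...) {
  tibble::tibble(n = x$n, mean_log2 = x$mean_log2, sd_log2 = x$sd_log2)
}

#' Standardize a log2 ratio to z-score (sigma) units
#'
#' `(log2_value - mean_log2) / sd_log2`: how many population standard
#' deviations the protein's log2 ratio lies from the population mean.
#'
#' @param log2_value Numeric vector of log2 ratios.
#' @param params A [fit_norm_params()] result (or any one-row data frame
#'   with `mean_log2` and `sd_log2 > 0`).
#' @return Numeric vector of z-scores.
#' @export
zscore <- function(log2_value, params) {
  stopifnot(nrow(params) == 1)
  if (!is.finite(params$sd_log2) || params$sd_log2 <= 0) {
    abort("degenerate population: sd_log2 must be > 0.")
  }
  (log2_value - params$mean_log2) / params$sd_log2
}

#' Two-sided confidence level to z-score threshold
#'
#' The standard-normal critical value of a two-sided confidence level:
#' 95 -> 1.960, 99 -> 2.576, 99.9 -> 3.291.
#'
#' @param level Confidence level in percent, strictly between 0 and 100.
#' @return The `(1 - (1 - level/100)/2)` standard-normal quantile.
#' @export
confidence_to_threshold <- function(level) {
  if (any(level <= 0 | level >= 100)) abort("`level` must be in (0, 100).")
  qnorm(1 - (1 - level / 100) / 2)
}

#' Average z-scores across replicates
#'
#' @param z Numeric vector of per-replicate z-scores (`NA` dropped).
#' @return Arithmetic mean; errors on an empty input.
#' @export
average_z <- function(z) {
  z <- z[!is.na(z)]
  if (!length(z)) abort("cannot average an empty set of z-scores.")
  mean(z)
}

#' Direction-free fold change of a ratio
#'
#' `max(r, 1/r)`, always `>= 1`; symmetric in `r` and `1/r`.
#'
#' @param r Positive ratio(s); `NA` passes through.
#' @return Numeric vector of fold changes.
#' @export
fold_change <- function(r) {
  if (any(r <= 0, na.rm = TRUE)) abort("ratios must be > 0 for fold change.")
  pmax(r, 1 / r)
}

tier_levels <- function(levels = c(95, 99, 99.9)) {
  sort(levels)
}

tier_of <- function(z, levels = c(95, 99, 99.9)) {
  levels <- tier_levels(levels)
  thr <- confidence_to_threshold(levels)
  out <- rep("none", length(z))
  for (i in seq_along(levels)) {
    out[!is.na(z) & abs(z) >= thr[i]] <- as.character(levels[i])
  }
  factor(out, levels = c("none", as.character(levels)))
}

direction_of <- function(z, level = 95) {
  thr <- confidence_to_threshold(level)
  dplyr::case_when(
    is.na(z) ~ "none",
    z >= thr ~ "up",
    z <= -thr ~ "down",
    .default = "none"
  )
}

#' Classify differential regulation from z-scores
#'
#' Assigns, per channel, the highest confidence tier whose threshold is
#' `<= |z|` (inclusive comparison), the direction of regulation at the base
#' level, and a combined flag set when both channels reach the base tier in
#' the same direction. Missing z-scores get tier `"none"`.
#'
#' @param records Tibble with `z_ml` and/or `z_hl` columns.
#' @param levels Confidence tiers in percent (default 95, 99, 99.9).
#' @param base_level Level used for `direction_*` and the `both_channels`
#'   flag (default 95).
#' @return `records` with `tier_ml`, `direction_ml`, `tier_hl`,
#'   `direction_hl`, `both_channels` columns appended (per available
#'   channel).
#' @export
classify_regulation <- function(records, levels = c(95, 99, 99.9), base_level = 95) {
  has_ml <- "z_ml" %in% names(records)
  has_hl <- "z_hl" %in% names(records)
  if (!has_ml && !has_hl) abort("`records` must contain `z_ml` and/or `z_hl`.")
  if (has_ml) {
    records$tier_ml <- tier_of(records$z_ml, levels)
    records$direction_ml <- direction_of(records$z_ml, base_level)
  }
  if (has_hl) {
    records$tier_hl <- tier_of(records$z_hl, levels)
    records$direction_hl <- direction_of(records$z_hl, base_level)
  }
  if (has_ml && has_hl) {
    records$both_channels <- records$direction_ml != "none" &
      records$direction_ml == records$direction_hl
  }
  records
}

#' Count regulated proteins per channel at a confidence level
#'
#' Counts records with `z >= threshold` (up) and `z <= -threshold` (down)
#' per channel, and the set regulated in the same direction in both
#' channels.
#'
#' @param records Tibble with `z_ml` and/or `z_hl` columns.
#' @param level Confidence level in percent (default 95).
#' @return A tibble with columns `channel` (`"M/L"`, `"H/L"`, `"both"`),
#'   `up`, `down`.
#' @export
count_regulated <- function(records, level = 95) {
  thr <- confidence_to_threshold(level)
  cnt <- function(z) {
    c(up = sum(z >= thr, na.rm = TRUE), down = sum(z <= -thr, na.rm = TRUE))
  }
  rows <- list()
  if ("z_ml" %in% names(records)) {
    k <- cnt(records$z_ml)
    rows <- c(rows, list(tibble::tibble(channel = "M/L", up = k[["up"]], down = k[["down"]])))
  }
  if ("z_hl" %in% names(records)) {
    k <- cnt(records$z_hl)
    rows <- c(rows, list(tibble::tibble(channel = "H/L", up = k[["up"]], down = k[["down"]])))
  }
  if (all(c("z_ml", "z_hl") %in% names(records))) {
    both_up <- sum(records$z_ml >= thr & records$z_hl >= thr, na.rm = TRUE)
    both_down <- sum(records$z_ml <= -thr & records$z_hl <= -thr, na.rm = TRUE)
    rows <- c(rows, list(tibble::tibble(channel = "both", up = both_up, down = both_down)))
  }
  dplyr::bind_rows(rows)
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes `2^-ddCt` with
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#'         (Ct_target,control - Ct_ref,control)`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Finite qPCR cycle-threshold values (vectorized).
#' @return Fold change of the target gene relative to the reference gene
#'   and control sample.
#' @export
#' @examples
#' ddct_fold(24, 18, 26, 19) # ddCt = -1 -> 2
ddct_fold <- function(ct_target_treated, ct_ref_treated,
                      ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) abort("all Ct values must be finite.")
  ddct <- (ct_target_treated - ct_ref_treated) - (ct_target_control - ct_ref_control)
  2^(-ddct)
}
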
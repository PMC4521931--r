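#' Filter peptide evidence by sequence length
#'
#' Reliable SILAC quantification excludes very short peptides; the
#' conventional cutoff is a minimum length of 6 amino acids.
#'
#' @param evidence Evidence tibble with at least a `sequence` column (see
#'   [read_evidence()] for the dialect).
#' @param min_length Minimum sequence length retained (default 6).
#' @return The evidence tibble with short rows removed, order preserved.
#' @export
filter_evidence <- function(evidence, min_length = 6) {
  stopifnot(min_length >= 1)
  dplyr::filter(evidence, nchar(.data$sequence) >= min_length)
}

#' Per-peptide M/L and H/L intensity ratios
#'
#' Adds `ratio_ml` and `ratio_hl` columns: channel intensity divided by the
#' light intensity when both are present and light > 0, `NA` otherwise
#' (missingness propagates, never errors).
#'
#' @param evidence Evidence tibble with `intensity_l`, `intensity_m`,
#'   `intensity_h` columns.
#' @return The input with `ratio_ml`, `ratio_hl` columns appended.
#' @export
peptide_ratios <- function(evidence) {
  safe_ratio <- function(num, den) {
    ifelse(!is.na(num) & !is.na(den) & den > 0, num / den, NA_real_)
  }
  dplyr::mutate(
    evidence,
    ratio_ml = safe_ratio(.data$intensity_m, .data$intensity_l),
    ratio_hl = safe_ratio(.data$intensity_h, .data$intensity_l)
  )
}

#' Aggregate peptide evidence into per-protein, per-replicate ratios
#'
#' The protein ratio in a replicate is the median (robust default; mean
#' available) of its defined peptide intensity ratios, computed separately
#' for M/L and H/L. A channel ratio is reported only when at least
#' `min_ratio_count` peptide ratios are defined.
#'
#' @param evidence Evidence tibble; peptide ratios are computed with
#'   [peptide_ratios()] if not already present.
#' @param method `"median"` (default) or `"mean"`.
#' @param min_ratio_count Minimum number of defined peptide ratios required
#'   for a protein-level ratio (default 1).
#' @return A tibble with one row per protein x replicate: `protein`,
#'   `replicate`, `ml_ratio`, `hl_ratio`, `n_peptides`, `n_ratio_ml`,
#'   `n_ratio_hl`.
#' @export
aggregate_proteins <- function(evidence, method = c("median", "mean"),
                               min_ratio_count = 1) {
  method <- match.arg(method)
  agg <- if (method == "median") stats::median else base::mean
  if (!all(c("ratio_ml", "ratio_hl") %in% names(evidence))) {
    evidence <- peptide_ratios(evidence)
  }
  guarded <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= min_ratio_count && length(x) > 0) agg(x) else NA_real_
  }
  evidence |>
    dplyr::group_by(.data$protein, .data$replicate) |>
    dplyr::summarise(
      ml_ratio = guarded(.data$ratio_ml),
      hl_ratio = guarded(.data$ratio_hl),
      n_peptides = dplyr::n(),
      n_ratio_ml = sum(!is.na(.data$ratio_ml)),
      n_ratio_hl = sum(!is.na(.data$ratio_hl)),
      .groups = "drop"
    )
}

#' Merge per-replicate protein quantifications
#'
#' Keeps proteins whose ratio is defined in at least `required_replicates`
#' replicates (per channel) and averages the per-replicate ratios. The
#' default averages on the ratio scale (arithmetic mean of ratios);
#' `average = "log2"` takes the geometric mean instead.
#'
#' @param quants Output of [aggregate_proteins()].
#' @param required_replicates Minimum replicates a channel ratio must be
#'   defined in (default 2).
#' @param average `"ratio"` (default) or `"log2"`.
#' @return A tibble with one row per retained protein: `protein`,
#'   `ml_average`, `hl_average`, `n_rep_ml`, `n_rep_hl`. A channel average
#'   is `NA` when that channel fails the replicate requirement; proteins
#'   failing it in both channels are dropped.
#' @export
merge_replicates <- function(quants, required_replicates = 2,
                             average = c("ratio", "log2")) {
  stopifnot(required_replicates >= 1)
  average <- match.arg(average)
  avg <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < required_replicates) return(NA_real_)
    if (average == "ratio") mean(x) else 2^mean(log2(x))
  }
  quants |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      ml_average = avg(.data$ml_ratio),
      hl_average = avg(.data$hl_ratio),
      n_rep_ml = sum(!is.na(.data$ml_ratio)),
      n_rep_hl = sum(!is.na(.data$hl_ratio)),
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$ml_average) | !is.na(.data$hl_average))
}
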
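#' End-to-end SILAC differential-regulation analysis
#'
#' Runs the full quantification-and-calling pipeline on a peptide-evidence
#' table: length filter, peptide intensity ratios, per-protein median
#' aggregation per replicate, replicate intersection and averaging, log2
#' transform, z-score standardization, confidence-tier classification and
#' fold change.
#'
#' Normalization modes:
#' \describe{
#'   \item{`"per-replicate"`}{(default) mean/SD fitted separately per
#'     channel per replicate; each protein gets a z-score per replicate,
#'     then replicate z-scores are averaged.}
#'   \item{`"paper-compat"`}{a single parameter set — fitted on the merged
#'     M/L log2 averages unless `params` is supplied — standardizes both
#'     channels' merged log2 averages. This mirrors published tables in
#'     which H/L z-scores are numerically consistent with the M/L
#'     population parameters.}
#' }
#'
#' @param evidence Evidence tibble (see [read_evidence()]).
#' @param min_length Minimum peptide length (default 6).
#' @param method Protein-level aggregation, `"median"` or `"mean"`.
#' @param min_ratio_count Minimum defined peptide ratios per protein ratio.
#' @param required_replicates Replicates a channel must be quantified in.
#' @param mode Normalization mode, see Details.
#' @param params Optional externally supplied `silac_norm` parameters
#'   (paper-compat mode only).
#' @param levels Confidence tiers in percent.
#' @param base_level Level for directions and regulated counts.
#' @param average Replicate ratio averaging, `"ratio"` or `"log2"`.
#' @return An object of class `silac_result`: list with `records` (one row
#'   per quantified protein with averages, log2 values, z-scores, tiers,
#'   directions, fold changes), `params` (fitted normalization parameters),
#'   `z_by_replicate` (per-replicate z-scores, per-replicate mode),
#'   `counts` (regulated counts at `base_level`) and `settings`.
#' @export
silac_differential <- function(evidence,
                               min_length = 6,
                               method = c("median", "mean"),
                               min_ratio_count = 1,
                               required_replicates = 2,
                               mode = c("per-replicate", "paper-compat"),
                               params = NULL,
                               levels = c(95, 99, 99.9),
                               base_level = 95,
                               average = c("ratio", "log2")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  average <- match.arg(average)

  ev <- filter_evidence(evidence, min_length)
  quants <- aggregate_proteins(ev, method = method, min_ratio_count = min_ratio_count)
  merged <- merge_replicates(quants, required_replicates = required_replicates,
                             average = average)

  records <- merged |>
    dplyr::mutate(
      log2_ml = ifelse(is.na(.data$ml_average), NA_real_, log2(.data$ml_average)),
      log2_hl = ifelse(is.na(.data$hl_average), NA_real_, log2(.data$hl_average))
    )

  z_by_replicate <- NULL
  if (mode == "per-replicate") {
    z_by_replicate <- per_replicate_z(quants)
    zavg <- z_by_replicate |>
      dplyr::group_by(.data$protein) |>
      dplyr::summarise(
        z_ml = if (all(is.na(.data$z_ml))) NA_real_ else average_z(.data$z_ml),
        z_hl = if (all(is.na(.data$z_hl))) NA_real_ else average_z(.data$z_hl),
        .groups = "drop"
      )
    records <- dplyr::left_join(records, zavg, by = "protein")
    params_out <- attr(z_by_replicate, "params")
  } else {
    if (is.null(params)) {
      params <- fit_norm_params(records$log2_ml, channel = "M/L")
    }
    records$z_ml <- zscore(records$log2_ml, params)
    records$z_hl <- zscore(records$log2_hl, params)
    params_out <- tidy(params)
  }

  records <- records |>
    classify_regulation(levels = levels, base_level = base_level) |>
    dplyr::mutate(
      fold_ml = ifelse(is.na(.data$ml_average), NA_real_, fold_change(.data$ml_average)),
      fold_hl = ifelse(is.na(.data$hl_average), NA_real_, fold_change(.data$hl_average))
    )

  structure(
    list(
      records = records,
      params = params_out,
      z_by_replicate = z_by_replicate,
      counts = count_regulated(records, base_level),
      settings = list(
        min_length = min_length, method = method,
        min_ratio_count = min_ratio_count,
        required_replicates = required_replicates, mode = mode,
        levels = levels, base_level = base_level, average = average,
        n_evidence = nrow(evidence), n_evidence_kept = nrow(ev),
        n_proteins_seen = dplyr::n_distinct(quants$protein),
        n_proteins_quantified = nrow(merged)
      )
    ),
    class = "silac_result"
  )
}

# z-scores per replicate: parameters fitted per channel on each replicate's
# own population of defined log2 ratios ("each data set").
per_replicate_z <- function(quants) {
  fits <- list()
  out <- quants |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(df, key) {
      res <- tibble::tibble(protein = df$protein,
                            z_ml = NA_real_, z_hl = NA_real_)
      for (ch in c("ml", "hl")) {
        ratios <- df[[paste0(ch, "_ratio")]]
        ok <- !is.na(ratios)
        if (sum(ok) >= 2) {
          p <- fit_norm_params(log2(ratios[ok]),
                               channel = paste(toupper(substr(ch, 1, 1)), "L", sep = "/"))
          fits[[length(fits) + 1]] <<- dplyr::mutate(tidy(p),
                                                     replicate = key$replicate,
                                                     .before = 1)
          res[[paste0("z_", ch)]][ok] <- zscore(log2(ratios[ok]), p)
        }
      }
      res
    }) |>
    dplyr::ungroup()
  attr(out, "params") <- dplyr::bind_rows(fits)
  out
}

#' @export
print.silac_result <- function(x, ...) {
  s <- x$settings
  cat("<silac_result>\n")
  cat(sprintf("  evidence rows: %d (kept after length filter: %d)\n",
              s$n_evidence, s$n_evidence_kept))
  cat(sprintf("  proteins seen: %d; quantified in >= %d replicate(s): %d (%.1f%%)\n",
              s$n_proteins_seen, s$required_replicates, s$n_proteins_quantified,
              100 * s$n_proteins_quantified / max(1, s$n_proteins_seen)))
  cat(sprintf("  normalization: %s\n", s$mode))
  cnt <- x$counts
  for (i in seq_len(nrow(cnt))) {
    cat(sprintf("  regulated at %s%%, %s: %d up, %d down\n",
                format(s$base_level), cnt$channel[i], cnt$up[i], cnt$down[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.silac_result <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.silac_result <- function(x, ...) {
  s <- x$settings
  cnt <- x$counts
  ml <- cnt[cnt$channel == "M/L", ]
  hl <- cnt[cnt$channel == "H/L", ]
  tibble::tibble(
    n_evidence = s$n_evidence,
    n_proteins_seen = s$n_proteins_seen,
    n_proteins_quantified = s$n_proteins_quantified,
    quantified_fraction = s$n_proteins_quantified / max(1, s$n_proteins_seen),
    up_ml = if (nrow(ml)) ml$up else NA_integer_,
    down_ml = if (nrow(ml)) ml$down else NA_integer_,
    up_hl = if (nrow(hl)) hl$up else NA_integer_,
    down_hl = if (nrow(hl)) hl$down else NA_integer_
  )
}

#' Plot a SILAC differential result
#'
#' Scatter of M/L vs H/L z-scores coloured by regulation direction, with
#' the base-level thresholds drawn; falls back to a single-channel
#' histogram when only one channel is present.
#'
#' @param object A [silac_differential()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.silac_result <- function(object, ...) {
  rec <- object$records
  thr <- confidence_to_threshold(object$settings$base_level)
  if (all(c("z_ml", "z_hl") %in% names(rec))) {
    rec$status <- dplyr::case_when(
      rec$direction_ml != "none" & rec$direction_hl != "none" ~ "both channels",
      rec$direction_ml != "none" ~ "M/L only",
      rec$direction_hl != "none" ~ "H/L only",
      .default = "not regulated"
    )
    ggplot2::ggplot(rec, ggplot2::aes(x = .data$z_ml, y = .data$z_hl,
                                      colour = .data$status)) +
      ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
      ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
      ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed") +
      ggplot2::labs(x = "z (M/L), sigma", y = "z (H/L), sigma", colour = NULL)
  } else {
    ch <- intersect(c("z_ml", "z_hl"), names(rec))[1]
    ggplot2::ggplot(rec, ggplot2::aes(x = .data[[ch]])) +
      ggplot2::geom_histogram(bins = 60, na.rm = TRUE) +
      ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed") +
      ggplot2::labs(x = paste(ch, "(sigma)"), y = "proteins")
  }
}
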
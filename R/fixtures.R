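#' Packaged reference tables from the source study
#'
#' Transcriptions of the published summary tables shipped with the
#' package: `"table1"` — per-channel log2-ratio population parameters and
#' regulated-protein counts at the three confidence tiers; `"table2"` —
#' the 51 upregulated proteins (accession, gene, M/L and H/L averages,
#' log2 values, z-scores); `"table3"` — the 111 downregulated proteins,
#' same columns.
#'
#' @param name `"table1"`, `"table2"` or `"table3"`.
#' @return A tibble; numeric cells carry the printed (2-decimal) precision.
#' @export
#' @examples
#' silac_fixture("table1")
silac_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  file <- c(table1 = "table1_population.tsv",
            table2 = "table2_upregulated.tsv",
            table3 = "table3_downregulated.tsv")[[name]]
  path <- system.file("extdata", file, package = "silacdiff", mustWork = TRUE)
  if (name == "table1") {
    readr::read_tsv(path, col_types = "cddiiiiii", progress = FALSE)
  } else {
    readr::read_tsv(path, col_types = "cccdddddd", progress = FALSE)
  }
}

#' Reference peptides used for label-incorporation checks
#'
#' The three peptides whose spectra demonstrate label incorporation and
#' channel spacing in the source study: GVVDSEDLPLNISR (heat shock protein
#' 90, singly charged MALDI ion), VNQIGSVTESLQACK (alpha-enolase, doubly
#' charged) and GGPEVQQVPAGER (fatty acid synthase, doubly charged).
#'
#' @return A tibble with columns `sequence`, `charge`, `protein`,
#'   `description`.
#' @export
example_peptides <- function() {
  tibble::tibble(
    sequence = c("GVVDSEDLPLNISR", "VNQIGSVTESLQACK", "GGPEVQQVPAGER"),
    charge = c(1L, 2L, 2L),
    protein = c("P08238", "P06733", "P49327"),
    description = c("heat shock protein 90", "alpha-enolase", "fatty acid synthase")
  )
}

#' Normalization parameters of a fixture channel
#'
#' Convenience accessor for the published population parameters: the
#' M/L row (mean -0.072, SD 1.237) or H/L row (mean -0.151, SD 1.143) of
#' the population table, as a `silac_norm` object usable with [zscore()].
#'
#' @param channel `"M/L"` or `"H/L"`.
#' @return A `silac_norm` object.
#' @export
fixture_norm_params <- function(channel = c("M/L", "H/L")) {
  channel <- match.arg(channel)
  t1 <- silac_fixture("table1")
  row <- t1[t1$channel == channel, ]
  out <- tibble::tibble(channel = channel, mean_log2 = row$mean_log2,
                        sd_log2 = row$sd_log2, n = NA_integer_)
  class(out) <- c("silac_norm", class(out))
  out
}
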
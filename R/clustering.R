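#' Build a z-score matrix from a SILAC differential result
#'
#' Extracts the per-replicate z-scores of the proteins regulated at the
#' result's base confidence level into a numeric matrix (rows = proteins,
#' columns = channel x replicate), the input hierarchical clustering
#' expects.
#'
#' @param result A [silac_differential()] result run in `"per-replicate"`
#'   mode.
#' @param regulated_only Keep only proteins with a non-`"none"` direction
#'   in either channel (default `TRUE`).
#' @return A numeric matrix with rownames = accessions and columns like
#'   `z_ml.rep1`, `z_hl.rep1`, ...; `NA` where a channel was not
#'   quantified.
#' @export
zscore_matrix <- function(result, regulated_only = TRUE) {
  stopifnot(inherits(result, "silac_result"))
  if (is.null(result$z_by_replicate)) {
    abort("per-replicate z-scores unavailable; rerun with mode = \"per-replicate\".")
  }
  keep <- result$records$protein
  if (regulated_only) {
    rec <- result$records
    keep <- rec$protein[(rec$direction_ml %||% "none") != "none" |
                          (rec$direction_hl %||% "none") != "none"]
  }
  wide <- result$z_by_replicate |>
    dplyr::filter(.data$protein %in% keep) |>
    tidyr::pivot_wider(
      names_from = "replicate",
      values_from = c("z_ml", "z_hl"),
      names_glue = "{.value}.{replicate}"
    )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$protein
  mat
}

#' Hierarchical clustering of a z-score matrix
#'
#' Agglomerative clustering of rows and/or columns with a configurable
#' distance metric and linkage. Missing values are imputed to 0 sigma (the
#' population mean) for the distance computation only; the stored matrix
#' keeps the original values. Leaf order is deterministic given the input
#' order; ties in merge distance follow the original index order.
#'
#' @param mat Numeric matrix with unique row and column names; at least 2
#'   rows and 2 columns on any clustered axis.
#' @param axis `"both"` (default), `"rows"` or `"columns"`.
#' @param metric Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return An object of class `silac_clust`: list with `matrix` (input
#'   values reordered to leaf order), `row_hclust`, `col_hclust` (NULL on
#'   unclustered axes), `metric`, `linkage`.
#' @export
cluster_zmatrix <- function(mat, axis = c("both", "rows", "columns"),
                            metric = "euclidean", linkage = "average") {
  axis <- match.arg(axis)
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    abort("`mat` must have unique rownames.")
  }
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat))) {
    abort("`mat` must have unique colnames.")
  }
  all_missing <- apply(mat, 1, function(x) all(is.na(x)))
  if (any(all_missing)) abort("all-missing rows cannot be clustered.")
  imp <- mat
  imp[is.na(imp)] <- 0

  cl <- function(m, what) {
    if (nrow(m) < 2) abort(sprintf("need at least 2 %s to cluster.", what))
    hclust(dist(m, method = metric), method = linkage)
  }
  row_hc <- col_hc <- NULL
  if (axis %in% c("both", "rows")) row_hc <- cl(imp, "rows")
  if (axis %in% c("both", "columns")) col_hc <- cl(t(imp), "columns")

  ord_r <- if (is.null(row_hc)) seq_len(nrow(mat)) else row_hc$order
  ord_c <- if (is.null(col_hc)) seq_len(ncol(mat)) else col_hc$order
  structure(
    list(matrix = mat[ord_r, ord_c, drop = FALSE],
         row_hclust = row_hc, col_hclust = col_hc,
         metric = metric, linkage = linkage),
    class = "silac_clust"
  )
}

#' @export
print.silac_clust <- function(x, ...) {
  cat(sprintf("<silac_clust> %d x %d matrix, %s distance, %s linkage\n",
              nrow(x$matrix), ncol(x$matrix), x$metric, x$linkage))
  invisible(x)
}

#' Heat-map of a clustered z-score matrix
#'
#' Tile plot in dendrogram leaf order with a symmetric diverging colour
#' scale centred at 0 sigma; missing values are drawn in their own colour.
#'
#' @param object A [cluster_zmatrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.silac_clust <- function(object, ...) {
  m <- object$matrix
  df <- tibble::tibble(
    protein = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    sample = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    z = as.vector(m)
  )
  lim <- max(abs(df$z), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$protein,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  midpoint = 0, limits = c(-lim, lim),
                                  na.value = "grey70", name = "z (sigma)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Export a clustered heat map and its companion files
#'
#' Writes the heat-map image, the reordered matrix as TSV (bit-exact
#' round-trip) and, when requested, the dendrograms in Newick format.
#'
#' @param x A [cluster_zmatrix()] result.
#' @param path Image path; format from the extension (png, pdf, svg ...).
#' @param tsv_path Optional path for the reordered matrix TSV.
#' @param newick_path Optional path for the row (and `<path>.cols` column)
#'   dendrogram in Newick format.
#' @param width,height Image size in inches.
#' @return Invisibly, the paths written.
#' @export
render_heatmap <- function(x, path, tsv_path = NULL, newick_path = NULL,
                           width = 6, height = 8) {
  stopifnot(inherits(x, "silac_clust"))
  if (nrow(x$matrix) == 0 || ncol(x$matrix) == 0) {
    abort("refusing to render an empty matrix.")
  }
  p <- autoplot(x)
  ggplot2::ggsave(path, p, width = width, height = height)
  written <- path
  if (!is.null(tsv_path)) {
    df <- tibble::as_tibble(x$matrix, rownames = "protein")
    # %.17g guarantees doubles survive the text round trip bit-exactly
    df[-1] <- lapply(df[-1], function(v) ifelse(is.na(v), NA, sprintf("%.17g", v)))
    readr::write_tsv(df, tsv_path)
    written <- c(written, tsv_path)
  }
  if (!is.null(newick_path)) {
    write_dendrogram_newick(x$row_hclust, newick_path)
    if (!is.null(x$col_hclust)) {
      colpath <- paste0(newick_path, ".cols")
      write_dendrogram_newick(x$col_hclust, colpath)
      written <- c(written, colpath)
    }
    written <- c(written, newick_path)
  }
  invisible(written)
}

write_dendrogram_newick <- function(hc, path) {
  if (is.null(hc)) abort("no dendrogram to export.")
  ape::write.tree(ape::as.phylo(hc), file = path)
}
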
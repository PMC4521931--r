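check_margins <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & N >= 1 & k <= pmin(K, n) & K <= N & n <= N
  if (any(!ok)) abort("inconsistent hypergeometric margins (need 0 <= k <= min(K, n); K, n <= N).")
}

#' One-tailed Fisher exact (hypergeometric tail) p-value
#'
#' Probability of observing an overlap of `k` or more under the
#' hypergeometric law: a list of `n` proteins drawn from a background of
#' `N` that contains `K` term members.
#'
#' @param k Observed overlap between list and term.
#' @param K Term size in the background.
#' @param n List size.
#' @param N Background size.
#' @return `P(X >= k)`; vectorized over all arguments.
#' @export
fisher_one_tailed <- function(k, K, n, N) {
  check_margins(k, K, n, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score (jackknifed Fisher p-value)
#'
#' The over-representation score used by DAVID/EASE: the one-tailed Fisher
#' p-value with one member removed from the overlap,
#' `P(X >= max(k - 1, 0))`. Always at least as large as the Fisher p-value,
#' penalizing terms supported by a single protein (`k = 1` scores 1).
#'
#' @inheritParams fisher_one_tailed
#' @return The jackknifed tail probability; vectorized.
#' @export
ease_score <- function(k, K, n, N) {
  check_margins(k, K, n, N)
  fisher_one_tailed(pmax(k - 1, 0), K, n, N)
}

#' Annotation-term over-representation analysis
#'
#' Tests each annotation term for over-representation in a protein list
#' against a background, with the one-tailed Fisher exact test and the
#' jackknifed EASE score. A term passes when its overlap count is at least
#' `min_count` and its EASE score is below `ease_threshold` (the
#' conventional filters are count >= 2 and EASE < 0.1). A
#' Benjamini-Hochberg adjusted EASE column is emitted for convenience;
#' `passes` uses the raw EASE score.
#'
#' @param proteins Character vector: the regulated-protein list (duplicates
#'   ignored; must be contained in `background`).
#' @param background Character vector: the protein universe.
#' @param annotations Tibble with columns `accession`, `term_id` and
#'   optionally `term_label`, `namespace` (see [read_annotations()]).
#'   Annotations for accessions outside the background are dropped.
#' @param min_count Minimum overlap count (default 2).
#' @param ease_threshold EASE cutoff in (0, 1] (default 0.1).
#' @return A tibble with one row per term overlapping the list (`k >= 1`):
#'   `term_id`, `term_label`, `namespace`, `k`, `K`, `n`, `N`, `fisher_p`,
#'   `ease_p`, `ease_bh`, `passes`; sorted by ascending `ease_p`, ties by
#'   descending `k` then `term_id`.
#' @export
enrich <- function(proteins, background, annotations,
                   min_count = 2, ease_threshold = 0.1) {
  stopifnot(min_count >= 0, ease_threshold > 0, ease_threshold <= 1)
  proteins <- unique(proteins)
  background <- unique(background)
  if (!length(background)) abort("`background` is empty.")
  outside <- setdiff(proteins, background)
  if (length(outside)) {
    abort(sprintf("protein list is not contained in the background (e.g. %s).",
                  paste(head(outside, 3), collapse = ", ")))
  }
  if (!"term_label" %in% names(annotations)) annotations$term_label <- NA_character_
  if (!"namespace" %in% names(annotations)) annotations$namespace <- NA_character_
  ann <- annotations |>
    dplyr::filter(.data$accession %in% background) |>
    dplyr::distinct(.data$accession, .data$term_id, .keep_all = TRUE)

  N <- length(background)
  n <- length(proteins)
  res <- ann |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      term_label = dplyr::first(.data$term_label),
      namespace = dplyr::first(.data$namespace),
      K = dplyr::n(),
      k = sum(.data$accession %in% proteins),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$k >= 1) |>
    dplyr::mutate(
      n = n, N = N,
      fisher_p = fisher_one_tailed(.data$k, .data$K, n, N),
      ease_p = ease_score(.data$k, .data$K, n, N),
      ease_bh = p.adjust(.data$ease_p, method = "BH"),
      passes = .data$k >= min_count & .data$ease_p < ease_threshold
    ) |>
    dplyr::arrange(.data$ease_p, dplyr::desc(.data$k), .data$term_id) |>
    dplyr::relocate("term_id", "term_label", "namespace", "k", "K", "n", "N")
  res
}
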
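# Brute-force hypergeometric upper-tail oracle: explicit pmf summation from
# log-binomial coefficients, independent of stats::phyper.
hyper_pmf_oracle <- function(x, K, n, N) {
  exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
}

hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(hyper_pmf_oracle(k:hi, K, n, N))
}

# Random but reproducible hypergeometric margins.
random_margins <- function(n_cases, seed) {
  set.seed(seed)
  tibble::tibble(
    N = sample(20:500, n_cases, replace = TRUE)
  ) |>
    dplyr::mutate(
      K = vapply(N, function(N) sample(1:N, 1), integer(1)),
      n = vapply(N, function(N) sample(1:N, 1), integer(1)),
      k = vapply(pmin(K, n), function(m) sample(0:m, 1), integer(1))
    )
}

# Small hand-rolled evidence table for unit tests.
toy_evidence <- function() {
  tibble::tibble(
    sequence = c("PEPTIDEK", "PEPTIDER", "AAAAAAK", "PEPTIDEK", "PEPTIDER", "AAAAAAK"),
    protein = rep(c("P1", "P1", "P2"), 2),
    charge = 2L,
    intensity_l = c(100, 200, 50, 110, 190, 60),
    intensity_m = c(500, 800, 100, 550, 760, 120),
    intensity_h = c(1000, 2000, 25, 1100, 1900, 30),
    replicate = rep(c("rep1", "rep2"), each = 3)
  )
}
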
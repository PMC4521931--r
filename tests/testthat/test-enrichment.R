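test_that("one-tailed Fisher and EASE agree with brute-force pmf summation", {
  cases <- random_margins(1000, seed = 17)
  fisher <- fisher_one_tailed(cases$k, cases$K, cases$n, cases$N)
  ease <- ease_score(cases$k, cases$K, cases$n, cases$N)
  oracle_f <- purrr::pmap_dbl(cases[c("k", "K", "n", "N")], function(k, K, n, N) {
    hyper_tail_oracle(k, K, n, N)
  })
  oracle_e <- purrr::pmap_dbl(cases[c("k", "K", "n", "N")], function(k, K, n, N) {
    hyper_tail_oracle(max(k - 1, 0), K, n, N)
  })
  expect_equal(fisher, oracle_f, tolerance = 1e-12)
  expect_equal(ease, oracle_e, tolerance = 1e-12)
  expect_true(all(ease >= fisher))
})

test_that("hypergeometric pmf sums to one over its support", {
  cases <- random_margins(50, seed = 23)
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      support <- max(0, n + K - N):min(K, n)
      expect_equal(sum(hyper_pmf_oracle(support, K, n, N)), 1, tolerance = 1e-12)
    })
  }
})

test_that("Fisher/EASE degenerate margins behave as limits demand", {
  expect_identical(fisher_one_tailed(0, 10, 10, 100), 1)
  expect_identical(fisher_one_tailed(5, 5, 5, 5), 1)
  expect_identical(ease_score(1, 10, 10, 100), 1) # jackknifed overlap 0
  expect_error(fisher_one_tailed(11, 10, 10, 100), "margins")
  expect_error(fisher_one_tailed(2, 10, 10, 5), "margins")
})

test_that("planted enrichment ranks first and passes the count/EASE filters", {
  cfg <- sim_config(n_proteins = 2000, seed = 12)
  sim <- simulate_evidence(cfg)
  ann <- simulate_annotations(sim$truth, n_terms = 30, planted_terms = 2,
                              enrichment_strength = 8, term_size_range = c(15, 25),
                              seed = 12)
  regulated <- sim$truth$protein[sim$truth$regulated]
  res <- enrich(regulated, sim$truth$protein, ann$annotations)
  expect_true(res$term_id[1] %in% ann$planted)
  expect_true(all(res$passes[res$term_id %in% ann$planted]))
  # oracle recomputation of the top hit
  top <- res[1, ]
  expect_equal(top$ease_p, hyper_tail_oracle(top$k - 1, top$K, top$n, top$N),
               tolerance = 1e-12)
})

test_that("single-protein overlaps never pass and the count filter is enforced", {
  background <- sprintf("P%03d", 1:50)
  ann <- tibble::tibble(accession = c("P001", "P002", "P003"),
                        term_id = c("T1", "T1", "T2"))
  res <- enrich(c("P001", "P003"), background, ann)
  expect_false(res$passes[res$term_id == "T2"]) # k = 1
  expect_identical(res$k[res$term_id == "T2"], 1L)
})

test_that("enrich has set semantics and validates containment", {
  background <- sprintf("P%03d", 1:100)
  ann <- tibble::tibble(accession = background[1:20],
                        term_id = rep(c("T1", "T2"), each = 10))
  lst <- background[1:10]
  res1 <- enrich(lst, background, ann)
  res2 <- enrich(c(lst, lst, lst[1]), background, ann)
  expect_identical(res1, res2)
  expect_error(enrich(c(lst, "NOT_THERE"), background, ann), "not contained")
  expect_error(enrich(lst, character(), ann), "empty")
  # list == background: forced overlap, fisher p = 1 everywhere
  res3 <- enrich(background, background, ann)
  expect_true(all(res3$fisher_p == 1))
  expect_true(all(res3$n == res3$N))
})

test_that("null annotations rarely reach nominal Fisher significance", {
  cfg <- sim_config(n_proteins = 2000, seed = 601)
  sim <- simulate_evidence(cfg)
  regulated <- sim$truth$protein[sim$truth$regulated]
  frac <- vapply(1:20, function(s) {
    ann <- simulate_annotations(sim$truth, n_terms = 50, seed = 600 + s)
    res <- enrich(regulated, sim$truth$protein, ann$annotations, min_count = 0)
    sum(res$fisher_p < 0.05) / length(unique(ann$annotations$term_id))
  }, numeric(1))
  expect_lte(mean(frac), 0.07)
})

test_that("strength-zero annotation generation almost never yields passing terms", {
  cfg <- sim_config(n_proteins = 2000, seed = 901)
  sim <- simulate_evidence(cfg)
  regulated <- sim$truth$protein[sim$truth$regulated]
  n_seeds <- 30
  passing <- vapply(seq_len(n_seeds), function(s) {
    ann <- simulate_annotations(sim$truth, planted_terms = 0,
                                enrichment_strength = 0, seed = 900 + s)
    res <- enrich(regulated, sim$truth$protein, ann$annotations)
    sum(res$passes)
  }, numeric(1))
  # one-sided binomial check of the >= 93% clean-seed rate (alpha = 0.01)
  critical <- qbinom(0.01, n_seeds, 0.93)
  expect_gte(sum(passing == 0), critical)
})
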
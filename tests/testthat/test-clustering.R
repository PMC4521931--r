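block_matrix <- function(seed = 41, n_up = 10, n_down = 10) {
  set.seed(seed)
  m <- rbind(
    matrix(rnorm(n_up * 4, 3, 0.3), n_up),
    matrix(rnorm(n_down * 4, -3, 0.3), n_down)
  )
  rownames(m) <- sprintf("P%03d", seq_len(nrow(m)))
  colnames(m) <- c("z_ml.rep1", "z_ml.rep2", "z_hl.rep1", "z_hl.rep2")
  m
}

test_that("identical rows merge at distance zero and sit on adjacent leaves", {
  m <- block_matrix()
  m["P003", ] <- m["P001", ]
  cl <- cluster_zmatrix(m, axis = "rows")
  expect_equal(min(cl$row_hclust$height), 0)
  ord <- rownames(cl$matrix)
  expect_equal(abs(which(ord == "P001") - which(ord == "P003")), 1)
})

test_that("two planted row blocks are recovered exactly by cutting the dendrogram", {
  m <- block_matrix(seed = 42)
  cl <- cluster_zmatrix(m, axis = "rows")
  groups <- cutree(cl$row_hclust, k = 2)
  expect_identical(length(unique(groups[1:10])), 1L)
  expect_identical(length(unique(groups[11:20])), 1L)
  expect_false(groups[1] == groups[11])
})

test_that("replicate column pairs cluster together before cross-pair merges", {
  set.seed(43)
  n <- 60
  a <- rnorm(n); b <- rnorm(n)
  # within-pair correlation ~0.95, across-pair ~0
  m <- cbind(
    a + rnorm(n, 0, 0.32), a + rnorm(n, 0, 0.32),
    b + rnorm(n, 0, 0.32), b + rnorm(n, 0, 0.32)
  )
  rownames(m) <- sprintf("P%03d", 1:n)
  colnames(m) <- c("z_ml.rep1", "z_ml.rep2", "z_hl.rep1", "z_hl.rep2")
  cl <- cluster_zmatrix(m)
  groups <- cutree(cl$col_hclust, k = 2)
  expect_identical(groups[["z_ml.rep1"]], groups[["z_ml.rep2"]])
  expect_identical(groups[["z_hl.rep1"]], groups[["z_hl.rep2"]])
  expect_false(groups[["z_ml.rep1"]] == groups[["z_hl.rep1"]])
})

test_that("clustering is invariant under row permutation up to relabeling", {
  m <- block_matrix(seed = 44)
  set.seed(45)
  perm <- sample(nrow(m))
  cl1 <- cluster_zmatrix(m, axis = "rows")
  cl2 <- cluster_zmatrix(m[perm, ], axis = "rows")
  expect_equal(sort(cl1$row_hclust$height), sort(cl2$row_hclust$height))
  g1 <- cutree(cl1$row_hclust, k = 4)
  g2 <- cutree(cl2$row_hclust, k = 4)[rownames(m)]
  # same partition: co-membership matrices agree
  expect_identical(outer(g1, g1, "=="), outer(g2, g2, "=="))
})

test_that("average-linkage merge heights are non-decreasing and cophenetic distances non-negative", {
  m <- block_matrix(seed = 46)
  cl <- cluster_zmatrix(m)
  expect_true(all(diff(cl$row_hclust$height) >= -1e-12))
  expect_true(all(cophenetic(cl$row_hclust) >= 0))
})

test_that("clustering rejects degenerate inputs", {
  m <- block_matrix()
  expect_error(cluster_zmatrix(m[1, , drop = FALSE], axis = "rows"), "at least 2")
  m_na <- m
  m_na["P001", ] <- NA_real_
  expect_error(cluster_zmatrix(m_na), "all-missing")
  m_dup <- m
  rownames(m_dup)[2] <- "P001"
  expect_error(cluster_zmatrix(m_dup), "unique rownames")
})

test_that("heat-map export writes image, bit-exact TSV and Newick trees", {
  m <- block_matrix(seed = 47, n_up = 4, n_down = 4)
  m["P002", "z_hl.rep2"] <- NA # rendered as missing, imputed only for distances
  cl <- cluster_zmatrix(m)
  img <- withr::local_tempfile(fileext = ".pdf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  render_heatmap(cl, img, tsv_path = tsv, newick_path = nwk)
  expect_true(file.size(img) > 0)
  back <- readr::read_tsv(tsv, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  rt <- as.matrix(as.data.frame(lapply(back[, -1], as.numeric)))
  dimnames(rt) <- list(back$protein, colnames(back)[-1])
  expect_identical(rt, cl$matrix)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, rownames(m))
})

test_that("regulated-protein z matrices come out of the pipeline with replicate columns", {
  cfg <- sim_config(n_proteins = 300, seed = 50)
  sim <- simulate_evidence(cfg)
  res <- silac_differential(sim$evidence)
  m <- zscore_matrix(res)
  expect_true(all(c("z_ml.rep1", "z_ml.rep2", "z_hl.rep1", "z_hl.rep2") %in% colnames(m)))
  rec <- tidy(res)
  expect_setequal(rownames(m),
                  rec$protein[rec$direction_ml != "none" | rec$direction_hl != "none"])
})
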
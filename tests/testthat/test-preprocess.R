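test_that("normalize_total rescales cells exactly and proportionally", {
  m <- lem(c(1, 3, 0, 2500, 7500, 0), 3, 2, labels = c(0L, 1L))
  out <- normalize_total(m, 1e4)
  expect_equal(out$counts[, 1], c(g01 = 2500, g02 = 7500, g03 = 0))
  # a cell already at the target is unchanged
  expect_identical(out$counts[, 2], m$counts[, 2])

  r <- random_lem(50, 30, seed = 7)
  rn <- normalize_total(r, 1e4)
  expect_true(all(abs(colSums(rn$counts) - 1e4) <= 1e-9 * 1e4))
  # within-cell proportions preserved
  ratios_in <- r$counts[2, ] / r$counts[1, ]
  ratios_out <- rn$counts[2, ] / rn$counts[1, ]
  expect_true(all(abs(ratios_in - ratios_out) <= 1e-12 * abs(ratios_in)))

  m0 <- lem(c(0, 0, 1, 1), 2, 2, labels = c(0L, 1L))
  expect_error(normalize_total(m0), "zero total.*c01")
})

test_that("log1p transform has the analytic fixed points", {
  m <- lem(c(0, exp(1) - 1, 0, 0), 2, 2, labels = c(0L, 1L))
  out <- log1p_transform(m)
  expect_equal(out$counts[1, 1], 0)
  expect_equal(out$counts[2, 1], 1)
  z <- lem(rep(0, 6), 3, 2, labels = c(0L, 1L))
  expect_equal(log1p_transform(z)$counts, z$counts)
  neg <- z; neg$counts[1, 1] <- -1
  expect_error(log1p_transform(neg), "non-negative")
})

test_that("select_hvg recovers planted variable genes", {
  # 3 genes differ strongly between two cell states at the same overall
  # mean as the 47 constant-rate genes, so the mean-variance trend is fit
  # from the bulk and the planted genes stand out by excess variance
  set.seed(12)
  n <- 60; ng <- 50
  state <- rep(c(0, 1), each = n / 2)
  counts <- matrix(rpois(ng * n, 60), ng, n,
                   dimnames = list(sprintf("g%02d", 1:ng), sprintf("c%02d", 1:n)))
  for (g in 1:3) {
    counts[g, state == 0] <- rpois(n / 2, 20)
    counts[g, state == 1] <- rpois(n / 2, 100)
  }
  m <- LabeledExpressionMatrix(counts, labels = state)
  top3 <- select_hvg(m, 3)
  expect_setequal(top3, c("g01", "g02", "g03"))

  # n_hvg = n_genes returns everything; repeated calls are deterministic
  expect_setequal(select_hvg(m, ng), rownames(counts))
  expect_identical(select_hvg(m, 5), select_hvg(m, 5))

  # exchangeable genes: contract is a deterministic subset of the right size
  r <- random_lem(40, 50, seed = 3)
  expect_length(select_hvg(r, 15), 15)

  # zero-variance genes cannot be requested
  mostly_const <- lem(c(rbind(c(1, 9, 3, 7), 5, 2)), 3, 4,
                      labels = c(0L, 0L, 1L, 1L))
  expect_error(select_hvg(mostly_const, 2), "nonzero variance")
  one_cell <- lem(1:3, 3, 1, labels = 0L)
  expect_error(select_hvg(one_cell, 1), "at least 2 cells")
})

test_that("HVG selection agrees with the reference vst implementation", {
  skip_if_not_installed("Seurat")
  set.seed(12)
  n <- 200; ng <- 300
  rates <- rlnorm(ng, meanlog = 3, sdlog = 0.8)
  counts <- matrix(rpois(ng * n, rates), ng, n,
                   dimnames = list(sprintf("g%03d", 1:ng), sprintf("c%03d", 1:n)))
  state <- rep(c(0L, 1L), each = n / 2)
  mid <- order(abs(rates - median(rates)))[1:5]  # planted at mid-range means
  for (g in mid) {
    counts[g, state == 0] <- rpois(n / 2, rates[g] / 3)
    counts[g, state == 1] <- rpois(n / 2, rates[g] * 5 / 3)
  }
  ours <- select_hvg(LabeledExpressionMatrix(counts, state), 10)
  hv <- Seurat::FindVariableFeatures(counts, selection.method = "vst",
                                     loess.span = 0.3, verbose = FALSE)
  theirs <- rownames(hv)[order(-hv$variance.standardized, rownames(hv))][1:10]
  expect_identical(ours, theirs)
})

test_that("scaling yields population mean 0 / variance 1, constants zero", {
  m <- lem(c(1, 5, 2, 5, 3, 5), 2, 3, labels = c(0L, 0L, 1L))
  out <- scale_unit_variance(m)
  expect_equal(mean(out$counts[1, ]), 0, tolerance = 1e-12)
  expect_equal(mean(out$counts[1, ]^2), 1, tolerance = 1e-9)  # ddof 0
  expect_identical(out$counts[2, ], c(c01 = 0, c02 = 0, c03 = 0))

  # clipping caps an extreme outlier at the bound
  set.seed(5)
  v <- c(rnorm(999, mean = 50), 5000)
  big <- lem(v, 1, 1000, labels = rep(c(0L, 1L), 500), gene_ids = "g1")
  clipped <- scale_unit_variance(big, clip = 10)
  expect_equal(max(abs(clipped$counts)), 10)
})

test_that("PCA matches a direct covariance eigensolve up to sign", {
  set.seed(21)
  m <- random_lem(10, 20, seed = 21)    # 20 cells x 10 genes
  sc <- scale_unit_variance(log1p_transform(m))
  emb <- pca_embed(sc, preprocess_config(n_components = 5))

  X <- t(sc$counts)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(Xc) / 1)       # eigensolve of the scatter matrix
  scores_oracle <- Xc %*% eig$vectors[, 1:5]
  for (k in 1:5) {
    a <- emb$coordinates[, k]; b <- scores_oracle[, k]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  # explained variance ratios agree with the eigenvalue shares
  expect_equal(emb$explained_variance_ratio,
               (eig$values / sum(eig$values))[1:5], tolerance = 1e-10)
})

test_that("PCA basics: separation, rank deficiency, sign convention, determinism", {
  # two clouds split along three of five gene axes, so the between-cloud
  # direction dominates the unit-variance noise spectrum
  set.seed(31)
  n <- 40
  counts <- matrix(rnorm(5 * n, 10), 5, n,
                   dimnames = list(sprintf("g%02d", 1:5), sprintf("c%02d", 1:n)))
  grp <- rep(c(0, 1), each = n / 2)
  counts[1:3, grp == 1] <- counts[1:3, grp == 1] + 50
  m <- LabeledExpressionMatrix(abs(counts), labels = grp)
  emb <- pca_embed(scale_unit_variance(m), preprocess_config(n_components = 2))
  pc1 <- emb$coordinates[, 1]
  thr <- mean(pc1)
  expect_true(all((pc1 > thr) == (grp == 1)) || all((pc1 > thr) == (grp == 0)))
  expect_gt(emb$explained_variance_ratio[1], emb$explained_variance_ratio[2])

  # rank-1 data: first component carries ~all variance
  v <- outer(1:4, seq(0, 3, length.out = 12))
  rank1 <- lem(as.numeric(v) + 0, 4, 12, labels = rep(c(0L, 1L), 6))
  e1 <- pca_embed(rank1, preprocess_config(n_components = 3))
  expect_gt(e1$explained_variance_ratio[1], 1 - 1e-10)

  # sign convention: the largest-magnitude loading is positive
  expect_true(all(apply(emb$gene_loadings, 2,
                        function(w) w[which.max(abs(w))] > 0)))

  # determinism: identical inputs give identical embeddings
  e2 <- pca_embed(scale_unit_variance(m), preprocess_config(n_components = 2))
  expect_identical(e2$coordinates, emb$coordinates)

  expect_error(pca_embed(m, preprocess_config(n_components = 50)),
               "n_components exceeds")
})

test_that("full-rank PCA preserves pairwise distances (rank-3 fixture)", {
  set.seed(41)
  W <- matrix(rnorm(8 * 3), 8, 3)        # 8 genes spanned by 3 factors
  H <- matrix(rnorm(3 * 15), 3, 15)      # 15 cells
  X <- W %*% H
  m <- lem(as.numeric(X - min(X)), 8, 15, labels = rep(c(0L, 1L), length.out = 15))
  emb <- pca_embed(m, preprocess_config(n_components = 3))
  D_orig <- dist(scale(t(m$counts), center = TRUE, scale = FALSE))
  D_pca <- dist(emb$coordinates)
  expect_equal(as.numeric(D_pca), as.numeric(D_orig), tolerance = 1e-9)
})

test_that("embedding CSV round-trips coordinates", {
  m <- random_lem(12, 10, seed = 9)
  emb <- pca_embed(scale_unit_variance(log1p_transform(normalize_total(m))),
                   preprocess_config(n_components = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_embedding_csv(emb, f)
  emb2 <- read_embedding_csv(f)
  expect_identical(emb2$cell_ids, emb$cell_ids)
  expect_equal(unname(emb2$coordinates), unname(emb$coordinates),
               tolerance = 1e-12)
})
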
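test_that("generation is a pure, reproducible function of the config", {
  cfg <- synthetic_config(n_control = 80, n_treated = 40, n_genes = 150,
                          seed = 7)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(s1$truth$cells, s2$truth$cells)

  s3 <- simulate_expression(synthetic_config(n_control = 80, n_treated = 40,
                                             n_genes = 150, seed = 8))
  expect_false(identical(s1$matrix$counts, s3$matrix$counts))
})

test_that("arms, labels, technical features and ground truth are consistent", {
  cfg <- synthetic_config(n_control = 120, n_treated = 50, n_genes = 200,
                          n_mito_genes = 8, n_cmo_features = 3, seed = 5)
  sim <- simulate_expression(cfg)
  m <- sim$matrix; truth <- sim$truth

  expect_identical(sum(m$labels == 0L), 120L)
  expect_identical(sum(m$labels == 1L), 50L)
  expect_identical(sum(startsWith(gene_ids(m), "MT-")), 8L)
  expect_identical(sum(startsWith(gene_ids(m), "CMO")), 3L)
  expect_identical(nrow(m$counts), 200L + 8L + 3L)

  # treated cells are all resistant; control sensitive count = round(f * n)
  trt_states <- truth$cells$true_state[match(names(m$labels)[m$labels == 1L],
                                             truth$cells$cell_id)]
  expect_true(all(trt_states == "resistant"))
  ctrl_states <- truth$cells$true_state[match(names(m$labels)[m$labels == 0L],
                                              truth$cells$cell_id)]
  expect_equal(sum(ctrl_states == "sensitive"), round(0.25 * 120))

  expect_identical(sum(truth$genes$role == "signal"), 10L)
  expect_identical(sum(truth$genes$role == "mito"), 8L)

  # mitochondrial mass sits near the intended 5 % share
  mito_frac <- colSums(m$counts[startsWith(gene_ids(m), "MT-"), ]) /
    colSums(m$counts)
  expect_lt(abs(mean(mito_frac) - 0.05), 0.02)
})

test_that("planted effect sizes are realized at the configured magnitude", {
  sim <- simulate_expression(synthetic_config(seed = 13))
  m <- sim$matrix; truth <- sim$truth
  ctrl <- truth$cells[match(names(m$labels)[m$labels == 0L], truth$cells$cell_id), ]
  sens_cells <- ctrl$cell_id[ctrl$true_state == "sensitive"]
  res_cells <- ctrl$cell_id[ctrl$true_state == "resistant"]
  expect_identical(length(sens_cells), 250L)

  sig <- truth$genes$gene_id[truth$genes$role == "signal"]
  lfc <- log2(rowMeans(m$counts[sig, sens_cells]) /
              rowMeans(m$counts[sig, res_cells]))
  expect_true(all(abs(abs(lfc) - 2) < 0.3))
})

test_that("degenerate sensitive fractions behave as the limits dictate", {
  # f = 0: arms are exchangeable; per-gene rank tests reject at chance rate
  sim0 <- simulate_expression(synthetic_config(
    n_control = 150, n_treated = 150, n_genes = 300, sensitive_fraction = 0,
    seed = 17))
  m0 <- sim0$matrix
  expect_true(all(sim0$truth$cells$true_state == "resistant"))
  # compare depth-normalized values: depth draws are shared across genes, so
  # raw-count tests would all inherit one random library-size fluctuation
  mn <- normalize_total(m0)
  set.seed(18)
  genes <- sample(gene_ids(mn), 100)
  p <- vapply(genes, function(g)
    stats::wilcox.test(mn$counts[g, mn$labels == 0L],
                       mn$counts[g, mn$labels == 1L], exact = FALSE)$p.value,
    numeric(1))
  expect_lte(sum(p < 0.01), 6)  # ~1 expected under the null

  # f = 1, large effect: control scores are uniformly far from treated
  sim1 <- simulate_expression(synthetic_config(
    n_control = 100, n_treated = 60, n_genes = 300, sensitive_fraction = 1,
    log2_effect = 3, n_signal_genes = 20, seed = 19))
  prep <- preprocess(drop_technical_features(sim1$matrix),
                     preprocess_config(n_hvg = 250, n_components = 15))
  lab <- prep$lognorm$labels
  D <- pairwise_distances(prep$embedding, names(lab)[lab == 0L],
                          names(lab)[lab == 1L])
  ctrl_scores <- similarity_scores(D, "min")
  # within-treated nearest-neighbour distances are far smaller
  Dtt <- pairwise_distances(prep$embedding, names(lab)[lab == 1L][1:30],
                            names(lab)[lab == 1L][31:60])
  expect_gt(min(ctrl_scores), max(apply(Dtt, 1, min)))

  expect_warning(simulate_expression(synthetic_config(
    n_control = 30, n_treated = 10, n_genes = 100,
    sensitive_fraction = 0.01, seed = 23)), "zero sensitive")
})

test_that("survivor bias: treated cells match resistant controls when unshifted", {
  sim <- simulate_expression(synthetic_config(
    n_control = 400, n_treated = 200, n_genes = 300, seed = 29))
  m <- sim$matrix; truth <- sim$truth
  res_ctrl <- truth$cells$cell_id[truth$cells$true_state == "resistant" &
                                  truth$cells$cell_id %in% names(m$labels)[m$labels == 0L]]
  trt <- names(m$labels)[m$labels == 1L]
  mn <- normalize_total(m)
  set.seed(31)
  genes <- sample(gene_ids(mn), 100)
  p <- vapply(genes, function(g)
    stats::wilcox.test(mn$counts[g, res_ctrl], mn$counts[g, trt],
                       exact = FALSE)$p.value, numeric(1))
  # family-level: no enrichment of rejections beyond the nominal rate
  expect_lte(sum(p < 0.01), 6)
})

test_that("ground-truth CSVs are written alongside the matrix", {
  sim <- simulate_expression(synthetic_config(n_control = 40, n_treated = 20,
                                              n_genes = 80, seed = 37))
  pre <- file.path(withr::local_tempdir(), "gt")
  write_ground_truth_csv(sim$truth, pre)
  cells <- read.csv(paste0(pre, "_cells.csv"))
  genes <- read.csv(paste0(pre, "_genes.csv"))
  expect_identical(nrow(cells), 60L)
  expect_setequal(unique(genes$role), c("background", "signal", "mito", "cmo"))
})
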
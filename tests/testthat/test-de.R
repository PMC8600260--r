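test_that("expression filter matches direct evaluation of its rule", {
  sim <- simulate_counts(desk_config(n_genes = 300, seed = 41))
  m <- sim$counts
  m[1, ] <- 0L   # all-zero gene
  mask <- filter_expressed(m, sim$samples, min_cpm = 1, min_samples = 3)
  expect_false(mask[1])
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  oracle <- apply(cpm, 1, function(x) sum(x >= 1) >= 3)
  expect_identical(unname(mask), unname(oracle))

  rich <- m
  rich[2, ] <- as.integer(round(colSums(m) * 100 / 1e6))  # ~100 CPM everywhere
  expect_true(filter_expressed(rich, sim$samples)[2])
})

test_that("NB GLM reproduces closed-form fits", {
  # constant counts, Poisson, equal offsets -> fitted mean is the average
  fit <- fit_nb_glm(c(10, 10, 10, 10), design = matrix(1, 4, 1),
                    offsets = rep(0, 4), phi = 0)
  expect_equal(unname(fit$fitted), rep(10, 4), tolerance = 1e-8)
  expect_equal(fit$deviance, 0, tolerance = 1e-10)

  # 4x difference between groups -> logFC exactly 2
  X <- cbind(1, c(0, 0, 1, 1))
  fit2 <- fit_nb_glm(c(5, 5, 20, 20), design = X, offsets = rep(0, 4), phi = 0.1)
  expect_equal(fit2$coefficients[2] / log(2), 2, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(fit2$fitted), c(5, 5, 20, 20), tolerance = 1e-6)
})

test_that("fitted deviance matches golden-section minimization on random genes", {
  set.seed(19)
  X <- cbind(1, rep(c(0, 1), each = 4))
  offsets <- log(runif(8, 0.8e6, 1.3e6))
  for (i in 1:30) {
    phi <- runif(1, 0, 0.5)
    mu <- exp(runif(1, 2, 6))
    y <- rnbinom(8, mu = mu * exp(offsets) / mean(exp(offsets)),
                 size = 1 / max(phi, 1e-8))
    y[y == 0] <- 1
    fit <- fit_nb_glm(y, X, offsets, phi)
    oracle <- oracle_two_group_deviance(y, X[, 2] == 1, offsets, phi)
    expect_equal(fit$deviance, oracle, tolerance = 1e-6)
  }
})

test_that("identical count rows receive identical dispersion estimates", {
  set.seed(23)
  y <- rnbinom(8, mu = 150, size = 5)
  m <- rbind(g1 = y, g2 = y,
             matrix(rnbinom(8 * 60, mu = 120, size = 5), 60, 8,
                    dimnames = list(sprintf("x%d", 1:60), NULL)))
  colnames(m) <- sprintf("s%d", 1:8)
  grp <- rep(c("A", "B"), each = 4)
  est <- estimate_dispersions(m, grp, offsets = log(colSums(m)),
                              ave_logcpm = rowMeans(log_cpm(m, factors = setNames(rep(1, 8), colnames(m)))$logcpm))
  expect_equal(unname(est$phi[1]), unname(est$phi[2]), tolerance = 1e-12)
  expect_equal(unname(est$squeezed_phi[1]), unname(est$squeezed_phi[2]),
               tolerance = 1e-12)
})

test_that("dispersion estimation recovers known truth", {
  set.seed(29)
  n <- 2000
  # Poisson data, 20 replicates per group -> squeezed dispersions near zero
  mu_p <- exp(runif(n, 3, 7))
  mp <- matrix(rpois(n * 40, rep(mu_p, 40)), n, 40,
               dimnames = list(sprintf("g%d", 1:n), sprintf("s%d", 1:40)))
  est_p <- estimate_dispersions(mp, rep(c("A", "B"), each = 20))
  expect_lt(median(est_p$squeezed_phi), 0.01)

  # phi = 0.2, 50 replicates per group
  mu_n <- exp(runif(n, 3, 7))
  mn <- matrix(rnbinom(n * 100, mu = rep(mu_n, 100), size = 5), n, 100,
               dimnames = list(sprintf("g%d", 1:n), sprintf("s%d", 1:100)))
  est_n <- estimate_dispersions(mn, rep(c("A", "B"), each = 50))
  expect_gt(median(est_n$squeezed_phi), 0.16)
  expect_lt(median(est_n$squeezed_phi), 0.24)
  # squeezed values sit between the raw and trend estimates
  lo <- pmin(est_n$phi, est_n$trend_phi) - 1e-10
  hi <- pmax(est_n$phi, est_n$trend_phi) + 1e-10
  expect_true(all(est_n$squeezed_phi >= lo & est_n$squeezed_phi <= hi))
})

test_that("exchanging the contrasted roles negates logFC and keeps p-values", {
  sim <- simulate_counts(desk_config(n_genes = 400, seed = 47))
  ab <- qlf_test(sim$counts, sim$samples, "W", "KM")
  ba <- qlf_test(sim$counts, sim$samples, "KM", "W")
  t <- ab$tested
  expect_identical(t, ba$tested)
  expect_equal(ab$logFC[t], -ba$logFC[t], tolerance = 1e-10)
  expect_equal(ab$p[t], ba$p[t], tolerance = 1e-10)
})

test_that("strong effects at moderate abundance are detected with high power", {
  cfg <- desk_config(n_genes = 1000, seed = 53, de_fraction = 0.15,
                     effect_size_logfc = 2)
  sim <- simulate_counts(cfg)
  de <- qlf_test(sim$counts, sim$samples, "W", "KM")
  mid <- sim$truth$is_de & sim$truth$baseline > 4 & de$tested
  expect_gte(mean(de$p[mid] < 0.05), 0.8)
})

test_that("BH adjustment dominates p and is monotone in p-rank", {
  sim <- simulate_counts(desk_config(n_genes = 500, seed = 59))
  de <- qlf_test(sim$counts, sim$samples, "W", "KM")
  p <- de$p[de$tested]; fdr <- de$fdr[de$tested]
  expect_true(all(fdr >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(fdr[o]) >= -1e-12))
  expect_equal(min(fdr), min(p.adjust(p, "BH")), tolerance = 1e-12)
})

test_that("a common offset shift leaves the fit invariant up to the intercept", {
  set.seed(61)
  X <- cbind(1, rep(c(0, 1), each = 3))
  off <- log(runif(6, 1e5, 2e5))
  y <- rnbinom(6, mu = 300, size = 5)
  f1 <- fit_nb_glm(y, X, off, phi = 0.1)
  f2 <- fit_nb_glm(y, X, off + log(3), phi = 0.1)
  expect_equal(f1$coefficients[2], f2$coefficients[2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-8)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-6)
})

test_that("DEG selection equals a brute-force filter and tags directions", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   logFC = c(0.3, -1.0, 2.0, -0.2),
                   ave_logcpm = 5, F = 1, df1 = 1, df2 = 5,
                   p = c(0.04, 0.04, 0.2, 0.001),
                   fdr = c(0.1, 0.1, 0.3, 0.01),
                   tested = TRUE)
  sel <- select_degs(de, p_threshold = 0.05, min_fold = 1.5)
  expect_identical(sel$gene, "b")          # |0.3| < log2(1.5); c fails p; d fails fold
  expect_identical(sel$direction, "down")

  sim <- simulate_counts(desk_config(n_genes = 600, seed = 67))
  der <- qlf_test(sim$counts, sim$samples, "W", "KM")
  sel2 <- select_degs(der, 0.05, 1.5)
  oracle <- der$gene[!is.na(der$p) & der$p < 0.05 & abs(der$logFC) > log2(1.5)]
  expect_setequal(sel2$gene, oracle)
})

test_that("results track edgeR's quasi-likelihood pipeline on shared input", {
  sim <- simulate_counts(desk_config(n_genes = 800, seed = 71, de_fraction = 0.1))
  mine <- qlf_test(sim$counts, sim$samples, "W", "KM")
  keep_ids <- mine$gene[mine$tested]

  grp <- sim$samples$group[match(colnames(sim$counts), sim$samples$sample_id)]
  use <- grp %in% c("W", "KM")
  y <- edgeR::DGEList(sim$counts[keep_ids, use],
                      group = factor(grp[use], levels = c("W", "KM")))
  y <- edgeR::calcNormFactors(y)
  design <- stats::model.matrix(~y$samples$group)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  res <- edgeR::glmQLFTest(fit)$table

  m <- mine[match(keep_ids, mine$gene), ]
  expect_gt(cor(m$logFC, res$logFC), 0.99)
  expect_gt(cor(m$p, res$PValue, method = "spearman"), 0.9)
  agree <- mean((m$p < 0.05) == (res$PValue < 0.05))
  expect_gt(agree, 0.9)
})
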
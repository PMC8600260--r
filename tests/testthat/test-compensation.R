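test_that("compensation coefficient identities hold", {
  expect_equal(compensation_coefficient(8, 4, 4), 100)
  expect_equal(compensation_coefficient(8, 8, 4), 0)
  expect_equal(compensation_coefficient(8, 6, 4), 50)
  expect_true(is.na(compensation_coefficient(5, 7, 5)))
})

test_that("the coefficient is invariant to adding a constant to all three means", {
  set.seed(83)
  km <- runif(200, 2, 10); z <- runif(200, 2, 10); w <- km - runif(200, 0.5, 3)
  for (const in c(-7, 0.3, 12)) {
    expect_equal(compensation_coefficient(km + const, z + const, w + const),
                 compensation_coefficient(km, z, w), tolerance = 1e-9)
  }
})

test_that("classification follows the compensated/over/uncompensated rule", {
  expect_identical(classify_compensation(100), "compensated")
  expect_identical(classify_compensation(150), "overcompensated")
  expect_identical(classify_compensation(-20), "uncompensated")
  expect_identical(classify_compensation(c(0.5, 0, NA, 100.0001)),
                   c("compensated", "uncompensated", "undefined", "overcompensated"))
})

test_that("fraction compensated counts coefficients in (lower, 100]", {
  rec <- data.frame(gene = letters[1:5],
                    coefficient = c(50, 99, -10, 120, 80),
                    comp_class = NA, de_p_km_w = c(0.001, 0.001, 0.001, 0.001, 0.5))
  fr <- fraction_compensated(rec, p_threshold = 0.01)
  expect_equal(fr$fraction, 0.5)
  expect_identical(fr$n, 4L)

  rec$coefficient <- 100
  expect_equal(fraction_compensated(rec, 0.01)$fraction, 1)

  rec$de_p_km_w <- 1
  fr0 <- fraction_compensated(rec, 0.01)
  expect_false(fr0$defined)
  expect_true(is.na(fr0$fraction))

  rec2 <- data.frame(gene = "a", coefficient = 0.5, comp_class = NA,
                     de_p_km_w = 0.001)
  expect_equal(fraction_compensated(rec2, 0.01, lower = 1)$fraction, 0)
  expect_equal(fraction_compensated(rec2, 0.01, lower = 0)$fraction, 1)
})

test_that("concordance matches exact antisymmetry and a rank-formula oracle", {
  set.seed(89)
  fc <- rnorm(50); fc[fc == 0] <- 0.1
  anti <- concordance(fc, -fc)
  expect_equal(anti$spearman_rho, -1)
  expect_equal(anti$opposite_fraction, 1)
  same <- concordance(fc, fc)
  expect_equal(same$spearman_rho, 1)
  expect_equal(same$opposite_fraction, 0)

  a <- c(1, 2, 3, 4); b <- c(3, 1, 4, 2)
  d <- rank(a) - rank(b)
  rho_oracle <- 1 - 6 * sum(d^2) / (4 * (16 - 1))
  expect_equal(concordance(a, b)$spearman_rho, rho_oracle, tolerance = 1e-12)

  expect_error(concordance(c(1, 2), c(2, 1)), ">=3")
})

test_that("coefficient density is a proper, symmetric Gaussian KDE", {
  d <- coefficient_density(c(40, 60))
  mid <- (d$grid[1] + d$grid[length(d$grid)]) / 2
  expect_equal(mid, 50, tolerance = 1e-9)
  expect_equal(d$density, rev(d$density), tolerance = 1e-9)

  set.seed(97)
  x <- c(rnorm(300, 80, 20), rnorm(100, 0, 30))
  dd <- coefficient_density(x)
  integral <- sum(diff(dd$grid) * (head(dd$density, -1) + dd$density[-1]) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)

  dg <- coefficient_density(c(50, 50, 50))
  expect_true(all(is.finite(dg$density)))
  expect_gt(dg$bandwidth, 0)
  expect_error(coefficient_density(numeric(0)), ">=2")
})

test_that("top partition matches a direct filter-sort oracle", {
  rec <- data.frame(gene = c("a", "b"), coefficient = c(60, 40),
                    comp_class = NA, de_p_km_w = c(0.01, 0.02))
  tp <- top_partition(rec, k = 50, cutoff = 50, p_threshold = 0.05)
  expect_identical(tp$compensated$gene, "a")
  expect_identical(tp$uncompensated$gene, "b")

  set.seed(101)
  rec2 <- data.frame(gene = sprintf("g%d", 1:200),
                     coefficient = runif(200, -50, 150),
                     comp_class = NA, de_p_km_w = runif(200))
  k <- 10
  tp2 <- top_partition(rec2, k = k, cutoff = 50, p_threshold = 0.5)
  degs <- rec2[rec2$de_p_km_w < 0.5, ]
  hi <- degs[degs$coefficient > 50, ]
  hi <- hi[order(hi$de_p_km_w), ][seq_len(min(k, sum(degs$coefficient > 50))), ]
  expect_setequal(tp2$compensated$gene, hi$gene)
  expect_true(all(diff(tp2$compensated$de_p_km_w) <= 0))   # highest p at top
  expect_true(all(tp2$uncompensated$coefficient <= 50))
  # k larger than available returns everything available
  tp3 <- top_partition(rec2, k = 1000, cutoff = 50, p_threshold = 0.5)
  expect_identical(nrow(tp3$compensated) + nrow(tp3$uncompensated), nrow(degs))
})

test_that("Z-scored rows have mean 0 and sd 1; constant rows are flagged", {
  norm <- structure(list(gene_ids = c("v", "c"), sample_ids = c("s1", "s2", "s3"),
                         logcpm = matrix(c(4, 5, 7, 5, 1, 5), 2, 3,
                                         dimnames = list(c("v", "c"), c("s1", "s2", "s3"))),
                         norm_factors = rep(1, 3), lib_sizes = rep(1e6, 3),
                         effective_lib_sizes = rep(1e6, 3), all_zero = c(FALSE, FALSE)),
                    class = "normalized_table")
  z <- zscore_rows(norm, c("v", "c"))
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(sd(z["v", ]), 1, tolerance = 1e-12)
  expect_true(all(z["c", ] == 0))
  expect_identical(unname(attr(z, "constant")), c(FALSE, TRUE))

  sim <- simulate_counts(desk_config(n_genes = 60, seed = 7))
  n2 <- log_cpm(sim$counts)
  z2 <- zscore_rows(n2, sim$truth$gene[1:30])
  expect_true(all(abs(rowMeans(z2)) < 1e-12))
  expect_true(all(abs(apply(z2, 1, sd) - 1) < 1e-12 | attr(z2, "constant")[1:30]))
})
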
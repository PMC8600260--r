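test_that("a null-configuration overlap gives p near 1", {
  universe <- sprintf("g%d", 1:100)
  set <- universe[1:10]
  lst <- universe[c(1, 2, 11:28)]   # overlap 2 = expected 10*20/100
  res <- fisher_set_test(set, lst, universe)
  expect_identical(res$overlap, 2L)
  expect_gt(res$p, 0.99)
})

test_that("fisher_set_test matches base fisher.test on random and extreme tables", {
  set.seed(103)
  for (i in 1:60) {
    N <- sample(5:60, 1)
    universe <- sprintf("u%d", 1:N)
    set <- sample(universe, sample(0:N, 1))
    lst <- sample(universe, sample(0:N, 1))
    mine <- fisher_set_test(set, lst, universe)
    expect_equal(mine$p, stats::fisher.test(mine$table)$p.value,
                 tolerance = 1e-9)
  }

  universe <- sprintf("u%d", 1:20)
  full <- fisher_set_test(universe[1:10], universe[1:10], universe)
  expect_equal(full$p, stats::fisher.test(full$table)$p.value, tolerance = 1e-12)

  disj <- fisher_set_test(c("x1", "x2"), universe[1:5], universe)
  expect_identical(disj$overlap, 0L)
  expect_equal(disj$p, stats::fisher.test(disj$table)$p.value, tolerance = 1e-12)

  expect_error(fisher_set_test("a", "b", character(0)), "empty universe")
})

test_that("enrich_all handles empty directions, orders members, rejects overlap", {
  universe <- sprintf("g%d", 1:40)
  sets <- list(S1 = universe[1:10], S2 = universe[11:30], S3 = c(universe[1:5], "zzz"))
  up <- universe[1:8]

  r <- enrich_all(sets, up = up, down = character(0), universe)
  expect_true(all(r$p_down == 1))
  expect_lt(r$p_up[r$set == "S1"], 0.05)
  expect_identical(r$direction_call[r$set == "S1"], "up")
  expect_identical(r$n_set_in_universe[r$set == "S3"], 5L)

  # order invariance: p depends only on the set, BH only on the p multiset
  r2 <- enrich_all(sets[c(2, 3, 1)], up = up, down = character(0), universe)
  expect_equal(r2$p_up[match(r$set, r2$set)], r$p_up, tolerance = 1e-12)
  expect_setequal(round(r2$fdr_up, 12), round(r$fdr_up, 12))

  logfc <- setNames(seq(2, -2, length.out = 40), universe)
  r3 <- enrich_all(sets, up, character(0), universe, logfc = logfc)
  mem <- strsplit(r3$members_by_logfc[r3$set == "S2"], ",")[[1]]
  expect_true(all(diff(logfc[mem]) <= 0))

  expect_error(enrich_all(sets, up = universe[1:3], down = universe[3:5], universe),
               "overlap")
})

test_that("DEG-restricted enrichment uses only genes past the threshold", {
  # 30 DEGs (20 up, 10 down) plus sub-threshold genes
  de <- data.frame(gene = sprintf("g%d", 1:60),
                   logFC = c(rep(2, 20), rep(-2, 10), rep(0.1, 30)),
                   ave_logcpm = 5, F = 10, df1 = 1, df2 = 5,
                   p = c(rep(0.001, 30), rep(0.9, 30)),
                   fdr = NA_real_, tested = TRUE)
  sets <- list(up_biased = sprintf("g%d", c(1:12, 21)),
               down_biased = sprintf("g%d", c(21:28, 1)))
  r <- deg_gsea_lite(de, sets, p_threshold = 0.05)
  expect_lt(r$p_up[r$set == "up_biased"], r$p_down[r$set == "up_biased"])
  expect_identical(r$direction_call[r$set == "up_biased"], "up")
  expect_lt(r$p_down[r$set == "down_biased"], r$p_up[r$set == "down_biased"])

  # adding sub-threshold genes changes nothing
  de2 <- rbind(de, data.frame(gene = sprintf("extra%d", 1:20), logFC = 3,
                              ave_logcpm = 5, F = 10, df1 = 1, df2 = 5,
                              p = 0.5, fdr = NA_real_, tested = TRUE))
  r2 <- deg_gsea_lite(de2, sets, p_threshold = 0.05)
  expect_equal(r2$p_up, r$p_up, tolerance = 1e-12)

  r0 <- deg_gsea_lite(de, sets, p_threshold = 1e-9)
  expect_identical(nrow(r0), 0L)
  expect_true(attr(r0, "empty"))
})

test_that("venn partitions match brute-force membership enumeration", {
  v <- venn(list(A = "a", B = "b"))
  expect_identical(unname(v[c("A_only", "B_only", "A_and_B")]), c(1L, 1L, 0L))

  v2 <- venn(list(A = c("x", "y"), B = c("x", "y")))
  expect_identical(unname(v2["A_and_B"]), 2L)
  expect_identical(sum(v2[c("A_only", "B_only")]), 0L)

  set.seed(107)
  pool <- sprintf("g%d", 1:60)
  sets <- list(K = sample(pool, 30), L = sample(pool, 25), M = sample(pool, 20))
  v3 <- venn(sets)
  union <- unique(unlist(sets))
  expect_identical(sum(v3), length(union))
  expect_identical(attr(v3, "union_size"), length(union))
  # brute force each exclusive region
  inK <- union %in% sets$K; inL <- union %in% sets$L; inM <- union %in% sets$M
  expect_identical(unname(v3["K_only"]), sum(inK & !inL & !inM))
  expect_identical(unname(v3["K_and_L"]), sum(inK & inL & !inM))
  expect_identical(unname(v3["K_and_L_and_M"]), sum(inK & inL & inM))
  # pairwise marginal recoverable from regions
  expect_identical(unname(v3["K_and_L"] + v3["K_and_L_and_M"]),
                   length(intersect(sets$K, sets$L)))

  expect_error(venn(list(A = "a", B = "b", C = "c", D = "d")), "2 or 3")
})
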
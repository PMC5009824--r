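test_that("the sorting score is the stated linear combination with valid weights", {
  # unit-vector decomposition at the published optimum
  expect_equal(son_score(1, 0, 0, 0.7, 0.3), 0.30)
  expect_equal(son_score(0, 1, 0, 0.7, 0.3), 0.49)
  expect_equal(son_score(0, 0, 1, 0.7, 0.3), 0.21)
  # alpha = 0 passes orthology through regardless of beta
  for (b in c(0, 0.4, 1)) expect_equal(son_score(0.37, 0.9, 0.1, 0, b), 0.37)
  # convex combination of ones is one
  expect_equal(son_score(1, 1, 1, 0.42, 0.77), 1)
  expect_error(son_score(1, 0, 0, alpha = 1.2, beta = 0.3), "alpha")
  expect_error(son_score(1, 0, 0, alpha = 0.5, beta = -0.1), "beta")
})

test_that("the score is monotone and linear in its components", {
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    x <- runif(3)
    base <- son_score(x[1], x[2], x[3], a, b)
    eps <- 0.05
    expect_gte(son_score(x[1] + eps, x[2], x[3], a, b), base)
    expect_gte(son_score(x[1], x[2] + eps, x[3], a, b), base)
    expect_gte(son_score(x[1], x[2], x[3] + eps, a, b), base)
    expect_equal(son_score(2 * x[1], 2 * x[2], 2 * x[3], a, b), 2 * base)
  }
})

test_that("ranking is a descending permutation with identifier tie-break", {
  expect_equal(rank_proteins(c(a = 0.9, b = 0.1, c = 0.5)),
               c(a = 1L, b = 3L, c = 2L))
  ties <- stats::setNames(rep(0.3, 6), c("f", "b", "d", "a", "e", "c"))
  r <- rank_proteins(ties)
  expect_equal(names(sort(r)), letters[1:6])
  set.seed(43)
  pr <- stats::setNames(runif(50), sprintf("p%02d", 1:50))
  expect_setequal(rank_proteins(pr), 1:50)
})

test_that("top-k selection size uses the ceiling convention", {
  expect_equal(top_k_count(100, 10), 10L)
  expect_equal(top_k_count(7, 50), 4L)
  expect_equal(top_k_count(1, 100), 1L)
})

test_that("son() produces a complete, deterministic score table", {
  b <- simulate_benchmark(n_proteins = 150, seed = 8)
  fit1 <- son(b$network, b$localization, b$orthologs)
  fit2 <- son(b$network, b$localization, b$orthologs)
  expect_identical(fit1$scores, fit2$scores)
  s <- fit1$scores
  expect_setequal(s$protein, b$network$nodes)
  expect_setequal(s$rank, seq_len(nrow(s)))
  expect_true(all(diff(s$pr) <= 1e-12)) # rank order is pr descending
  expect_true(all(s$pr >= 0 & s$pr <= 1))
  expect_true(all(s$NNC >= 0 & s$NNC <= 1))
  expect_true(all(s$NSL >= 0 & s$NSL <= 1))
  expect_true(all(s$NOS >= 0 & s$NOS <= 1))
  # pr recomputes from the stored components
  expect_equal(s$pr, son_score(s$NOS, s$NSL, s$NNC, 0.7, 0.3))
})

test_that("boundary parameter settings reduce to single-component rankings", {
  b <- simulate_benchmark(n_proteins = 200, seed = 15)
  comp <- sonrank:::son_components(b$network, b$localization, b$orthologs)
  fits <- list(
    nnc = son(b$network, b$localization, b$orthologs, alpha = 1, beta = 1),
    nsl = son(b$network, b$localization, b$orthologs, alpha = 1, beta = 0),
    nos = son(b$network, b$localization, b$orthologs, alpha = 0, beta = 0.6)
  )
  expect_equal(coef(fits$nnc)[names(comp$nnc)], comp$nnc)
  expect_equal(coef(fits$nsl)[names(comp$nsl)], comp$nsl)
  expect_equal(coef(fits$nos)[names(comp$nos)], comp$nos)
  expect_identical(ranked_proteins(fits$nnc), ranked_proteins(comp$nnc))
  expect_identical(ranked_proteins(fits$nsl), ranked_proteins(comp$nsl))
  expect_identical(ranked_proteins(fits$nos), ranked_proteins(comp$nos))
})

test_that("missing annotation sources zero the corresponding score with a warning", {
  b <- simulate_benchmark(n_proteins = 100, seed = 22)
  expect_warning(fit <- son(b$network, orthologs = b$orthologs), "NSL")
  expect_true(all(fit$scores$NSL == 0))
  expect_warning(fit2 <- son(b$network, localization = b$localization), "NOS")
  expect_true(all(fit2$scores$NOS == 0))
})

test_that("son object methods expose scores, predictions and summaries", {
  b <- simulate_benchmark(n_proteins = 100, seed = 5)
  fit <- son(b$network, b$localization, b$orthologs)
  expect_equal(unname(coef(fit)), fit$scores$pr)
  expect_equal(predict(fit, top_percent = 10), fit$scores$protein[1:10])
  expect_identical(as.data.frame(fit), fit$scores)
  expect_output(print(fit), "SON essentiality ranking")
  expect_output(print(summary(fit)), "location correlation")
})

test_that("the parameter grid is consistent with standalone fits and beta-invariant at alpha 0", {
  b <- simulate_benchmark(n_proteins = 150, seed = 12)
  grid <- son_grid(b$network, b$localization, b$orthologs, gold = b$essential,
                   alphas = c(0, 0.7), betas = c(0, 0.3, 1),
                   percents = c(10, 25))
  expect_equal(nrow(grid), 6L)
  a0 <- grid[grid$alpha == 0, c("top_10", "top_25")]
  expect_true(all(vapply(a0, function(col) length(unique(col)) == 1L, logical(1))))

  cell <- grid[grid$alpha == 0.7 & grid$beta == 0.3, ]
  fit <- son(b$network, b$localization, b$orthologs, alpha = 0.7, beta = 0.3)
  counts <- topk_essential_counts(fit, b$essential, percents = c(10, 25))
  expect_equal(c(cell$top_10, cell$top_25), unname(counts))

  expect_error(son_grid(b$network, b$localization, b$orthologs,
                        gold = b$essential, alphas = numeric(0)), "empty")
})
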
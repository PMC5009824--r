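test_that("extreme-set selection sizes and tie-breaks are deterministic", {
  scores <- stats::setNames(runif(100), sprintf("p%03d", 1:100))
  sets <- select_extreme_sets(scores, 5)
  expect_length(sets$top, 5L)
  expect_length(sets$bottom, 5L)
  expect_length(intersect(sets$top, sets$bottom), 0L)

  ties <- stats::setNames(rep(0.5, 10), letters[10:1])
  sets <- select_extreme_sets(ties, 50)
  expect_equal(sets$top, letters[1:5])
  expect_equal(sets$bottom, letters[6:10])

  expect_error(select_extreme_sets(numeric(0), 5), "empty")
})

make_ann <- function(...) annotation_map(list(...))

test_that("LCC piecewise branches evaluate as defined", {
  # top t1..t10 all in L; bottom only b1..b5 in L -> f=10, h=5 -> 10/5 - 1 = 1
  top <- sprintf("t%02d", 1:10)
  bottom <- sprintf("b%02d", 1:10)
  ann <- annotation_map(c(
    stats::setNames(rep(list("L"), 10), top),
    stats::setNames(rep(list("L"), 5), bottom[1:5])
  ))
  tab <- compute_lcc_table(top, bottom, ann)
  expect_equal(tab$f, 10L)
  expect_equal(tab$h, 5L)
  expect_equal(tab$lcc, 1)

  # reversed: f=5, h=10 -> 1 - 10/5 = -1
  tab2 <- compute_lcc_table(bottom, top, ann)
  expect_equal(tab2$lcc, -1)

  # equality f = h -> 0 through the positive branch
  ann3 <- annotation_map(c(
    stats::setNames(rep(list("L"), 7), top[1:7]),
    stats::setNames(rep(list("L"), 7), bottom[1:7])
  ))
  expect_equal(compute_lcc_table(top, bottom, ann3)$lcc, 0)
})

test_that("zero-denominator substitution follows the branch-restricted policies", {
  top <- sprintf("t%02d", 1:10)
  bottom <- sprintf("b%02d", 1:10)
  entries <- list()
  add <- function(entries, prots, loc) {
    for (p in prots) entries[[p]] <- c(entries[[p]], loc)
    entries
  }
  # L1: f=2, h=4 -> 1 - 2 = -1 ; L2: f=1, h=4 -> -3 ; L3: f=0, h=2 (substituted)
  # L4: f=3, h=1 -> 2          ; L5: f=2, h=0 (substituted from positive pool)
  entries <- add(entries, top[1:2], "L1"); entries <- add(entries, bottom[1:4], "L1")
  entries <- add(entries, top[3], "L2");   entries <- add(entries, bottom[5:8], "L2")
  entries <- add(entries, bottom[9:10], "L3")
  entries <- add(entries, top[4:6], "L4"); entries <- add(entries, bottom[1], "L4")
  entries <- add(entries, top[7:8], "L5")
  ann <- annotation_map(entries)

  lit <- compute_lcc_table(top, bottom, ann, lcc_zero_policy = "literal")
  lit <- stats::setNames(lit$lcc, lit$location)
  expect_equal(lit[["L1"]], -1)
  expect_equal(lit[["L2"]], -3)
  expect_equal(lit[["L3"]], -1) # max over the negative branch {-1, -3}
  expect_equal(lit[["L4"]], 2)
  expect_equal(lit[["L5"]], 2)  # max over the positive branch {2}

  sym <- compute_lcc_table(top, bottom, ann, lcc_zero_policy = "symmetric_extreme")
  sym <- stats::setNames(sym$lcc, sym$location)
  expect_equal(sym[["L3"]], -3) # most extreme negative value
  expect_equal(sym[["L5"]], 2)  # positive branch unchanged

  # empty substitution pools give 0
  ann2 <- make_ann(t01 = "Lpos", b01 = "Lneg")
  tab2 <- compute_lcc_table(top, bottom, ann2)
  tab2 <- stats::setNames(tab2$lcc, tab2$location)
  # Lpos: f=1, h=0, positive pool empty (no location with h>0, f>=h) -> 0
  expect_equal(tab2[["Lpos"]], 0)
  # Lneg: f=0, h=1, negative pool empty -> 0
  expect_equal(tab2[["Lneg"]], 0)
})

test_that("SL sums location coefficients and defaults to 0 when unannotated", {
  lcc <- data.frame(location = c("L1", "L2", "L3"), f = 1L, h = 1L,
                    lcc = c(1, -1, 0.4))
  ann <- make_ann(a = c("L1", "L2"), b = "L3")
  sl <- compute_sl(ann, lcc, nodes = c("a", "b", "c"))
  expect_equal(sl, c(a = 0, b = 0.4, c = 0))
})

test_that("NSL normalization matches its shifted/rescaled definition", {
  expect_equal(normalize_nsl(c(a = 2, b = -2, c = 0)),
               c(a = 1, b = 0, c = 0.5))
  expect_equal(normalize_nsl(c(a = 0, b = 0)), c(a = 0, b = 0))
  expect_equal(normalize_nsl(c(a = 3)), c(a = 1))
  expect_equal(normalize_nsl(c(a = -1, b = -1)), c(a = 0, b = 0))
  set.seed(5)
  for (i in 1:20) {
    sl <- stats::setNames(rnorm(30), sprintf("p%02d", 1:30))
    nsl <- normalize_nsl(sl)
    expect_true(all(nsl >= 0 & nsl <= 1 + 1e-12))
    expect_equal(unname(nsl[which.max(sl)]), 1)
    expect_equal(order(nsl), order(sl)) # order preserved
  }
})

test_that("LCC is identical whether f,h are counts or within-set fractions", {
  set.seed(9)
  for (i in 1:20) {
    m <- sample(5:40, 1L)
    f <- sample(0:m, 8L, replace = TRUE)
    h <- sample(0:m, 8L, replace = TRUE)
    from_counts <- sonrank:::lcc_values(f, h)
    from_fracs <- sonrank:::lcc_values(f / m, h / m)
    expect_equal(from_counts, from_fracs)
  }
})

test_that("LCC is monotone in f for fixed h and flips branch under set swap", {
  h <- 6L
  vals <- sonrank:::lcc_values(0:12, rep(h, 13L))
  finite_defined <- 2:13 # f >= 1
  expect_true(all(diff(vals[finite_defined]) >= 0))

  # swap: a strictly positive-branch location becomes negative-branch
  f <- c(9L, 2L); h2 <- c(3L, 5L)
  fwd <- sonrank:::lcc_values(f, h2)
  bwd <- sonrank:::lcc_values(h2, f)
  expect_gt(fwd[1L], 0)
  expect_lt(bwd[1L], 0)
})
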
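test_that("design matrices encode the model equation", {
  q <- c(2, 2, 4, 4)
  d <- design_matrices(c("A", "A", "B", "B"), q, model_spec("poisson", "term"))
  expect_equal(colnames(d$full), c("intercept", "logq", "yB"))
  expect_equal(colnames(d$null), c("intercept", "logq"))
  expect_equal(unname(d$full[, "logq"]), log(q))
  expect_equal(d$df_test, 1)
  expect_equal(d$offset, rep(0, 4))
  # continuous outcome: one column, identity s_k
  y <- c(0.1, 0.5, 0.9, 1.3)
  dc <- design_matrices(y, q, model_spec("gaussian", "term"))
  expect_equal(unname(dc$full[, "y"]), y)
  expect_equal(dc$df_test, 1)
  # offset mode: log(q) is a fixed offset, not a column
  do <- design_matrices(c("A", "A", "B", "B"), q, model_spec("poisson", "offset"))
  expect_equal(do$offset, log(q))
  expect_equal(colnames(do$full), c("intercept", "yB"))
  # K groups give K - 1 test columns
  d3 <- design_matrices(c("A", "A", "B", "B", "C", "C"), rep(1, 6),
                        model_spec("poisson", "offset"))
  expect_equal(d3$df_test, 2)
})

test_that("degenerate outcomes are rejected, constant log(q) term dropped", {
  expect_error(design_matrices(c("A", "A", "A"), rep(1, 3), model_spec()),
               "no contrast")
  expect_error(design_matrices(rep(2.5, 3), rep(1, 3), model_spec()),
               "no contrast")
  expect_warning(
    d <- design_matrices(c("A", "B"), c(3, 3), model_spec("poisson", "term")),
    "constant")
  expect_equal(colnames(d$null), "intercept")
})

test_that("two-group Poisson deviances match the closed form", {
  grp <- c("A", "A", "B", "B")
  cases <- list(c(10, 12, 30, 28), c(0, 0, 5, 5), c(3, 3, 3, 3), c(50, 1, 2, 60))
  for (y in cases) {
    cts <- matrix(y, nrow = 1, dimnames = list("g", paste0("s", 1:4)))
    r <- de_test(cts, grp, factors = rep(1, 4), family = "poisson")
    expect_equal(r$D, closed_form_two_group_D(y, grp), tolerance = 1e-6)
  }
  # the worked constants: group-mean MLEs give 2[22 log(11/20) + 58 log(29/20)]
  r <- de_test(matrix(c(10, 12, 30, 28), 1, dimnames = list("g", NULL)),
               grp, factors = rep(1, 4), family = "poisson")
  expect_equal(r$D, 2 * (22 * log(11 / 20) + 58 * log(29 / 20)), tolerance = 1e-8)
  r0 <- de_test(matrix(c(0, 0, 5, 5), 1, dimnames = list("g", NULL)),
                grp, factors = rep(1, 4), family = "poisson")
  expect_equal(r0$D, 2 * 10 * log(2), tolerance = 1e-8)
})

test_that("no variation means no signal: D = 0, p = 1", {
  cts <- matrix(7, nrow = 2, ncol = 4,
                dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  for (fam in c("poisson", "gaussian")) {
    r <- de_test(cts, c("A", "A", "B", "B"), factors = rep(2, 4), family = fam)
    expect_equal(r$D, c(0, 0))
    expect_equal(r$p_asymptotic, c(1, 1))
  }
})

test_that("equal factors in offset mode reduce to no normalization", {
  set.seed(11)
  cts <- matrix(rpois(40, 30), nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  grp <- c("A", "A", "B", "B")
  for (fam in c("poisson", "gaussian")) {
    a <- de_test(cts, grp, factors = rep(5, 4), family = fam)
    b <- de_test(cts, grp, factors = rep(1, 4), family = fam)
    expect_equal(a$D, b$D, tolerance = 1e-8)
  }
})

test_that("Gaussian two-group D is monotone in the squared pooled t statistic", {
  set.seed(12)
  grp <- c(rep("A", 5), rep("B", 5))
  stats <- t(vapply(1:30, function(i) {
    y <- rpois(10, 50)
    cts <- matrix(y, 1, dimnames = list("g", paste0("s", 1:10)))
    r <- de_test(cts, grp, factors = rep(1, 10), family = "gaussian")
    z <- log(y + 0.5)
    tt <- t.test(z[grp == "A"], z[grp == "B"], var.equal = TRUE)$statistic
    c(D = r$D, t2 = unname(tt)^2)
  }, c(D = 0, t2 = 0)))
  o <- order(stats[, "t2"])
  expect_true(all(diff(stats[o, "D"]) >= -1e-10))
})

test_that("invalid counts for the Poisson family are rejected", {
  grp <- c("A", "A", "B", "B")
  neg <- matrix(c(-1, 2, 3, 4), 1, dimnames = list("g", NULL))
  expect_error(de_test(neg, grp, factors = rep(1, 4), family = "poisson"),
               "negative")
  frac <- matrix(c(1.5, 2, 3, 4), 1, dimnames = list("g", NULL))
  expect_error(de_test(frac, grp, factors = rep(1, 4), family = "poisson"),
               "integer")
})

test_that("permuted null statistics have the right shape, multiset and determinism", {
  set.seed(13)
  cts <- matrix(rpois(60, 25), nrow = 6,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  grp <- rep(c("A", "B"), each = 5)
  n1 <- permute_null(cts, grp, rep(1, 10), family = "gaussian", B = 7, seed = 99)
  expect_equal(dim(n1$D0), c(6, 7))
  for (b in 1:7) {
    expect_equal(sort(grp[n1$perms[, b]]), sort(grp))
  }
  n2 <- permute_null(cts, grp, rep(1, 10), family = "gaussian", B = 7, seed = 99)
  expect_identical(n1$D0, n2$D0)
  expect_error(permute_null(cts, grp, rep(1, 10), B = 0), "B must be")
})

test_that("threaded per-gene fitting reproduces serial results exactly", {
  set.seed(14)
  cts <- matrix(rpois(200, 40), nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  grp <- rep(c("A", "B"), each = 5)
  a <- de_test(cts, grp, factors = NULL, family = "poisson", threads = 1)
  b <- de_test(cts, grp, factors = NULL, family = "poisson", threads = 4)
  expect_identical(a, b)
})

test_that("pooled permutation p-values follow the exceedance formula", {
  # floor: an observed value above every null
  expect_equal(permutation_pvalues(10, matrix(1:4, 2)), 1 / 5)
  # hand-counted: m = 2, B = 2
  expect_equal(permutation_pvalues(c(5, 1), matrix(c(0, 2, 3, 6), 2)),
               c(2 / 5, 4 / 5))
  # strict inequality: ties do not exceed
  expect_equal(permutation_pvalues(3, matrix(c(3, 3, 3, 3), 2)), 1 / 5)
  expect_error(permutation_pvalues(1, numeric(0)), "empty")
})

test_that("linear-scan permutation p-values equal brute force on random instances", {
  set.seed(15)
  for (i in 1:40) {
    m <- sample(1:50, 1); B <- sample(1:20, 1)
    obs <- round(rexp(m, 1 / 3), 2)         # rounding forces ties
    nulls <- matrix(round(rexp(m * B, 1 / 3), 2), m, B)
    expect_equal(permutation_pvalues(obs, nulls), brute_perm_pvalues(obs, nulls))
  }
})

test_that("permutation p-values are invariant to common monotone rescaling", {
  set.seed(16)
  obs <- rexp(20); nulls <- matrix(rexp(100), 20)
  p1 <- permutation_pvalues(obs, nulls)
  mono <- function(x) log1p(3 * x)
  expect_equal(permutation_pvalues(mono(obs), mono(nulls)), p1)
})

test_that("de_test with permutation inference attaches pooled p-values", {
  set.seed(17)
  cts <- matrix(rpois(80, 30), nrow = 8,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  grp <- rep(c("A", "B"), each = 5)
  r <- de_test(cts, grp, family = "gaussian", inference = "permutation",
               B = 10, seed = 5)
  expect_true(all(!is.na(r$p_permutation)))
  expect_true(all(r$p_permutation > 0 & r$p_permutation <= 1))
  nulls <- attr(r, "null_statistics")
  expect_equal(r$p_permutation, brute_perm_pvalues(r$D, nulls$D0))
})
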
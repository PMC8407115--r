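test_that("Yeo-Johnson normalization standardizes, preserves order, and is log-like on log-normal data", {
  set.seed(40)
  v <- rexp(50) + rnorm(50, 0, 0.1)
  yj <- yeo_johnson(v)
  expect_equal(mean(yj$values), 0, tolerance = 1e-10)
  expect_equal(sd(yj$values), 1, tolerance = 1e-10)
  expect_equal(order(yj$values), order(v))  # monotone

  lambdas <- vapply(1:20, function(s) {
    set.seed(s)
    yeo_johnson(exp(rnorm(100, 2, 0.7)))$lambda
  }, numeric(1))
  expect_lt(abs(median(lambdas)), 0.35)

  expect_error(yeo_johnson(rep(3, 10)), "constant")
})

test_that("noiseless mediation constructions are recovered exactly", {
  X <- rep(c(0, 1), each = 10)
  M <- 1 * X
  Y <- 2 * M
  f <- suppressWarnings(fit_mediation(X, M + rnorm(20, 0, 0), Y, n_boot = 300,
                                      seed = 1))
  expect_equal(f$a, 1, tolerance = 1e-12)
  expect_equal(f$b, 2, tolerance = 1e-12)
  expect_equal(f$c, 0, tolerance = 1e-10)
  expect_equal(f$mediation_effect, 2, tolerance = 1e-10)
  expect_equal(f$total_effect, f$a * f$b + f$c, tolerance = 1e-12)
  expect_true(all(f$ci[, 1] <= coef(f) + 1e-10 & coef(f) <= f$ci[, 2] + 1e-10))
})

test_that("mediation fit validates inputs", {
  X <- rep(c(0, 1), each = 10); M <- rnorm(20); Y <- rnorm(20)
  expect_error(fit_mediation(rep(0, 20), M, Y), "both levels")
  expect_error(fit_mediation(c(X[-1], 2), M, Y), "0/1")
  expect_error(fit_mediation(X[1:5], M[1:5], Y[1:5]), "at least 10")
  expect_warning(fit_mediation(X, M, Y, n_boot = 100), "n_boot")
})

test_that("planted mediation paths are recovered at large n", {
  set.seed(41)
  n <- 500
  X <- rbinom(n, 1, 0.5)
  M <- 0.8 * X + rnorm(n)
  Y <- 0.5 * M + 0.2 * X + rnorm(n)
  f <- fit_mediation(X, M, Y, n_boot = 500, seed = 2)
  expect_equal(f$a, 0.8, tolerance = 0.15)
  expect_equal(f$b, 0.5, tolerance = 0.15)
  expect_equal(f$c, 0.2, tolerance = 0.2)
})

test_that("bootstrap intervals are seed-reproducible and widen as n shrinks", {
  set.seed(42)
  make <- function(n) {
    X <- rbinom(n, 1, 0.5)
    M <- 0.8 * X + rnorm(n)
    Y <- 0.5 * M + 0.2 * X + rnorm(n)
    list(X = X, M = M, Y = Y)
  }
  d <- make(500)
  f1 <- fit_mediation(d$X, d$M, d$Y, n_boot = 400, seed = 9)
  f2 <- fit_mediation(d$X, d$M, d$Y, n_boot = 400, seed = 9)
  expect_identical(f1$ci, f2$ci)

  widths <- vapply(c(500, 100, 30), function(n) {
    set.seed(43)
    d <- make(n)
    f <- fit_mediation(d$X, d$M, d$Y, n_boot = 400, seed = 5)
    diff(f$ci["mediation", ])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("noiseless conditional-process construction is exact", {
  g <- expand.grid(X = c(0, 1), W = c(0, 1))
  g <- g[rep(1:4, each = 5), ]
  M <- -1 * g$X + 0 * g$W + -1 * g$X * g$W
  Y <- 1 * M
  f <- suppressWarnings(fit_conditional_process(g$X, g$W, M, Y, n_boot = 300,
                                                seed = 1))
  expect_equal(f$a1, -1, tolerance = 1e-10)
  expect_equal(f$a3, -1, tolerance = 1e-10)
  expect_equal(f$b, 1, tolerance = 1e-10)
  # conditional indirect effects at the two moderator levels
  expect_equal((f$a1 + f$a3 * 0) * f$b, -1, tolerance = 1e-10)
  expect_equal((f$a1 + f$a3 * 1) * f$b, -2, tolerance = 1e-10)
  expect_equal(f$index_mod_med, f$a3 * f$b, tolerance = 1e-12)
})

test_that("conditional process model validates the 2x2 design", {
  X <- rep(c(0, 1), each = 10)
  W <- rep(0, 20); W[X == 0] <- rep(c(0, 1), 5)
  expect_error(fit_conditional_process(X, W, rnorm(20), rnorm(20)),
               "empty X x W cell")
})

test_that("a null interaction is covered by the bootstrap interval", {
  covered <- 0
  for (s in 1:20) {
    d <- make_mediation_data(58, params = list(a1 = -1, a2 = 0.3, a3 = 0,
                                               b = 1, c = 0.2,
                                               sd_m = 0.5, sd_y = 1),
                             seed = 800 + s)
    f <- fit_conditional_process(d$X, d$W, d$M, d$Y, n_boot = 300,
                                 seed = 800 + s)
    if (f$ci["index", 1] <= 0 && f$ci["index", 2] >= 0) covered <- covered + 1
  }
  expect_gte(covered / 20, 0.9)
})

test_that("model screen enumerates outcome x mediator x direction", {
  set.seed(44)
  n <- 40
  X <- rep(c(0, 1), each = n / 2)
  outs <- list(y1 = rnorm(n), y2 = rnorm(n), y3 = rnorm(n))
  meds <- list(m1 = rnorm(n), m2 = rnorm(n))
  sc <- screen_models(outs, meds, X, n_boot = 300, seed = 3)
  expect_equal(nrow(sc), 3 * 2 * 2)
  expect_setequal(unique(sc$direction), c("mediator_as_M", "outcome_as_M"))

  sc1 <- screen_models(outs[1], meds[1], X, n_boot = 300, seed = 3)
  expect_equal(nrow(sc1), 2)

  expect_error(screen_models(outs, c(meds, list(y1 = rnorm(n))), X,
                             n_boot = 300), "collision")
})

test_that("direction swap exchanges the mediator and outcome roles", {
  set.seed(45)
  n <- 60
  X <- rbinom(n, 1, 0.5)
  m <- 1.5 * X + rnorm(n)
  y <- 0.5 * m + rnorm(n)
  sc <- screen_models(list(out = y), list(med = m), X, n_boot = 300, seed = 4,
                      normalize = FALSE)
  fwd <- sc[sc$direction == "mediator_as_M", ]
  rev <- sc[sc$direction == "outcome_as_M", ]
  # in the forward direction, a is the X -> m slope; in reverse, the X -> y slope
  expect_equal(fwd$a, unname(coef(lm(m ~ X))[2]), tolerance = 1e-10)
  expect_equal(rev$a, unname(coef(lm(y ~ X))[2]), tolerance = 1e-10)
})
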
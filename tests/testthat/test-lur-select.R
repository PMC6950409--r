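test_that("Spearman screen computes rho on ranks and enforces priors", {
  x <- c(1, 3, 7, 9, 12)
  d <- make_design(data.frame(v = x), pm25 = x^3)   # monotone, nonlinear
  expect_equal(spearman_screen(d)$spearman_rho, 1)

  # hand ranks for {(1,2),(2,1),(3,3)}: rank cor = 0.5
  d2 <- make_design(data.frame(v = c(1, 2, 3)), pm25 = c(2, 1, 3))
  expect_equal(spearman_screen(d2)$spearman_rho, 0.5)

  # greenness prior is negative: a positively correlated NDVI column drops
  set.seed(1)
  nd <- rnorm(30)
  d3 <- make_design(data.frame(NDVI_1500m = nd), pm25 = 5 + nd + rnorm(30, 0, 0.3))
  scr <- spearman_screen(d3)
  expect_gt(scr$spearman_rho, 0)
  expect_false(scr$keep)
  expect_equal(scr$reason, "sign_mismatch")

  d4 <- make_design(data.frame(flat = rep(3, 10)), pm25 = rnorm(10))
  scr4 <- spearman_screen(d4)
  expect_false(scr4$keep)
  expect_equal(scr4$reason, "zero_variance")
})

test_that("univariate ranking orders by R^2 with name tie-breaks", {
  set.seed(11)
  x1 <- rnorm(40)
  df <- data.frame(b_dup = x1, a_dup = x1, noise = rnorm(40))
  d <- make_design(df, pm25 = x1)
  rk <- univariate_rank(d, names(df))
  expect_equal(rk$name[1:2], c("a_dup", "b_dup"))  # tie broken by name
  expect_equal(rk$r2[1], 1)
  expect_equal(rk$name[3], "noise")
  # closed-form oracle: univariate R^2 = cor(x, y)^2
  expect_equal(rk$r2[rk$name == "noise"],
               cor(df$noise, d$data$pm25)^2)
})

test_that("OLS fit matches hand values, lm, and the normal-equations oracle", {
  x <- seq(-3, 3, length.out = 25)
  d <- make_design(data.frame(x = x), pm25 = 2 * x + 1)
  f <- fit_ols(d, "x")
  expect_equal(unname(f$coefficients), c(1, 2))
  expect_equal(f$r2, 1)
  expect_equal(f$rmse, 0)

  set.seed(21)
  X <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 + X %*% c(1, -2, 0.5) + rnorm(50)
  d2 <- make_design(as.data.frame(X), pm25 = as.vector(y))
  f2 <- fit_ols(d2, c("a", "b", "c"))
  want <- oracle_ols(X, as.vector(y))
  expect_equal(unname(f2$coefficients), want$beta, tolerance = 1e-8)
  expect_equal(unname(f2$se), want$se, tolerance = 1e-8)
  expect_equal(unname(f2$p_value), want$p, tolerance = 1e-8)
  expect_equal(f2$r2, want$r2, tolerance = 1e-10)
  lmfit <- summary(lm(pm25 ~ a + b + c, data = d2$data))
  expect_equal(unname(f2$coefficients), unname(coef(lmfit)[, 1]))
  expect_equal(f2$adj_r2, lmfit$adj.r.squared)

  # permutation invariance
  perm <- sample(50)
  d3 <- d2; d3$data <- d2$data[perm, ]
  expect_equal(fit_ols(d3, c("a", "b", "c"))$coefficients, f2$coefficients)

  # rank deficiency names the aliased column
  d4 <- make_design(data.frame(a = X[, 1], twin = X[, 1]), pm25 = as.vector(y))
  expect_error(fit_ols(d4, c("a", "twin")), "twin")
})

test_that("VIF matches the auxiliary-regression oracle and car::vif", {
  set.seed(31)
  z <- rnorm(60)
  df <- data.frame(p = z + rnorm(60, 0, 0.6),
                   q = z + rnorm(60, 0, 0.6),
                   r = rnorm(60))
  d <- make_design(df, pm25 = rnorm(60))
  got <- vif(d, c("p", "q", "r"))
  expect_equal(unname(got), unname(oracle_vif(df, c("p", "q", "r"))),
               tolerance = 1e-10)
  if (requireNamespace("car", quietly = TRUE)) {
    cv <- car::vif(lm(pm25 ~ p + q + r, data = d$data))
    expect_equal(unname(got), unname(cv), tolerance = 1e-8)
  }
  expect_true(all(got >= 1))

  # orthogonal pair: both 1 (construct exactly uncorrelated columns)
  a <- c(1, 1, -1, -1); b <- c(1, -1, 1, -1)
  d2 <- make_design(data.frame(a = a, b = b), pm25 = rnorm(4))
  expect_equal(unname(vif(d2, c("a", "b"))), c(1, 1))

  d3 <- make_design(data.frame(a = z, copy = z), pm25 = rnorm(60))
  expect_true(all(is.infinite(vif(d3, c("a", "copy")))))
})

test_that("partial R^2 agrees with the Frisch-Waugh residual oracle", {
  set.seed(41)
  x1 <- rnorm(80); x2 <- 0.5 * x1 + rnorm(80)
  y <- 1 + x1 + 0.7 * x2 + rnorm(80)
  d <- make_design(data.frame(x1 = x1, x2 = x2), pm25 = y)
  f <- fit_ols(d, c("x1", "x2"))
  pr2 <- partial_r2(f)
  # oracle: squared correlation of residuals from regressing y and x_j on
  # the other predictors
  for (v in c("x1", "x2")) {
    other <- setdiff(c("x1", "x2"), v)
    ry <- resid(lm(reformulate(other, "pm25"), data = d$data))
    rx <- resid(lm(reformulate(other, v), data = d$data))
    expect_equal(pr2[[v]], cor(ry, rx)^2, tolerance = 1e-10)
  }
  # single-term model: partial R^2 equals model R^2
  f1 <- fit_ols(d, "x1")
  expect_equal(partial_r2(f1)[["x1"]], f1$r2, tolerance = 1e-10)
  # a term orthogonal to the response given the rest is ~0
  d2 <- make_design(data.frame(x1 = x1,
                               junk = resid(lm(rnorm(80) ~ y + x1))),
                    pm25 = y)
  expect_lt(partial_r2(fit_ols(d2, c("x1", "junk")))[["junk"]], 0.05)
})

test_that("stepwise selects the signal and rejects a collinear clone", {
  set.seed(51)
  n <- 120
  x1 <- rnorm(n)
  noise <- as.data.frame(replicate(10, rnorm(n)))
  names(noise) <- sprintf("n%02d", 1:10)
  d <- make_design(cbind(data.frame(x1 = x1), noise),
                   pm25 = 10 + 2 * x1 + rnorm(n, 0, 0.05))
  m <- supervised_stepwise(d)
  expect_true("x1" %in% m$terms$name)
  expect_true(all(m$terms$p_value < 0.1))
  expect_true(all(m$terms$vif < 3))

  clone <- x1 + rnorm(n, 0, sd(x1) * 0.14)   # ~0.99 correlation
  # both truly predictive, so the p gate passes and only VIF can reject
  d2 <- make_design(data.frame(x1 = x1, clone = clone),
                    pm25 = 10 + x1 + clone + rnorm(n, 0, 0.05))
  m2 <- supervised_stepwise(d2)
  expect_equal(nrow(m2$terms), 1)            # VIF gate keeps exactly one
  skip_reasons <- m2$trace$reason[m2$trace$action == "skip"]
  expect_true(any(grepl("VIF", skip_reasons)))
})

test_that("stepwise is deterministic and degrades to intercept-only", {
  set.seed(61)
  s <- simulate_lur_dataset(202, n_obs = 250)
  m1 <- supervised_stepwise(s$design)
  m2 <- supervised_stepwise(s$design)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$terms, m2$terms)

  flat <- make_design(data.frame(NDVI_500m = rnorm(20)),
                      pm25 = rnorm(20))
  # force the screen to drop everything via an impossible prior
  flat$candidates$direction_prior <- if (spearman_screen(flat)$spearman_rho > 0)
    -1L else 1L
  expect_warning(m0 <- supervised_stepwise(flat), "intercept-only")
  expect_equal(nrow(m0$terms), 0)
  expect_equal(m0$intercept, mean(flat$data$pm25))
})

test_that("pure-noise responses yield small models (no runaway selection)", {
  sizes <- vapply(1:8, function(k) {
    s <- simulate_lur_dataset(k * 977, n_obs = 250)
    set.seed(k)
    s$design$data$pm25 <- rnorm(250, 20, 5)
    nrow(supervised_stepwise(s$design)$terms)
  }, numeric(1))
  expect_lte(median(sizes), 2)
})

test_that("model report mirrors the fitted model", {
  set.seed(71)
  x <- rnorm(50)
  d <- make_design(data.frame(x = x), pm25 = 3 + x + rnorm(50, 0, 0.4))
  m <- supervised_stepwise(d)
  rep <- model_report(m)
  expect_equal(rep$Variable[1], "Intercept")
  expect_equal(rep$beta[-1], m$terms$beta)
  expect_equal(unique(rep$R2), m$r2)
  expect_true(all(c("VIF", "partial_R2", "RMSE") %in% names(rep)))
})
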
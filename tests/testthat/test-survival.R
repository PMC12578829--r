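test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # censoring: S drops only at event times
  km2 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km2$surv, c(3 / 4, 3 / 4 * 1 / 2))
  expect_error(km_estimate(c(1, 2), c(0, 0)), ">= 1 event")
})

test_that("log-rank test matches the hand-summed hypergeometric oracle", {
  # identical groups: chi2 = 0, p = 1
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- rep(1, 8)
  grp <- rep(c(0, 1), each = 4)
  lr <- logrank_test(tm, ev, grp)
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  # 10-sample toy, oracle summed term by term
  tm2 <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  ev2 <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  g2 <- rep(c("a", "b"), each = 5)
  U <- 0; V <- 0
  for (t in sort(unique(tm2[ev2 == 1]))) {
    at <- tm2 >= t
    nj <- sum(at); n1 <- sum(at & g2 == "a")
    dj <- sum(tm2 == t & ev2 == 1)
    d1 <- sum(tm2 == t & ev2 == 1 & g2 == "a")
    U <- U + d1 - dj * n1 / nj
    V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  lr2 <- logrank_test(tm2, ev2, g2)
  expect_equal(lr2$chi2, U^2 / V)
  expect_error(logrank_test(tm2, ev2, rep("a", 10)), "2")
})

test_that("KM and log-rank agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(61)
  n <- 80
  tm <- rexp(n, 0.2); cc <- runif(n, 0, 8)
  time <- pmin(tm, cc); ev <- as.integer(tm <= cc)
  grp <- rep(c(0, 1), each = n / 2)
  km <- km_estimate(time, ev)
  sf <- summary(survival::survfit(survival::Surv(time, ev) ~ 1))
  expect_equal(km$surv, sf$surv, tolerance = 1e-12)
  lr <- logrank_test(time, ev, grp)
  sd_ <- survival::survdiff(survival::Surv(time, ev) ~ grp)
  expect_equal(lr$chi2, sd_$chisq, tolerance = 1e-9)
})

test_that("Cox Newton solution matches oracles and flags pathologies", {
  skip_if_not_installed("survival")
  set.seed(62)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.1 * exp(0.7 * x)); cc <- runif(n, 0, 25)
  time <- pmin(tm, cc); ev <- as.integer(tm <= cc)
  fit <- cox_fit(cbind(x = x), time, ev)
  expect_true(fit$converged)
  # grid-search maximisation of the partial likelihood
  grid <- seq(-2, 2, by = 1e-3)
  pll <- vapply(grid, function(b)
    selnc:::.cox_pll(b, cbind(x), time, ev)$ll, numeric(1))
  expect_lt(abs(unname(fit$beta) - grid[which.max(pll)]), 1e-3)
  # agreement with coxph (Breslow)
  cp <- survival::coxph(survival::Surv(time, ev) ~ x, ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(cp)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cp)))),
               tolerance = 1e-6)
  # null data: estimate within 2 se of zero
  set.seed(63)
  xn <- rnorm(200)
  tmn <- rexp(200, 0.1); ccn <- runif(200, 0, 25)
  fn <- cox_fit(cbind(x = xn), pmin(tmn, ccn),
                as.integer(tmn <= ccn))
  expect_lt(abs(unname(fn$beta)), 2 * unname(fn$se))
  # perfect collinearity is flagged, never silent
  fd <- cox_fit(cbind(a = xn, b = xn), pmin(tmn, ccn),
                as.integer(tmn <= ccn))
  expect_false(fd$converged && fd$stable)
  expect_error(cox_fit(cbind(k = rep(1, 200)), pmin(tmn, ccn),
                       as.integer(tmn <= ccn)), "constant")
})

test_that("univariate screen finds planted features and honours contracts", {
  set.seed(64)
  n <- 300; p <- 55
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  beta <- c(rep(1, 3), rep(-1, 2), rep(0, p - 5))
  tm <- rexp(n, 0.1 * exp(drop(X %*% beta)))
  cc <- runif(n, 0, 30)
  time <- pmin(tm, cc); ev <- as.integer(tm <= cc)
  scr <- univariate_screen(X, time, ev, alpha = 0.05)
  expect_true(all(sprintf("f%02d", 1:5) %in%
                    scr$feature[scr$significant]))
  expect_true(all(c("beta", "p", "q", "logrank_p") %in% colnames(scr)))
  scr0 <- univariate_screen(X, time, ev, alpha = 0)
  expect_equal(sum(scr0$significant), 0L)
  Xc <- cbind(X[, 1:3], const = 1)
  expect_warning(s2 <- univariate_screen(Xc, time, ev), "constant")
  expect_equal(attr(s2, "skipped"), "const")
})

test_that("LASSO path contracts: lambda_max zero, L1 monotone, MLE limit", {
  set.seed(65)
  n <- 250; p <- 5
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", 1:p)))
  tm <- rexp(n, 0.1 * exp(drop(X %*% c(1, -0.8, 0.5, 0, 0))))
  cc <- runif(n, 0, 30)
  time <- pmin(tm, cc); ev <- as.integer(tm <= cc)
  path <- lasso_cox_path(X, time, ev, seed = 9,
                         lambda_min_ratio = 1e-7)
  expect_true(all(path$beta[, 1] == 0))
  l1 <- colSums(abs(path$beta))
  # lambda is descending, so L1 norms are non-decreasing along the path
  expect_true(all(diff(l1) > -1e-8))
  mle <- cox_fit(X, time, ev)
  expect_lt(max(abs(path$beta[, ncol(path$beta)] - mle$beta)), 1e-4)
  expect_error(lasso_cox_path(X, time, rep(0L, n)), "events")
})

test_that("survival forest orders risk by the true hazard and is seeded", {
  set.seed(66)
  n <- 100
  x <- runif(n)
  # noiseless monotone hazard: larger x dies strictly earlier
  time <- 10 - 9 * x
  ev <- rep(1L, n)
  X <- cbind(x = x)
  m <- rsf_fit(X, time, ev, n_trees = 100, min_node_events = 1,
               seed = 4)
  sc <- risk_score(m, X)
  # bootstrap trees cannot separate every adjacent pair, so perfect
  # concordance is approached, not attained exactly
  expect_gte(c_index(sc, time, ev), 0.99)
  expect_gte(cor(sc, x, method = "spearman"), 0.99)
  # identical rows give identical scores
  Xi <- cbind(x = rep(0.5, 20))
  expect_equal(length(unique(risk_score(m, Xi))), 1L)
  # bitwise determinism under a fixed seed
  m2 <- rsf_fit(X, time, ev, n_trees = 100, min_node_events = 1,
                seed = 4)
  expect_identical(risk_score(m2, X), sc)
  expect_error(rsf_fit(X, time, ev, n_trees = 5), "n_trees")
})

test_that("permutation importance ranks the signal feature first", {
  set.seed(67)
  n <- 150
  X <- cbind(sig = runif(n), noise = runif(n))
  time <- 10 - 9 * X[, "sig"] + runif(n, 0, 0.3)
  ev <- rep(1L, n)
  m <- rsf_fit(X, time, ev, n_trees = 100, min_node_events = 2, seed = 2)
  imp <- feature_importance(m, X, time, ev, n_perm = 5, seed = 3)
  expect_equal(imp$feature[1], "sig")
  expect_lt(abs(imp$importance[imp$feature == "noise"]), 0.02)
  expect_error(feature_importance(m, X, time, ev, n_perm = 0), "n_perm")
})

test_that("IPCW time-dependent AUC obeys its closed forms", {
  set.seed(68)
  n <- 100
  time <- runif(n, 0, 10)
  ev <- rep(1L, n)
  expect_equal(time_dependent_auc(-time, time, ev, 5), 1.0)
  expect_equal(time_dependent_auc(rep(1, n), time, ev, 5), 0.5)
  # random scores on a null: near 0.5
  set.seed(69)
  n2 <- 500
  tm <- rexp(n2, 0.2); cc <- runif(n2, 0, 10)
  t2 <- pmin(tm, cc); e2 <- as.integer(tm <= cc)
  a <- time_dependent_auc(rnorm(n2), t2, e2, 5)
  expect_gt(a, 0.45); expect_lt(a, 0.55)
  expect_error(time_dependent_auc(rnorm(n), time, ev, 20), "controls")
  expect_error(time_dependent_auc(rnorm(n), time + 20, ev, 5), "cases")
})

test_that("risk-group analysis detects a planted effect", {
  set.seed(70)
  n <- 200
  sc <- rnorm(n)
  tm <- rexp(n, 0.1 * exp(1.5 * sc)); cc <- runif(n, 0, 40)
  time <- pmin(tm, cc); ev <- as.integer(tm <= cc)
  rg <- risk_group_analysis(sc, time, ev)
  expect_lt(rg$logrank$p, 0.01)
  expect_lt(rg$score_time_cor, 0)
  expect_true(all(rg$km_high$surv <= 1) &&
                !is.unsorted(rev(rg$km_high$surv)))
  expect_error(risk_group_analysis(sc[1:3], time[1:3], ev[1:3]), ">= 4")
  expect_error(risk_group_analysis(rep(1, 10), time[1:10], ev[1:10]),
               "identical")
})
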
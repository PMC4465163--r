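test_that("AUC equals the pair-counting value on the worked example", {
  r <- rocAnalysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$n_pos, 2); expect_equal(r$n_neg, 2)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
})

test_that("perfect separation and label flips behave as expected", {
  s <- c(1, 2, 3, 10, 11, 12)
  l <- c(0, 0, 0, 1, 1, 1)
  expect_equal(rocAnalysis(s, l)$auc, 1)
  r <- rocAnalysis(c(0.3, 0.1, 0.9, 0.2, 0.8), c(1, 0, 1, 0, 0))
  rf <- rocAnalysis(c(0.3, 0.1, 0.9, 0.2, 0.8), c(0, 1, 0, 1, 1))
  expect_equal(rf$auc, 1 - r$auc)
  expect_error(rocAnalysis(s, rep(1, 6)), "negative")
  expect_error(rocAnalysis(s, rep(0, 6)), "positive")
})

test_that("AUC matches exhaustive pair counting on random inputs with ties", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(rocAnalysis(scores, labels)$auc, pairAUC(scores, labels))
  }
})

test_that("the optimal cutoff minimizes distance to the upper-left corner", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(8:60, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- rocAnalysis(scores, labels)
    achieved <- sqrt((1 - r$optimal_sens)^2 + (1 - r$optimal_spec)^2)
    expect_equal(achieved, bruteCutoffDistance(scores, labels))
  }
  # perfect separation: distance 0
  r <- rocAnalysis(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(sqrt((1 - r$optimal_sens)^2 + (1 - r$optimal_spec)^2), 0)
  expect_true(r$optimal_cutoff > 2 && r$optimal_cutoff < 8)
})

test_that("a degenerate constant marker still reports a corner cutoff", {
  r <- rocAnalysis(rep(2, 10), rbinom(10, 1, 0.5))
  expect_equal(r$auc, 0.5)
  d <- sqrt((1 - r$optimal_sens)^2 + (1 - r$optimal_spec)^2)
  expect_equal(d, 1)                      # best achievable is a corner
  expect_equal(r$optimal_spec, 1)         # tie broken toward specificity
})

test_that("product-limit curve matches the hand-computed example", {
  s <- kmLogrank(c(1, 2, 3), c(1, 1, 1), rep("a", 3))
  expect_equal(s$curves[["a"]]$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(s$groups$events, 3)
  expect_true(is.na(s$logrank_p))
})

test_that("identical groups give a null log-rank test", {
  t <- rep(c(2, 4, 6, 8), 2)
  e <- rep(c(1, 0, 1, 1), 2)
  g <- rep(c(0, 1), each = 4)
  s <- kmLogrank(t, e, g)
  expect_equal(s$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(s$logrank_p, 1, tolerance = 1e-10)
})

test_that("fully censored data yield flat curves and unreached medians", {
  s <- kmLogrank(c(5, 6, 7, 8), c(0, 0, 0, 0), c(0, 0, 1, 1))
  expect_true(all(s$curves[[1]]$surv == 1))
  expect_true(all(s$curves[[2]]$surv == 1))
  expect_true(all(is.na(s$groups$median)))
  expect_error(kmLogrank(c(-1, 2), c(1, 1), c(0, 1)), "> 0")
})

test_that("Cox recovers a binary hazard ratio of 2 and its CI covers truth", {
  set.seed(7)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.05 * 2^x)
  fit <- coxFit(data.frame(x = x), t, rep(1, n))
  expect_gt(fit$hr, 1.6); expect_lt(fit$hr, 2.5)
  expect_true(fit$ci_low <= 2 && 2 <= fit$ci_high)
})

test_that("Cox estimate converges to the true rate ratio with n", {
  err <- vapply(c(200, 1000, 5000), function(n) {
    set.seed(n)
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, rate = 0.05 * 2^x)
    abs(log(coxFit(data.frame(x = x), t, rep(1, n))$hr) - log(2))
  }, numeric(1))
  expect_lt(err[3], 0.1)
  expect_lt(err[3], err[1] + 0.05)
})

test_that("Cox contract violations are rejected with diagnostics", {
  set.seed(9)
  t <- rexp(50, 0.1); e <- rep(1, 50)
  expect_error(coxFit(data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50),
                                 d = rnorm(50)), t, e),
               "three covariates")
  expect_error(coxFit(data.frame(x = rep(1, 50)), t, e), "constant")
  # complete separation on a binary covariate
  x <- c(rep(0, 25), rep(1, 25))
  ts <- c(rexp(25, 0.001) + 100, rexp(25, 10))
  expect_error(coxFit(data.frame(x = x), ts, rep(1, 50)), "converge")
  # log transform of a non-positive covariate
  expect_error(coxFit(data.frame(x = c(-1, rexp(49))), t, e,
                      logTransform = "x"), "log-transform")
})

test_that("null-covariate Cox CIs cover 1 at roughly the nominal rate", {
  cover <- vapply(1:200, function(i) {
    set.seed(i)
    x <- rnorm(60)
    t <- rexp(60, 0.1)
    f <- coxFit(data.frame(x = x), t, rep(1, 60))
    f$ci_low <= 1 && 1 <= f$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.90)
})

test_that("stability correlations behave on constructed inputs", {
  set.seed(12)
  fa <- as.data.frame(matrix(runif(9 * 10), 10))
  names(fa) <- c("suv_max", "suv_mean", "mtv_ml", "cov", "entropy",
                 "correlation", "contrast", "busyness", "coarseness")
  tab <- pearsonTable(fa, fa)
  expect_equal(tab$r, rep(1, 9))
  fb <- fa; fb$entropy <- -fa$entropy
  expect_equal(tab$r[tab$feature == "entropy"], 1)
  expect_equal(pearsonTable(fa, fb)$r[tab$feature == "entropy"], -1)
  fc <- fa; fc$cov <- 0
  expect_true(pearsonTable(fa, fc)$degenerate[tab$feature == "cov"])
  expect_error(pearsonTable(fa[1:2, ], fa[1:2, ]), "at least 3")
})

test_that("size dependency is exact for linear features and small for independent ones", {
  set.seed(13)
  f <- data.frame(mtv_ml = runif(200, 5, 100))
  f$suv_max <- 2 * f$mtv_ml            # noiseless linear
  f$entropy <- rnorm(200)              # independent by construction
  tab <- sizeDependency(f, columns = c("suv_max", "entropy"))
  expect_equal(tab$r[tab$feature == "suv_max"], 1)
  expect_lt(abs(tab$r[tab$feature == "entropy"]), 0.2)
  tab2 <- sizeDependency(cbind(f, m2 = f$mtv_ml), columns = "m2")
  expect_equal(tab2$r, 1)
})
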
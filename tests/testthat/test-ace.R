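test_that("degenerate pair data is attributed to the shared environment", {
  ## y1 == y2 with varying pair means: rMZ = rDZ = 1 implies C = 1
  set.seed(3)
  pm <- rnorm(60, 10, 2)
  pairs <- data.frame(pair_id = sprintf("P%02d", 1:60),
                      zygosity = rep(c("MZ", "DZ"), c(40, 20)),
                      y1 = pm, y2 = pm)
  fit <- twin_ace(y ~ 1, pairs_to_long(pairs), model = "ACE")
  expect_gt(fit$std[["C"]], 0.95)
  expect_lt(fit$std[["A"]], 0.05)
  expect_lt(fit$std[["E"]], 0.01)
})

test_that("optimizer matches the exhaustive grid-search oracle on a 30-pair fixture", {
  pairs <- sim_ace_pairs(20, 10, A = 0.5, C = 0.2, E = 0.3, mu = 2, seed = 42)
  fit <- twin_ace(y ~ 1, pairs_to_long(pairs), model = "ACE")
  oracle <- oracle_grid_search(pairs$y1, pairs$y2, pairs$zygosity, rounds = 4)
  expect_gte(fit$logLik, oracle$ll - 1e-4)
  expect_lt(abs(fit$logLik - oracle$ll), 1e-4)
  ## and the package likelihood agrees with the independent oracle pointwise
  vc <- fit$varcomp
  ll_oracle <- oracle_pair_loglik(pairs$y1, pairs$y2, pairs$zygosity,
                                  vc[["a2"]], vc[["c2"]], vc[["e2"]])
  expect_equal(fit$logLik, ll_oracle, tolerance = 1e-6)
})

test_that("AE data is recovered with the model-implied correlations", {
  pairs <- sim_ace_pairs(5000, 2500, A = 0.63, C = 0, E = 0.37, seed = 7)
  fit <- twin_ace(y ~ 1, pairs_to_long(pairs), model = "AE")
  expect_lt(abs(fit$std[["A"]] - 0.63), 0.03)
  expect_equal(unname(fit$implied_r["rMZ"] / fit$implied_r["rDZ"]), 2,
               tolerance = 1e-6)
})

test_that("log-likelihood nesting holds on arbitrary data", {
  for (s in 1:3) {
    pairs <- sim_ace_pairs(80, 40, A = runif(1, 0, 0.5), C = runif(1, 0, 0.3),
                           E = 0.4, mu = rnorm(1), seed = 100 + s)
    long <- pairs_to_long(pairs)
    lls <- vapply(c("E", "CE", "AE", "ACE", "saturated"), function(m)
      twin_ace(y ~ 1, long, model = m)$logLik, 1)
    expect_gte(lls["saturated"], lls["ACE"] - 1e-6)
    expect_gte(lls["ACE"], lls["AE"] - 1e-6)
    expect_gte(lls["ACE"], lls["CE"] - 1e-6)
    expect_gte(lls["AE"], lls["E"] - 1e-6)
    expect_gte(lls["CE"], lls["E"] - 1e-6)
  }
})

test_that("standardized shares sum to one and imply rMZ >= rDZ when a2 > 0", {
  for (s in 1:5) {
    pairs <- sim_ace_pairs(60, 30, A = runif(1, 0, 0.6), C = runif(1, 0, 0.3),
                           E = 0.4, seed = 200 + s)
    fit <- twin_ace(y ~ 1, pairs_to_long(pairs), model = "ACE")
    expect_lt(abs(sum(fit$std) - 1), 1e-8)
    if (fit$varcomp[["a2"]] > 1e-10) {
      expect_gt(fit$implied_r[["rMZ"]], fit$implied_r[["rDZ"]])
    } else {
      expect_equal(fit$implied_r[["rMZ"]], fit$implied_r[["rDZ"]],
                   tolerance = 1e-8)
    }
  }
})

test_that("fits are equivariant under phenotype rescaling", {
  pairs <- sim_ace_pairs(100, 50, A = 0.4, C = 0.2, E = 0.4, seed = 11)
  long <- pairs_to_long(pairs)
  long$age <- rep(rnorm(150, 50, 10), each = 2)
  f1 <- twin_ace(y ~ age, long, model = "ACE")
  long2 <- long; long2$y <- long$y * 3.7
  f2 <- twin_ace(y ~ age, long2, model = "ACE")
  expect_equal(f2$varcomp, f1$varcomp * 3.7^2, tolerance = 1e-4)
  expect_equal(f2$std, f1$std, tolerance = 1e-6)
  ## LRT p-values are scale-free
  sat1 <- twin_ace(y ~ age, long, model = "saturated")
  sat2 <- twin_ace(y ~ age, long2, model = "saturated")
  p1 <- anova(f1, sat1)$p_value[2]
  p2 <- anova(f2, sat2)$p_value[2]
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("parameter recovery across the (A, C, E) grid", {
  grid <- list(c(0.6, 0, 0.4), c(0.3, 0.3, 0.4), c(0, 0.5, 0.5), c(0, 0, 1))
  for (g in grid) {
    err <- vapply(1:10, function(r) {
      pairs <- sim_ace_pairs(500, 250, g[1], g[2], g[3],
                             seed = 7000 + 17 * r + round(100 * g[1]))
      fit <- twin_ace(y ~ 1, pairs_to_long(pairs), model = "ACE")
      mean(abs(fit$std - c(A = g[1], C = g[2], E = g[3])))
    }, 1)
    expect_lt(mean(err), 0.08)   # 500+250 pairs, 10 replicates per corner
  }
})

test_that("saturated comparison detects zygosity heteroskedasticity", {
  ## MZ variance twice the DZ variance violates every structured model
  rej <- vapply(1:40, function(r) {
    pairs <- sim_ace_pairs(67, 33, A = 0.4, C = 0, E = 0.6, seed = 3000 + r)
    j <- pairs$zygosity == "MZ"
    pairs$y1[j] <- pairs$y1[j] * sqrt(2)
    pairs$y2[j] <- pairs$y2[j] * sqrt(2)
    long <- pairs_to_long(pairs)
    ace <- twin_ace(y ~ 1, long, model = "ACE")
    sat <- twin_ace(y ~ 1, long, model = "saturated")
    anova(ace, sat)$p_value[2] < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.5)
})

test_that("likelihood-ratio tests from printed deviances reproduce known p-values", {
  ## basilar length: deviances 1144.393 / 1165.349 on 9 df round to p = 0.01
  r1 <- deviance_lrt(1144.393, 1165.349, df = 9)
  expect_equal(r1$chi_square, 20.956, tolerance = 1e-6)
  expect_equal(round(r1$p_value, 2), 0.01)
  ## basilar area: 242.4058 / 280.1872 on 9 df is far below 0.001
  r2 <- deviance_lrt(242.4058, 280.1872, df = 9)
  expect_lt(r2$p_value, 0.001)
  expect_identical(deviance_lrt(100, 100, df = 3)$p_value, 1)
  expect_error(deviance_lrt(120, 100, df = 3), class = "nesting_error")
})

test_that("model selection follows min AIC with BIC tie-breaking", {
  ## published basilar-length and basilar-area AIC triples
  expect_identical(select_model(data.frame(
    model = c("ACE", "AE", "CE"), AIC = c(1179.85, 1177.11, 1182.74))), "AE")
  expect_identical(select_model(data.frame(
    model = c("ACE", "AE", "CE"), AIC = c(277.860, 275.811, 275.271))), "CE")
  expect_identical(select_model(data.frame(
    model = c("ACE", "AE"), AIC = c(100, 100), BIC = c(95, 90))), "AE")
  expect_error(select_model(data.frame()), class = "validation_error")
  expect_error(select_model(list()), class = "validation_error")

  ## pure-E data prefers the E model most of the time
  hits <- vapply(1:30, function(r) {
    pairs <- sim_ace_pairs(300, 150, A = 0, C = 0, E = 1, seed = 4000 + r)
    long <- pairs_to_long(pairs)
    fits <- lapply(c("ACE", "AE", "CE", "E"), function(m)
      twin_ace(y ~ 1, long, model = m))
    select_model(fits)$model == "E"
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("profile confidence intervals behave at boundaries and cover", {
  ## boundary: C estimated at 0 gives a lower bound of exactly 0
  pairs <- sim_ace_pairs(200, 100, A = 0.6, C = 0, E = 0.4, seed = 21)
  fit <- twin_ace(y ~ 1, pairs_to_long(pairs), model = "ACE")
  ci <- confint(fit)
  expect_identical(ci["C", "lower"], 0)
  expect_true(ci["A", "lower"] <= fit$std[["A"]],
              ci["A", "upper"] >= fit$std[["A"]])
  ## AE model: A and E intervals mirror each other (A + E = 1)
  fit_ae <- twin_ace(y ~ 1, pairs_to_long(pairs), model = "AE")
  ci_ae <- confint(fit_ae)
  expect_equal(ci_ae["A", "lower"], 1 - ci_ae["E", "upper"], tolerance = 1e-3)
  ## pure E model: degenerate interval at 1
  fit_e <- twin_ace(y ~ 1, pairs_to_long(pairs), model = "E")
  expect_identical(unname(confint(fit_e)["E", ]), c(1, 1))
})

test_that("profile intervals agree with a parametric-bootstrap oracle", {
  pairs <- sim_ace_pairs(80, 40, A = 0.5, C = 0, E = 0.5, seed = 31)
  long <- pairs_to_long(pairs)
  fit <- twin_ace(y ~ 1, long, model = "AE")
  ci <- confint(fit)["A", ]
  boot <- vapply(1:400, function(b) {
    yb <- simulate(fit, seed = 5000 + b)
    lb <- long
    lb$y <- as.vector(t(yb))
    twin_ace(y ~ 1, lb, model = "AE")$std[["A"]]
  }, 1)
  bci <- unname(quantile(boot, c(0.025, 0.975)))
  expect_lt(abs(ci[["lower"]] - bci[1]), 0.05)
  expect_lt(abs(ci[["upper"]] - bci[2]), 0.05)
})

test_that("covariate machinery: effects, Wald CIs, LRTs and collinearity", {
  set.seed(13)
  n_pairs <- 1050
  long <- pairs_to_long(sim_ace_pairs(700, 350, A = 0, C = 0.3, E = 0.7,
                                      seed = 51))
  long$smoking <- rbinom(nrow(long), 1, 0.3)
  long$height_cm <- rep(rnorm(n_pairs, 168, 9), each = 2)
  long$y <- long$y + 0.212 * long$smoking + 0.025 * long$height_cm
  fit <- twin_ace(y ~ smoking + height_cm, long, model = "CE")
  eff <- covariate_effects(fit)
  sm <- eff[eff$covariate == "smoking", ]
  expect_lt(abs(sm$estimate - 0.212), 0.05)
  expect_true(sm$lower < 0.212 && sm$upper > 0.212)
  ht <- eff[eff$covariate == "height_cm", ]
  expect_lt(abs(ht$estimate - 0.025), 0.005)
  expect_error(covariate_effects(fit, "bmi"), class = "validation_error")

  ## dropping an active covariate is detected by the LRT
  red <- twin_ace(y ~ height_cm, long, model = "CE")
  lrt <- deviance_lrt(-2 * fit$logLik, -2 * red$logLik, df = 1)
  expect_lt(lrt$p_value, 0.01)
  expect_equal(anova(red, fit)$p_value[2], lrt$p_value, tolerance = 1e-9)

  ## a duplicated covariate is flagged, not silently split
  long$smoking2 <- long$smoking
  expect_error(twin_ace(y ~ smoking + smoking2, long, model = "CE"),
               class = "collinearity_error")
})

test_that("null covariates are covered by their Wald intervals at the nominal rate", {
  cover <- vapply(1:150, function(r) {
    pairs <- sim_ace_pairs(60, 30, A = 0.4, C = 0, E = 0.6, seed = 6000 + r)
    long <- pairs_to_long(pairs)
    set.seed(6000 + r)
    long$x <- rnorm(nrow(long))
    fit <- twin_ace(y ~ x, long, model = "AE")
    eff <- covariate_effects(fit, "x")
    eff$lower < 0 && eff$upper > 0
  }, TRUE)
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("intrapair correlations match the ANOVA ICC oracle", {
  ## hand fixture: the ICC must equal (MSB - MSW) / (MSB + MSW) from aov()
  set.seed(17)
  pairs <- sim_ace_pairs(10, 10, A = 0.5, C = 0.2, E = 0.3, seed = 61)
  long <- pairs_to_long(pairs)
  res <- intrapair_correlation(y ~ 1, long)
  for (z in c("MZ", "DZ")) {
    sub <- long[long$zygosity == z, ]
    sub$y <- sub$y - mean(sub$y)
    av <- summary(stats::aov(y ~ pair_id, data = sub))[[1]]
    msb <- av["pair_id", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
    expect_equal(res$r[res$zygosity == z], (msb - msw) / (msb + msw),
                 tolerance = 1e-9)
  }

  ## perfect within-pair agreement
  pm <- rnorm(20, 5, 3)
  perfect <- data.frame(pair_id = sprintf("Q%02d", 1:20),
                        zygosity = rep(c("MZ", "DZ"), each = 10),
                        y1 = pm, y2 = pm)
  rp <- intrapair_correlation(y ~ 1, pairs_to_long(perfect))
  expect_equal(rp$r, c(1, 1), tolerance = 1e-9)

  ## independent members: both correlations near zero
  indep <- sim_ace_pairs(2500, 2500, A = 0, C = 0, E = 1, seed = 71)
  ri <- intrapair_correlation(y ~ 1, pairs_to_long(indep))
  expect_lt(max(abs(ri$r)), 0.06)
  expect_true(all(ri$lower < ri$r & ri$r < ri$upper))
})

test_that("incomplete pairs are dropped and counted", {
  pairs <- sim_ace_pairs(20, 10, A = 0.4, C = 0.1, E = 0.5, seed = 81)
  long <- pairs_to_long(pairs)
  long$y[c(1, 10)] <- NA   # cripples two pairs
  fit <- twin_ace(y ~ 1, long, model = "ACE")
  expect_identical(fit$n_dropped, 2L)
  expect_identical(unname(sum(fit$n_pairs)), 28L)
})

test_that("fit object methods are coherent", {
  pairs <- sim_ace_pairs(50, 25, A = 0.4, C = 0.2, E = 0.4, mu = 3, seed = 91)
  long <- pairs_to_long(pairs)
  long$age <- rep(rnorm(75, 50, 10), each = 2)
  fit <- twin_ace(y ~ age, long, model = "ACE")
  expect_equal(AIC(fit), -2 * fit$logLik + 2 * fit$npar)
  expect_equal(BIC(fit), -2 * fit$logLik + fit$npar * log(150))
  expect_identical(nobs(fit), 150L)
  expect_length(coef(fit), 2L)
  expect_identical(dim(vcov(fit)), c(2L, 2L))
  r <- residuals(fit)
  expect_identical(dim(r), c(75L, 2L))
  y_new <- simulate(fit, seed = 1)
  expect_identical(dim(y_new), c(75L, 2L))
  expect_output(print(summary(fit, profile = FALSE)), "Mean model")
  s <- summary(fit)
  expect_true(all(s$components$lower <= s$components$estimate + 1e-9))
})
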
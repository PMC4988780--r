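test_that("OLS recovers exact linear relations and the normal equations", {
  g <- c(0, 1, 2, 0, 1, 2)
  x <- c(1, -1, 1, -1, 1, -1)  # orthogonal-ish covariate
  y <- 2 * g
  fit <- ols_fit(y, cbind(`(Intercept)` = 1, x = x, dosage = g))
  expect_equal(unname(fit$coefficients["dosage"]), 2.0, tolerance = 1e-12)
  expect_lt(fit$sigma, 1e-10)

  # tiny-dataset oracle: closed-form normal equations solve(X'X, X'y)
  set.seed(14)
  X <- cbind(1, rnorm(6), c(0, 1, 2, 1, 0, 2))
  y2 <- rnorm(6)
  fit2 <- ols_fit(y2, X)
  expect_equal(unname(fit2$coefficients),
               unname(solve(crossprod(X), crossprod(X, y2))[, 1]),
               tolerance = 1e-10)
  # permutation invariance
  perm <- c(4, 2, 6, 1, 3, 5)
  fit3 <- ols_fit(y2[perm], X[perm, ])
  expect_equal(fit3$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(fit3$se, fit2$se, tolerance = 1e-10)

  expect_warning(ols_fit(y2, cbind(X, X[, 2])), "aliased")
  expect_error(ols_fit(y2[1:3], X[1:3, ]), "n <=")
})

test_that("tobit with zero censoring reduces to OLS", {
  set.seed(15)
  n <- 80
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  X <- cbind(1, x)
  to <- tobit_fit(y, X, min(y) - 1, rep(FALSE, n))
  ol <- ols_fit(y, X)
  expect_true(to$converged)
  expect_equal(to$coefficients, ol$coefficients, tolerance = 1e-6,
               ignore_attr = TRUE)
  # MLE scale uses n, OLS n - p
  expect_equal(to$sigma, ol$sigma * sqrt((n - 2) / n), tolerance = 1e-4)
  # 2% censoring stays within a whisker of OLS
  cen <- rank(y) <= 2
  cc <- min(y[!cen]) - 1e-10
  to2 <- tobit_fit(y, X, cc, cen)
  expect_equal(unname(to2$coefficients[2]), unname(ol$coefficients[2]),
               tolerance = 0.05)
})

test_that("tobit MLE matches a dense grid-search likelihood oracle (n=40)", {
  set.seed(16)
  n <- 40
  x <- rnorm(n)
  lat <- 0.3 + 0.8 * x + rnorm(n, 0, 0.9)
  cc <- unname(quantile(lat, 0.3))
  cen <- lat < cc
  y <- lat; y[cen] <- cc - 0.5   # censored entries' stored values are inert
  X <- cbind(1, x)
  fit <- tobit_fit(y, X, cc, cen)
  expect_true(fit$converged)

  nll <- function(b0, b1, s) {
    mu <- b0 + b1 * x
    -(sum(dnorm((lat[!cen] - mu[!cen]) / s, log = TRUE) - log(s)) +
        sum(pnorm((cc - mu[cen]) / s, log.p = TRUE)))
  }
  # profile the intercept on a fine grid for each (slope, sigma) cell
  slopes <- seq(0.2, 1.6, by = 0.005)
  sigmas <- seq(0.5, 1.6, by = 0.005)
  best <- c(Inf, NA, NA)
  for (s in sigmas) {
    vals <- vapply(slopes, function(b1)
      optimize(function(b0) nll(b0, b1, s), c(-3, 3), tol = 1e-9)$objective,
      numeric(1))
    if (min(vals) < best[1])
      best <- c(min(vals), slopes[which.min(vals)], s)
  }
  expect_equal(unname(fit$coefficients[2]), best[2], tolerance = 1e-2)
  expect_equal(fit$sigma, best[3], tolerance = 1e-2)
  expect_lte(-fit$loglik, best[1] + 1e-6)  # MLE at least as good as the grid
})

test_that("tobit agrees with an independent censored-gaussian fitter", {
  skip_if_not_installed("survival")
  set.seed(17)
  n <- 150
  x <- rnorm(n)
  lat <- -0.2 + 0.6 * x + rnorm(n, 0, 0.8)
  cc <- unname(quantile(lat, 0.35))
  cen <- lat < cc
  y <- lat; y[cen] <- cc
  fit <- tobit_fit(y, cbind(1, x), cc, cen)
  sr <- survival::survreg(survival::Surv(y, !cen, type = "left") ~ x,
                          dist = "gaussian")
  expect_equal(unname(fit$coefficients), unname(coef(sr)), tolerance = 1e-4)
  expect_equal(fit$sigma, sr$scale, tolerance = 1e-4)
  expect_equal(unname(fit$se[2]),
               unname(sqrt(diag(sr$var))[2]), tolerance = 1e-3)
})

test_that("tobit is unbiased where half-LLOQ OLS attenuates (30% censoring)", {
  set.seed(18)
  n <- 400; reps <- 60
  true_slope <- 0.3
  bt <- bo <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- rbinom(n, 2, 0.3)
    lat <- true_slope * g + rnorm(n, 0, 1)
    raw <- exp(lat)
    lloq <- unname(quantile(raw, 0.30))
    pa <- prepare_analyte(raw, raw < lloq, lloq, "a")
    X <- cbind(1, g)
    bt[r] <- tobit_fit(pa$y, X, pa$c, pa$censored_mask)$coefficients[2]
    bo[r] <- ols_fit(pa$y, X)$coefficients[2]
  }
  # effects live on the INT scale; compare both estimators to the tobit mean
  # (the INT rescales the latent slope slightly, so judge attenuation)
  expect_gt(mean(bt), mean(bo))           # OLS on imputed data attenuates
  expect_lt(abs(mean(bt) - true_slope) , 0.05)
  expect_gt((mean(bt) - mean(bo)), 2 * abs(mean(bt) - true_slope))
})

test_that("logistic fit reproduces closed-form 2x2 odds ratios", {
  # balanced table, OR = 1
  y <- rep(c(1, 0, 1, 0), times = c(10, 10, 10, 10))
  x <- rep(c(0, 0, 1, 1), times = c(10, 10, 10, 10))
  f <- logistic_fit(y, cbind(1, x))
  expect_equal(unname(f$coefficients[2]), 0, tolerance = 1e-8)
  expect_equal(unname(2 * pnorm(-abs(f$coefficients[2] / f$se[2]))), 1,
               tolerance = 1e-6)
  # (20,10 / 10,20): OR = 4
  y2 <- rep(c(1, 0, 1, 0), times = c(20, 10, 10, 20))
  x2 <- rep(c(0, 1), times = c(30, 30))
  f2 <- logistic_fit(y2, cbind(1, x2))
  expect_equal(unname(f2$coefficients[2]), -log(4), tolerance = 1e-6)
  expect_true(f2$converged)
  # perfect separation flagged
  ys <- c(rep(0, 10), rep(1, 10))
  xs <- c(rnorm(10, -3), rnorm(10, 3))
  expect_warning(fs <- logistic_fit(ys, cbind(1, xs)), "separation")
  expect_false(fs$converged)
  expect_error(logistic_fit(rep(1, 10), cbind(1, rnorm(10))), "class")
})

test_that("Wald p-values equal 2*pnorm(-|z|) in scans", {
  set.seed(19)
  st <- simulate_study(sim_config(seed = 19, n1 = 120, n2 = 100,
    n_variants = 15,
    analytes = list(analyte_spec("a1", censor_q = 0))))
  X1 <- covariate_design(st$cohort1$covariates)
  s1 <- scan_analyte(prep_analyte(st$cohort1, "a1"), st$cohort1$genotypes, X1)
  ok <- s1$converged
  expect_equal(s1$p[ok], 2 * pnorm(-abs(s1$beta[ok] / s1$se[ok])),
               tolerance = 1e-12)
  expect_equal(s1$z[ok], s1$beta[ok] / s1$se[ok], tolerance = 1e-12)
})

test_that("a planted pQTL attains the scan minimum p and monomorphics are flagged", {
  cfg <- sim_config(seed = 20, n1 = 600, n2 = 500, n_variants = 30,
    maf_range = c(0.1, 0.5),
    analytes = list(analyte_spec("a1", causal_variants = "v0007",
                                 slopes = 0.8, censor_q = 0)))
  st <- simulate_study(cfg)
  X1 <- covariate_design(st$cohort1$covariates)
  s1 <- scan_analyte(prep_analyte(st$cohort1, "a1"), st$cohort1$genotypes, X1)
  expect_equal(s1$variant_id[which.min(s1$p)], "v0007")

  # inject a monomorphic variant
  g <- st$cohort1$genotypes
  g$dosage[, "v0001"] <- 0
  s2 <- scan_analyte(prep_analyte(st$cohort1, "a1"), g, X1)
  row <- s2[s2$variant_id == "v0001", ]
  expect_equal(row$beta, 0); expect_equal(row$p, 1)
  expect_false(row$converged)
})

test_that("fast linear path equals the per-variant engine", {
  cfg <- sim_config(seed = 22, n1 = 150, n2 = 100, n_variants = 10,
    analytes = list(analyte_spec("a1", causal_variants = "v0003",
                                 slopes = 0.4, censor_q = 0)))
  st <- simulate_study(cfg)
  b <- st$cohort1
  X <- covariate_design(b$covariates)
  pa <- prep_analyte(b, "a1")
  fast <- scan_analyte(pa, b$genotypes, X)
  # force the slow path via one missing dosage in an unrelated variant
  g2 <- b$genotypes
  g2$dosage[1, "v0010"] <- NA
  slow <- scan_analyte(pa, g2, X)
  keep <- slow$variant_id != "v0010"
  expect_equal(fast$beta[keep], slow$beta[keep], tolerance = 1e-10)
  expect_equal(fast$se[keep], slow$se[keep], tolerance = 1e-10)
  expect_equal(fast$p[keep], slow$p[keep], tolerance = 1e-10)
})

test_that("null scans control type-I error at nominal level", {
  cfg <- sim_config(seed = 23, n1 = 250, n2 = 200, n_variants = 400,
    maf_range = c(0.05, 0.5),
    analytes = list(analyte_spec("a1", censor_q = 0)))
  st <- simulate_study(cfg)
  X1 <- covariate_design(st$cohort1$covariates)
  s1 <- scan_analyte(prep_analyte(st$cohort1, "a1"), st$cohort1$genotypes, X1)
  rate <- mean(s1$p < 0.05)
  # binomial 99% band around 0.05 at 400 tests
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / 400) + 1e-9)
  expect_gt(ks.test(s1$p, "punif")$p.value, 0.01)
})
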
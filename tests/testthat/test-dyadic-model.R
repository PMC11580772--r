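# Reduced-scale MCMC settings are used throughout (2 short chains); the
# convergence gate is relaxed accordingly via fastMCMC().

test_that("input validation catches broken dyad tables", {
  d <- simDyadCounts(seed = 1)
  expect_error(fitNBMultiMembership(d[1:5, ], terms = "x_contact"),
               "at least 10")
  bad <- d; bad$possible_minutes[3] <- 0
  expect_error(fitNBMultiMembership(bad, terms = "x_contact"),
               "exposure")
  bad <- d; bad$groom_minutes[1] <- -2
  expect_error(fitNBMultiMembership(bad, terms = "x_contact"), "counts")
  bad <- d; bad$bat_j[2] <- bad$bat_i[2]
  expect_error(fitNBMultiMembership(bad, terms = "x_contact"), "bat_i")
  dup <- d; dup$x2 <- dup$x_contact
  expect_error(fitNBMultiMembership(dup, terms = c("x_contact", "x2")),
               "rank-deficient")
})

test_that("contact standardization uses unfamiliar dyads as reference", {
  d <- data.frame(x_contact = c(1, 2, 3, 10, 20),
                  unfamiliar = c(1, 1, 1, 0, 0))
  z <- standardizeContact(d)
  expect_equal(mean(z$x_contact[z$unfamiliar == 1]), 0, tolerance = 1e-12)
  expect_equal(sd(z$x_contact[z$unfamiliar == 1]), 1, tolerance = 1e-12)
  st <- attr(z, "zStats")
  expect_equal(unname(st["mean"]), 2)
  expect_error(standardizeContact(data.frame(x_contact = rep(1, 4),
                                             unfamiliar = 1)),
               "zero variance")
})

test_that("a fixed seed reproduces draws and label swaps leave fits invariant", {
  d <- simDyadCounts(nBats = 10, beta = 0.5, seed = 3)
  mc <- fastMCMC()
  f1 <- do.call(fitNBMultiMembership,
                c(list(d, terms = "x_contact", seed = 42L), mc))
  f2 <- do.call(fitNBMultiMembership,
                c(list(d, terms = "x_contact", seed = 42L), mc))
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
  ## undirected membership: swapping bat_i/bat_j is the same model
  sw <- d; sw$bat_i <- d$bat_j; sw$bat_j <- d$bat_i
  f3 <- do.call(fitNBMultiMembership,
                c(list(sw, terms = "x_contact", seed = 42L), mc))
  expect_identical(posteriorDraws(f1), posteriorDraws(f3))
  ## diagnostics cover every monitored parameter
  dg <- convergenceDiagnostics(f1)
  expect_true(all(colnames(posteriorDraws(f1)) %in% dg$parameter))
})

test_that("the exposure offset makes coefficients rate-scale quantities", {
  d <- simDyadCounts(nBats = 12, beta = 0.6, sigmaBat = 0.2, seed = 7)
  mc <- fastMCMC()
  f1 <- do.call(fitNBMultiMembership,
                c(list(d, terms = "x_contact", seed = 1L), mc))
  d2 <- d
  d2$possible_minutes <- d$possible_minutes * 2
  d2$groom_minutes <- d$groom_minutes * 2
  f2 <- do.call(fitNBMultiMembership,
                c(list(d2, terms = "x_contact", seed = 1L), mc))
  b1 <- posteriorDraws(f1, "x_contact")[, 1]
  b2 <- posteriorDraws(f2, "x_contact")[, 1]
  pooled <- sqrt(sd(b1)^2 + sd(b2)^2)
  expect_lt(abs(mean(b1) - mean(b2)), 3 * pooled)
})

test_that("planted slope and random-effect structure are recovered", {
  b <- log(1.32)
  d <- simDyadCounts(nBats = 16, beta = b, sigmaBat = 0.4, phi = 3, seed = 11)
  mc <- fastMCMC()
  fit <- do.call(fitNBMultiMembership,
                 c(list(d, terms = "x_contact", standardize = FALSE,
                        seed = 2L), mc))
  dr <- posteriorDraws(fit, "x_contact")[, 1]
  ci <- quantile(dr, c(0.025, 0.975))
  expect_true(ci[1] <= b && b <= ci[2])
  ## sigma ordering: planted 0.8 vs 0 random-effect SD
  hi <- simDyadCounts(nBats = 14, beta = 0, sigmaBat = 0.8, seed = 12)
  lo <- simDyadCounts(nBats = 14, beta = 0, sigmaBat = 0.0, seed = 12)
  fh <- do.call(fitNBMultiMembership,
                c(list(hi, terms = "x_contact", standardize = FALSE,
                       seed = 3L), mc))
  fl <- do.call(fitNBMultiMembership,
                c(list(lo, terms = "x_contact", standardize = FALSE,
                       seed = 3L), mc))
  expect_gt(median(posteriorDraws(fh, "sigmaBat")[, 1]),
            median(posteriorDraws(fl, "sigmaBat")[, 1]))
})

test_that("percent change is the elementwise exp transform", {
  expect_equal(percentChange(0)$median, 0)
  expect_equal(percentChange(log(2))$median, 100)
  expect_equal(percentChange(log(1.32))$median, 32, tolerance = 1e-12)
  pc <- percentChange(c(log(1.1), log(1.2), log(1.3)))
  expect_equal(pc$draws, c(10, 20, 30), tolerance = 1e-9)
  expect_error(percentChange(numeric(0)), "draws")
})

test_that("draw-wise Bayesian R2 matches a hand computation and its limits", {
  ## 3 draws x 4 observations, hand-computable
  mu <- rbind(c(1, 2, 3, 4),
              c(2, 2, 2, 2),      # constant fit -> 0
              c(10, 10, 30, 30))
  phi <- c(2, 2, 5)
  hand <- function(m, p) {
    vf <- var(m); vr <- mean(m + m^2 / p); vf / (vf + vr)
  }
  r2 <- bayesR2Draws(mu, phi)
  expect_equal(r2[1], hand(mu[1, ], 2), tolerance = 1e-12)
  expect_equal(r2[2], 0)
  expect_equal(r2[3], hand(mu[3, ], 5), tolerance = 1e-12)
  expect_true(all(r2 >= 0 & r2 <= 1))

  ## noise-free limit: residual variance -> 0 gives R2 -> 1
  big <- matrix(c(1e8, 2e8, 3e8, 4e8), 1)
  expect_gt(bayesR2Draws(big, 1e12), 0.99)
})

test_that("R2 partition needs nested specs and is centered near zero under the null", {
  d <- simDyadCounts(nBats = 14, beta = 0, sigmaBat = 0.4, seed = 21)
  mc <- fastMCMC()
  full <- do.call(fitNBMultiMembership,
                  c(list(d, terms = "x_contact", standardize = FALSE,
                         seed = 5L), mc))
  intOnly <- do.call(fitNBMultiMembership,
                     c(list(d, terms = character(0), standardize = FALSE,
                            seed = 5L), mc))
  expect_error(r2Partition(full, full), "exactly one term")
  part <- r2Partition(full, intOnly)
  expect_identical(part$term, "x_contact")
  expect_true(part$lower <= 0 || abs(part$median) < 0.05)
  expect_lt(abs(part$median), 0.1)

  ## a strong planted slope claims a positive share
  ds <- simDyadCounts(nBats = 14, beta = 1, sigmaBat = 0.2, seed = 22)
  fs <- do.call(fitNBMultiMembership,
                c(list(ds, terms = "x_contact", standardize = FALSE,
                       seed = 6L), mc))
  rs <- do.call(fitNBMultiMembership,
                c(list(ds, terms = character(0), standardize = FALSE,
                       seed = 6L), mc))
  ps <- r2Partition(fs, rs)
  expect_gt(ps$median, 0)
  expect_gt(mean(ps$draws > 0), 0.9)
})

test_that("familiarity model returns one fit per window with the right sign", {
  d <- genStudy2(study2Config(seed = 71L, nBats = 12L,
                              encounterRateFamiliar = 0.6,
                              encounterRateUnfamiliar = 0.15))
  dur <- firstContactDurations(segmentEncounters(d$pings), d$bats)
  mc <- fastMCMC()
  fits <- do.call(familiarityModel,
                  c(list(dur, windowsH = c(4, 24), seed = 8L), mc))
  expect_named(fits, c("w4", "w24"))
  expect_s4_class(fits$w4, "PosteriorSummary")
  ## familiar pairs were planted with 4x the encounter rate
  b24 <- posteriorDraws(fits$w24, "unfamiliar")[, 1]
  expect_lt(median(b24), 0)
  expect_error(familiarityModel(dur, windowsH = 5), "not present")
})

test_that("prior-predictive draws have finite means under default priors", {
  set.seed(31)
  n <- 2000
  beta0 <- rnorm(n, 0, 5)
  sig <- abs(2.5 * rt(n, 3))
  u1 <- rnorm(n, 0, sig); u2 <- rnorm(n, 0, sig)
  mu <- exp(pmin(log(600) + beta0 + u1 + u2, 50))
  expect_true(all(is.finite(mu)))
  expect_true(is.finite(median(mu)))
})
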
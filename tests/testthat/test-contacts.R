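test_that("encounter segmentation splits on gaps and floors singleton durations", {
  p <- data.frame(bat_a = "X", bat_b = "Y", t_s = c(0, 10, 20),
                  rssi = c(-70, -60, -65))
  one <- segmentEncounters(p, maxGapS = 15, pingIntervalS = 2)
  expect_identical(nrow(one), 1L)
  expect_equal(one$start_s, 0); expect_equal(one$end_s, 20)
  expect_equal(one$duration_s, 20)
  expect_equal(one$max_rssi, -60); expect_identical(one$n_pings, 3L)

  three <- segmentEncounters(p, maxGapS = 5, pingIntervalS = 2)
  expect_identical(nrow(three), 3L)
  expect_equal(three$duration_s, rep(2, 3))  # singleton floor

  single <- segmentEncounters(p[1, ], maxGapS = 60, pingIntervalS = 2)
  expect_identical(single$n_pings, 1L)
  expect_equal(single$duration_s, 2)
  expect_error(segmentEncounters(p, maxGapS = -1), "maxGapS")
})

test_that("pair identity is unordered and streams are time-sorted per pair", {
  enc <- segmentEncounters(toyPings(), maxGapS = 60, pingIntervalS = 2)
  ## X-Y pings at 0-20 and 400-404 -> two encounters; Y-Z -> one
  expect_identical(nrow(enc), 3L)
  expect_identical(sum(enc$bat_a == "X" & enc$bat_b == "Y"), 2L)
  expect_true(all(enc$bat_a < enc$bat_b))
})

test_that("contact calling retains the top tail with ties kept", {
  set.seed(8)
  enc <- data.frame(bat_a = "X", bat_b = "Y", start_s = 1:100, end_s = 1:100,
                    duration_s = 2, max_rssi = sample(seq(-90, -40.5, by = 0.5)),
                    n_pings = 1L)
  top5 <- callContacts(enc, 0.95)
  expect_identical(nrow(top5), 5L)
  expect_setequal(top5$max_rssi, sort(enc$max_rssi, decreasing = TRUE)[1:5])

  flat <- enc; flat$max_rssi <- -60
  expect_identical(nrow(callContacts(flat, 0.95)), 100L)  # ties retained
  expect_error(callContacts(enc[0, ], 0.95), "empty")
  expect_error(callContacts(enc, 1.2), "quantile")
})

test_that("contact-calling threshold matches an independent sort-based rank", {
  set.seed(15)
  n <- 1000
  enc <- data.frame(bat_a = "X", bat_b = "Y", start_s = seq_len(n),
                    end_s = seq_len(n), duration_s = 2,
                    max_rssi = rnorm(n, -60, 8), n_pings = 1L)
  got <- callContacts(enc, 0.95)
  srt <- sort(enc$max_rssi)
  ## type-7 quantile by hand
  h <- (n - 1) * 0.95 + 1
  thr <- srt[floor(h)] + (h - floor(h)) * (srt[floor(h) + 1] - srt[floor(h)])
  expect_equal(attr(got, "threshold"), thr, tolerance = 1e-12)
  expect_identical(nrow(got), sum(enc$max_rssi >= thr))
  expect_lt(abs(nrow(got) / n - 0.05), 1 / n + 1e-9)
})

test_that("window durations intersect encounters with half-open windows", {
  enc <- data.frame(bat_a = "X", bat_b = "Y", start_s = 3.9 * 3600,
                    end_s = 4.1 * 3600, duration_s = 0.2 * 3600,
                    max_rssi = -50, n_pings = 100L)
  dur <- firstContactDurations(enc, toyBats())
  xy <- dur[dur$bat_a == "X" & dur$bat_b == "Y", ]
  expect_equal(xy$w4, 6)    # only the part before 4 h
  expect_equal(xy$w8, 12)   # the whole encounter
  ## all other pairs present with zero
  expect_identical(nrow(dur), 6L)
  expect_true(all(dur$w24[!(dur$bat_a == "X" & dur$bat_b == "Y")] == 0))
  expect_error(firstContactDurations(enc, toyBats()[1:2, ]),
               NA)  # X and Y known
  bad <- enc; bad$bat_a <- "NOPE"
  expect_error(firstContactDurations(bad, toyBats()), "unknown bat")
})

test_that("minutes are monotone in window length and consistent at 24 h", {
  d <- genStudy2(study2Config(seed = 33L, nBats = 12L))
  enc <- segmentEncounters(d$pings)
  dur <- firstContactDurations(enc, d$bats)
  wc <- paste0("w", c(4, 8, 12, 16, 20, 24))
  m <- as.matrix(dur[, wc])
  expect_true(all(diff(t(m)) >= -1e-9))
  ## conservation: 24-h value equals the sum of per-interval increments
  inc <- cbind(m[, 1], t(diff(t(m))))
  expect_equal(rowSums(inc), m[, 6], tolerance = 1e-9)
  ## ledger oracle
  pw <- d$truth$pairWindows
  i <- match(paste(dur$bat_a, dur$bat_b), paste(pw$bat_a, pw$bat_b))
  for (w in wc) expect_equal(dur[[w]], pw[[w]][i], tolerance = 1e-12)
})

test_that("density counts positive pairs and grows with the window", {
  d <- genStudy2(study2Config(seed = 41L, nBats = 12L))
  enc <- segmentEncounters(d$pings)
  dur <- firstContactDurations(callContacts(enc, 0.8), d$bats)
  dens <- vapply(c(4, 8, 12, 16, 20, 24), function(w)
    networkMetrics(contactNetwork(dur, d$bats, w))$density, numeric(1))
  expect_true(all(diff(dens) >= 0))
  expect_true(all(dens >= 0 & dens <= 1))
})

test_that("assortativity matches the closed-form categorical coefficient", {
  bats <- toyBats()  # X,Y in S1; Z,W in S2
  mk <- function(edges) {
    dur <- edges
    siteOf <- setNames(bats$site, bats$bat)
    dur$familiar <- siteOf[dur$bat_a] == siteOf[dur$bat_b]
    names(dur)[names(dur) == "minutes"] <- "w4"
    contactNetwork(dur, bats, 4)
  }
  ## perfectly within-site network
  within <- mk(data.frame(bat_a = c("X", "Z"), bat_b = c("Y", "W"),
                          minutes = c(5, 9)))
  expect_equal(networkMetrics(within)$assortativity, 1)

  ## hand-computed mixing matrix: edges X-Y (w=2, S1-S1), X-Z (w=1, S1-S2),
  ## Y-W (w=1, S1-S2). Total stub weight 2*4=8.
  ## e = [[4, 2], [2, 0]]/8; a = (6/8, 2/8)
  ## r = (sum e_ii - sum a_i^2) / (1 - sum a_i^2)
  ##   = (0.5 - (0.5625 + 0.0625)) / (1 - 0.625) = -0.125/0.375 = -1/3
  toy <- mk(data.frame(bat_a = c("X", "X", "Y"), bat_b = c("Y", "Z", "W"),
                       minutes = c(2, 1, 1)))
  expect_equal(networkMetrics(toy)$assortativity, -1 / 3, tolerance = 1e-12)

  ## empty network
  none <- mk(data.frame(bat_a = "X", bat_b = "Y", minutes = 0))
  m <- networkMetrics(none)
  expect_equal(m$density, 0)
  expect_true(is.na(m$assortativity))
})

test_that("random edge placement gives near-zero mean assortativity", {
  ## sites large enough that the no-self-pair finite-size bias (within-site
  ## pairs are n(n-1)/2, not n^2/2) is negligible
  bats <- data.frame(bat = sprintf("b%02d", 1:45),
                     site = rep(c("S1", "S2", "S3"), each = 15),
                     stringsAsFactors = FALSE)
  prs <- t(combn(bats$bat, 2))
  siteOf <- setNames(bats$site, bats$bat)
  set.seed(55)
  r <- vapply(1:50, function(k) {
    sel <- sample.int(nrow(prs), 300)
    dur <- data.frame(bat_a = prs[sel, 1], bat_b = prs[sel, 2],
                      w4 = runif(300, 1, 5), stringsAsFactors = FALSE)
    dur$familiar <- siteOf[dur$bat_a] == siteOf[dur$bat_b]
    networkMetrics(contactNetwork(dur, bats, 4))$assortativity
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("unweighted assortativity agrees with igraph", {
  skip_if_not_installed("igraph")
  bats <- data.frame(bat = sprintf("b%02d", 1:15),
                     site = rep(c("S1", "S2", "S3"), each = 5),
                     stringsAsFactors = FALSE)
  prs <- t(combn(bats$bat, 2))
  siteOf <- setNames(bats$site, bats$bat)
  set.seed(9)
  sel <- sample.int(nrow(prs), 40)
  dur <- data.frame(bat_a = prs[sel, 1], bat_b = prs[sel, 2], w4 = 1,
                    stringsAsFactors = FALSE)
  dur$familiar <- siteOf[dur$bat_a] == siteOf[dur$bat_b]
  mine <- networkMetrics(contactNetwork(dur, bats, 4))$assortativity
  g <- igraph::graph_from_data_frame(dur[, 1:2], directed = FALSE,
                                     vertices = bats$bat)
  ig <- igraph::assortativity_nominal(
    g, as.integer(factor(siteOf[igraph::V(g)$name])))
  expect_equal(mine, ig, tolerance = 1e-12)
})

test_that("familiarity contrast bootstraps pair means per class and window", {
  d <- genStudy2(study2Config(seed = 61L, nBats = 12L,
                              encounterRateFamiliar = 0.6,
                              encounterRateUnfamiliar = 0.15))
  dur <- firstContactDurations(segmentEncounters(d$pings), d$bats)
  fc <- familiarityContrast(dur, nBoot = 500, seed = 9)
  expect_identical(nrow(fc), 12L)  # 6 windows x 2 classes
  expect_true(all(fc$lower <= fc$mean & fc$mean <= fc$upper))
  ## planted ordering: familiar pairs accumulate more contact at 24 h
  m24 <- fc[fc$window_h == 24, ]
  expect_gt(m24$mean[m24$familiar], m24$mean[!m24$familiar])
  ## degenerate class: all zeros -> point CI
  dur0 <- dur; dur0[dur0$familiar, paste0("w", c(4, 8, 12, 16, 20, 24))] <- 0
  fc0 <- familiarityContrast(dur0, nBoot = 200, seed = 1)
  z <- fc0[fc0$familiar & fc0$window_h == 4, ]
  expect_equal(c(z$mean, z$lower, z$upper), c(0, 0, 0))
  expect_error(familiarityContrast(dur[dur$familiar, ]), "classes")
})

test_that("planted familiarity ordering is detected across replicates", {
  ok <- vapply(1:20, function(k) {
    d <- genStudy2(study2Config(seed = 600L + k, nBats = 12L,
                                encounterRateFamiliar = 0.5,
                                encounterRateUnfamiliar = 0.25))
    pw <- d$truth$pairWindows
    mean(pw$w24[pw$familiar]) > mean(pw$w24[!pw$familiar])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
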
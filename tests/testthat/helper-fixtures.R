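# Small in-code fixtures shared across test files.

# one 2-bat cage and one 4-bat cage with an introduced stranger each
toyCages <- function() {
  data.frame(
    cage = c("C1", "C1", "C2", "C2", "C2", "C2"),
    bat = c("A", "B", "C", "D", "E", "F"),
    site = c("S2", "S1", "S2", "S1", "S1", "S1"),
    role = c("stranger", "resident", "stranger", rep("resident", 3)),
    stringsAsFactors = FALSE)
}

toyEvents <- function() {
  data.frame(
    actor = c("A", "A", "B", "C", "C"),
    receiver = c("B", "B", "A", "D", "E"),
    behavior = c("affiliative", "affiliative", "aggressive",
                 "affiliative", "affiliative"),
    onset_s = c(0, 1000, 50, 200, 21000),
    duration_s = c(100, 52, 10, 300, 400),
    stringsAsFactors = FALSE)
}

# deterministic ping stream: two encounters for one pair, one for another
toyPings <- function() {
  rbind(
    data.frame(bat_a = "X", bat_b = "Y", t_s = c(0, 10, 20), rssi = c(-70, -60, -65)),
    data.frame(bat_a = "Y", bat_b = "Z", t_s = 500, rssi = -50),
    data.frame(bat_a = "X", bat_b = "Y", t_s = c(400, 404), rssi = c(-80, -75)))
}

toyBats <- function() {
  data.frame(bat = c("X", "Y", "Z", "W"), site = c("S1", "S1", "S2", "S2"),
             stringsAsFactors = FALSE)
}

# grid-search oracle for the aggregated binomial likelihood: maximize over
# (intercept, slope) by nested refinement, independent of glm()
gridAggBinomSlope <- function(z, successes, trials,
                              span = 10, steps = 61, rounds = 6) {
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * z)
    sum(successes * log(p) + (trials - successes) * log1p(-p))
  }
  c0 <- c1 <- 0; s <- span
  for (r in seq_len(rounds)) {
    g0 <- seq(c0 - s, c0 + s, length.out = steps)
    g1 <- seq(c1 - s, c1 + s, length.out = steps)
    vals <- outer(g0, g1, Vectorize(ll))
    i <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    c0 <- g0[i[1]]; c1 <- g1[i[2]]
    s <- s / (steps / 4)
  }
  c(intercept = c0, slope = c1)
}

# tiny dyadic dataset for NB multi-membership fits (deterministic shape,
# stochastic counts under a supplied seed)
simDyadCounts <- function(nBats = 12, beta = 0, sigmaBat = 0.3, phi = 3,
                          seed = 1) {
  set.seed(seed)
  bats <- sprintf("b%02d", seq_len(nBats))
  prs <- t(combn(bats, 2))
  n <- nrow(prs)
  x <- rnorm(n)
  u <- rnorm(nBats, 0, sigmaBat); names(u) <- bats
  possible <- round(runif(n, 200, 800))
  mu <- exp(log(possible) - 4 + beta * x + u[prs[, 1]] + u[prs[, 2]])
  data.frame(bat_i = prs[, 1], bat_j = prs[, 2],
             groom_minutes = rnbinom(n, size = phi, mu = mu),
             possible_minutes = possible, x_contact = x,
             unfamiliar = 1L, stringsAsFactors = FALSE)
}

fastMCMC <- function() list(nChains = 2L, nAdapt = 300L, nBurn = 300L,
                            nIter = 700L, rhatMax = 1.3)
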
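## Synthetic-data generators with ground-truth ledgers.
##
## Both generators emulate introduction experiments on female vampire bats:
## Study-1-style small-cage introductions with scored first interactions and
## long-term aggregated-binomial cooperation rates, and Study-2-style
## flight-cage introductions tracked with proximity sensors and followed by
## long-term allogrooming counts. Every random quantity is recorded in a
## ground-truth ledger so downstream stages can be tested by exact
## bookkeeping and parameter recovery.

#' Create a Study-1-style generator configuration
#'
#' Defaults emulate the small-cage introduction design: 18 cages of 2 or 4
#' adult females, the first 6 h of behaviour scored, affiliative events an
#' order of magnitude more common and longer than aggressive ones (mean
#' affiliative duration about 252 s, aggressive durations capped near 25 s),
#' and long-term cooperation observed over roughly 10 months as
#' seconds-with-behaviour out of possible seconds.
#'
#' @param nCages number of introduction cages.
#' @param cageSizes integer vector of cage sizes (2 or 4), length `nCages`.
#' @param eventRateAffiliative,eventRateAggressive events per hour per
#'   directed cagemate pair.
#' @param affilDurationMeanS mean affiliative event duration (seconds).
#' @param horizonS scored window in seconds (default 6 h = 21600 s).
#' @param obsDays long-term observation span in days.
#' @param baselineLogit intercept of the long-term behaviour logit.
#' @param effectAffiliative planted slope of standardized first-interaction
#'   affiliative seconds on the long-term logit.
#' @param dyadNoiseSD SD of dyad-level logit noise.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a validated \code{\link{Study1Config-class}} object.
#' @export
study1Config <- function(nCages = 18L,
                         cageSizes = rep(c(2L, 4L), length.out = 18L),
                         eventRateAffiliative = 0.5,
                         eventRateAggressive = 0.05,
                         affilDurationMeanS = 252,
                         horizonS = 21600,
                         obsDays = 303,
                         baselineLogit = -6,
                         effectAffiliative = 0,
                         dyadNoiseSD = 0.5,
                         seed = 1L) {
  new("Study1Config",
      nCages = as.integer(nCages),
      cageSizes = as.integer(cageSizes),
      eventRateAffiliative = eventRateAffiliative,
      eventRateAggressive = eventRateAggressive,
      affilDurationMeanS = affilDurationMeanS,
      horizonS = horizonS,
      obsDays = obsDays,
      baselineLogit = baselineLogit,
      effectAffiliative = effectAffiliative,
      dyadNoiseSD = dyadNoiseSD,
      seed = as.integer(seed))
}

#' Create a Study-2-style generator configuration
#'
#' Defaults emulate 20 sensor-tagged females from 3 capture sites (190
#' unordered pairs, 133 unfamiliar), pings every 2 s during encounters, and
#' long-term allogrooming counts drawn from a negative binomial with a
#' log-exposure offset, per-bat random intercepts, and a forced-proximity
#' treatment crossed with a pre/post period. The planted
#' forced-proximity-by-period interaction defaults to \code{log(3.38)}, i.e.
#' a 238\% rate increase; \code{betaContact} defaults to 0 (no effect of
#' first contacts).
#'
#' @param nBats,nSites tagged bats and capture sites.
#' @param pingIntervalS sensor ping interval (seconds).
#' @param encounterRateFamiliar,encounterRateUnfamiliar encounters per hour
#'   per pair by familiarity class.
#' @param encounterDurationMeanS mean encounter duration (seconds).
#' @param rssiNoiseSD per-ping RSSI noise SD (signal units).
#' @param betaContact planted slope of standardized first-contact minutes
#'   (4-h window) on the log grooming rate.
#' @param betaTreatmentInteraction planted forced-proximity x post-period
#'   log-rate interaction.
#' @param phi negative-binomial dispersion (size).
#' @param sigmaBat SD of per-bat random intercepts.
#' @param seed integer seed.
#' @return a validated \code{\link{Study2Config-class}} object.
#' @export
study2Config <- function(nBats = 20L,
                         nSites = 3L,
                         pingIntervalS = 2,
                         encounterRateFamiliar = 0.5,
                         encounterRateUnfamiliar = 0.25,
                         encounterDurationMeanS = 120,
                         rssiNoiseSD = 4,
                         betaContact = 0,
                         betaTreatmentInteraction = log(3.38),
                         phi = 2,
                         sigmaBat = 0.5,
                         seed = 1L) {
  new("Study2Config",
      nBats = as.integer(nBats),
      nSites = as.integer(nSites),
      pingIntervalS = pingIntervalS,
      encounterRateFamiliar = encounterRateFamiliar,
      encounterRateUnfamiliar = encounterRateUnfamiliar,
      encounterDurationMeanS = encounterDurationMeanS,
      rssiNoiseSD = rssiNoiseSD,
      betaContact = betaContact,
      betaTreatmentInteraction = betaTreatmentInteraction,
      phi = phi,
      sigmaBat = sigmaBat,
      seed = as.integer(seed))
}

## log-normal parameterized by its arithmetic mean and sdlog
.rlnormMean <- function(n, mean, sdlog) {
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a Study-1-style dataset with a ground-truth ledger
#'
#' Simulates timed affiliative and aggressive events between cagemates over
#' the scored introduction window, then draws long-term grooming and sharing
#' seconds for each directed introduced (unfamiliar) dyad from an aggregated
#' binomial whose logit is \code{baselineLogit + effectAffiliative * z} plus
#' dyad-level noise, where \code{z} is the standardized affiliative
#' first-interaction seconds across the introduced dyads.
#'
#' In 4-bat cages one bat is the introduced stranger (the unfamiliar dyads
#' are stranger-resident pairs); in 2-bat cages the single dyad is
#' unfamiliar. Events occur between all cagemates; long-term rows are
#' produced for introduced dyads only, in both directions. Events that would
#' cross the scoring horizon are truncated at it.
#'
#' @param config a \code{\link{study1Config}} object.
#' @return list with elements \code{events} (actor, receiver, behavior,
#'   onset_s, duration_s), \code{cages} (cage, bat, site, role),
#'   \code{longterm} (actor, receiver, response, behavior_s, possible_s) and
#'   \code{truth}, a ledger holding the exact per-dyad event totals, the
#'   planted coefficients and the dyad noise.
#' @export
genStudy1 <- function(config) {
  stopifnot(is(config, "Study1Config"))
  validObject(config)
  set.seed(config@seed)
  horizon <- config@horizonS

  ## cage membership: fresh bats per cage; residents from site S1, the
  ## introduced stranger from site S2
  cages <- do.call(rbind, lapply(seq_len(config@nCages), function(ci) {
    sz <- config@cageSizes[ci]
    bats <- sprintf("C%02dB%d", ci, seq_len(sz))
    data.frame(cage = sprintf("C%02d", ci), bat = bats,
               site = c("S2", rep("S1", sz - 1L)),
               role = c("stranger", rep("resident", sz - 1L)),
               stringsAsFactors = FALSE)
  }))

  ## directed cagemate pairs
  dyads <- do.call(rbind, lapply(split(cages, cages$cage), function(cg) {
    g <- expand.grid(actor = cg$bat, receiver = cg$bat,
                     stringsAsFactors = FALSE)
    g <- g[g$actor != g$receiver, ]
    g$cage <- cg$cage[1]
    g$unfamiliar <- cg$role[match(g$actor, cg$bat)] == "stranger" |
      cg$role[match(g$receiver, cg$bat)] == "stranger"
    g
  }))
  rownames(dyads) <- NULL

  horizonH <- horizon / 3600
  genEvents <- function(rate, behavior, durFun) {
    n <- rpois(nrow(dyads), rate * horizonH)
    idx <- rep(seq_len(nrow(dyads)), n)
    if (!length(idx))
      return(data.frame(actor = character(), receiver = character(),
                        behavior = character(), onset_s = numeric(),
                        duration_s = numeric(), stringsAsFactors = FALSE))
    onset <- runif(length(idx), 0, horizon)
    dur <- pmin(durFun(length(idx)), horizon - onset)  # truncate at horizon
    dur <- pmax(dur, 1)
    data.frame(actor = dyads$actor[idx], receiver = dyads$receiver[idx],
               behavior = behavior, onset_s = onset,
               duration_s = pmin(dur, horizon - onset),
               stringsAsFactors = FALSE)
  }
  events <- rbind(
    genEvents(config@eventRateAffiliative, "affiliative",
              function(n) .rlnormMean(n, config@affilDurationMeanS, 0.8)),
    genEvents(config@eventRateAggressive, "aggressive",
              function(n) pmin(.rlnormMean(n, 8, 0.7), 25))
  )
  events <- events[order(events$onset_s), ]
  rownames(events) <- NULL

  ## exact per-directed-dyad totals
  totals <- dyads[, c("actor", "receiver", "cage", "unfamiliar")]
  for (b in c("affiliative", "aggressive")) {
    ev <- events[events$behavior == b, ]
    key <- paste(ev$actor, ev$receiver)
    s <- tapply(ev$duration_s, key, sum)
    v <- as.numeric(s[paste(totals$actor, totals$receiver)])
    totals[[paste0(b, "_s")]] <- ifelse(is.na(v), 0, v)
  }

  ## long-term aggregated binomial for introduced (unfamiliar) directed dyads
  lt <- totals[totals$unfamiliar, ]
  x <- lt$affiliative_s
  z <- if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  noise <- rnorm(nrow(lt), 0, config@dyadNoiseSD)
  scaleDays <- config@obsDays / 303
  longterm <- do.call(rbind, lapply(c("grooming", "sharing"), function(resp) {
    possMin <- if (resp == "grooming") runif(nrow(lt), 540, 1860)
               else runif(nrow(lt), 240, 960)
    possible <- round(possMin * 60 * scaleDays)
    p <- plogis(config@baselineLogit + config@effectAffiliative * z + noise)
    data.frame(actor = lt$actor, receiver = lt$receiver, response = resp,
               behavior_s = rbinom(nrow(lt), possible, p),
               possible_s = possible, stringsAsFactors = FALSE)
  }))
  rownames(longterm) <- NULL

  truth <- list(
    directedTotals = totals,
    coefficients = c(baselineLogit = config@baselineLogit,
                     effectAffiliative = config@effectAffiliative),
    dyadNoise = data.frame(actor = lt$actor, receiver = lt$receiver,
                           noise = noise, z = z, stringsAsFactors = FALSE),
    eventSecondsTotal = sum(events$duration_s)
  )
  list(events = events, cages = cages, longterm = longterm, truth = truth)
}

#' Generate a Study-2-style dataset with a ground-truth ledger
#'
#' Simulates, for each unordered pair of bats, encounter episodes over the
#' first 24 h (higher rates for familiar pairs when configured), emits
#' regular sensor pings during each encounter with Gaussian RSSI noise
#' around a familiarity-independent encounter level, and draws long-term
#' allogrooming minutes per dyad and period (pre/post treatment) from a
#' negative binomial with log-exposure offset, planted fixed effects and
#' per-bat random intercepts.
#'
#' Encounters closer than 60 s are merged before pings are emitted, so
#' encounter segmentation at the default gap reconstructs the ledger
#' exactly. The planted contact slope acts on first-contact minutes in the
#' first 4 h, standardized over unfamiliar pairs.
#'
#' @param config a \code{\link{study2Config}} object.
#' @return list with elements \code{pings} (bat_a, bat_b, t_s, rssi),
#'   \code{bats} (bat, site), \code{grooming} (one row per dyad x period)
#'   and \code{truth}, a ledger with realized encounters, per-pair window
#'   minutes, per-row NB means, random effects and planted coefficients.
#' @export
genStudy2 <- function(config) {
  stopifnot(is(config, "Study2Config"))
  validObject(config)
  set.seed(config@seed)
  horizonS <- 24 * 3600
  gapS <- 60  # minimum separation between distinct encounters

  bats <- data.frame(
    bat = sprintf("B%02d", seq_len(config@nBats)),
    site = sprintf("S%d", rep_len(seq_len(config@nSites), config@nBats)),
    stringsAsFactors = FALSE)

  pairs <- t(utils::combn(bats$bat, 2L))
  pairDf <- data.frame(bat_a = pairs[, 1], bat_b = pairs[, 2],
                       stringsAsFactors = FALSE)
  siteOf <- setNames(bats$site, bats$bat)
  pairDf$familiar <- siteOf[pairDf$bat_a] == siteOf[pairDf$bat_b]

  ## -- encounters and pings -----------------------------------------------
  encList <- vector("list", nrow(pairDf))
  pingList <- vector("list", nrow(pairDf))
  for (k in seq_len(nrow(pairDf))) {
    rate <- if (pairDf$familiar[k]) config@encounterRateFamiliar
            else config@encounterRateUnfamiliar
    n <- rpois(1, rate * 24)
    if (n == 0) next
    start <- sort(runif(n, 0, horizonS))
    dur <- rexp(n, 1 / config@encounterDurationMeanS)
    ## merge episodes separated by <= gapS so segmentation is unambiguous
    end <- start + dur
    keepStart <- start[1]; keepEnd <- end[1]
    ms <- numeric(); me <- numeric()
    for (i in seq_len(n)[-1]) {
      if (start[i] - keepEnd <= gapS) keepEnd <- max(keepEnd, end[i])
      else { ms <- c(ms, keepStart); me <- c(me, keepEnd)
             keepStart <- start[i]; keepEnd <- end[i] }
    }
    ms <- c(ms, keepStart); me <- c(me, min(keepEnd, horizonS))
    me <- pmin(me, horizonS)
    ok <- ms < horizonS
    ms <- ms[ok]; me <- me[ok]
    if (!length(ms)) next
    level <- rnorm(length(ms), -60, 6)
    ep <- lapply(seq_along(ms), function(i) {
      t <- seq(ms[i], me[i], by = config@pingIntervalS)
      data.frame(bat_a = pairDf$bat_a[k], bat_b = pairDf$bat_b[k], t_s = t,
                 rssi = level[i] + rnorm(length(t), 0, config@rssiNoiseSD),
                 enc = i, stringsAsFactors = FALSE)
    })
    ep <- do.call(rbind, ep)
    pingList[[k]] <- ep[, c("bat_a", "bat_b", "t_s", "rssi")]
    ## realized encounter spans as seen by the sensor stream
    encList[[k]] <- do.call(rbind, lapply(split(ep, ep$enc), function(e)
      data.frame(bat_a = e$bat_a[1], bat_b = e$bat_b[1],
                 start_s = min(e$t_s), end_s = max(e$t_s),
                 max_rssi = max(e$rssi), n_pings = nrow(e),
                 stringsAsFactors = FALSE)))
  }
  pings <- do.call(rbind, c(pingList,
    list(data.frame(bat_a = character(), bat_b = character(),
                    t_s = numeric(), rssi = numeric(),
                    stringsAsFactors = FALSE))))
  encounters <- do.call(rbind, c(encList,
    list(data.frame(bat_a = character(), bat_b = character(),
                    start_s = numeric(), end_s = numeric(),
                    max_rssi = numeric(), n_pings = integer(),
                    stringsAsFactors = FALSE))))
  rownames(pings) <- rownames(encounters) <- NULL

  ## ledger window minutes (same conventions as firstContactDurations)
  windowsH <- c(4, 8, 12, 16, 20, 24)
  dur <- pmax(encounters$end_s - encounters$start_s, config@pingIntervalS)
  winMin <- sapply(windowsH, function(w) {
    ov <- pmin(encounters$start_s + dur, w * 3600) - encounters$start_s
    ov <- pmax(ov, 0)
    key <- paste(encounters$bat_a, encounters$bat_b)
    s <- tapply(ov, key, sum) / 60
    out <- as.numeric(s[paste(pairDf$bat_a, pairDf$bat_b)])
    ifelse(is.na(out), 0, out)
  })
  colnames(winMin) <- paste0("w", windowsH)
  pairWindows <- cbind(pairDf, as.data.frame(winMin))

  ## -- long-term grooming: NB multi-membership ----------------------------
  ## forced-proximity trios: one bat per capture site where the design has
  ## three sites (every forced pair then crosses sites, i.e. is unfamiliar),
  ## otherwise random trios
  nTrios <- config@nBats %/% 3L
  if (config@nSites == 3L && nTrios > 0) {
    bySite <- split(bats$bat, bats$site)
    nTrios <- min(nTrios, min(lengths(bySite)))
    picks <- lapply(bySite, function(b) sample(b, nTrios))
    trioBats <- as.character(unlist(lapply(seq_len(nTrios), function(t)
      vapply(picks, `[`, "", t))))
  } else if (nTrios > 0) {
    trioBats <- sample(bats$bat, 3L * nTrios)
  } else trioBats <- character()
  trioId <- rep(seq_len(nTrios), each = 3L)
  forcedPair <- rep(FALSE, nrow(pairDf))
  if (nTrios > 0) {
    tOf <- setNames(trioId, trioBats)
    ta <- tOf[pairDf$bat_a]; tb <- tOf[pairDf$bat_b]
    forcedPair <- !is.na(ta) & !is.na(tb) & ta == tb
  }

  xRaw <- pairWindows$w4
  unf <- !pairDf$familiar
  mu_x <- mean(xRaw[unf]); sd_x <- sd(xRaw[unf])
  z <- if (sd_x > 0) (xRaw - mu_x) / sd_x else xRaw * 0

  u <- rnorm(config@nBats, 0, config@sigmaBat)
  names(u) <- bats$bat
  b0 <- -5; bFP <- 0.3; bPost <- 0.2

  grooming <- do.call(rbind, lapply(c(0L, 1L), function(post) {
    possible <- round(runif(nrow(pairDf), 300, 900))
    eta <- log(possible) + b0 +
      config@betaContact * z +
      bFP * forcedPair + bPost * post +
      config@betaTreatmentInteraction * forcedPair * post +
      u[pairDf$bat_a] + u[pairDf$bat_b]
    mu <- exp(eta)
    data.frame(bat_i = pairDf$bat_a, bat_j = pairDf$bat_b,
               groom_minutes = rnbinom(nrow(pairDf), size = config@phi,
                                       mu = mu),
               possible_minutes = possible,
               x_contact = xRaw,
               forced_proximity = as.integer(forcedPair),
               post_treatment = post,
               unfamiliar = as.integer(unf),
               mu_true = mu,
               stringsAsFactors = FALSE)
  }))
  rownames(grooming) <- NULL
  muTrue <- grooming$mu_true
  grooming$mu_true <- NULL

  truth <- list(
    encounters = encounters,
    pairWindows = pairWindows,
    windowsH = windowsH,
    batEffects = u,
    coefficients = c(intercept = b0, betaContact = config@betaContact,
                     betaForced = bFP, betaPost = bPost,
                     betaInteraction = config@betaTreatmentInteraction),
    phi = config@phi,
    mu = muTrue,
    zStats = c(mean = mu_x, sd = sd_x)
  )
  list(pings = pings, bats = bats, grooming = grooming, truth = truth)
}

#' Write a generated dataset to CSV files (plus a JSON ledger)
#'
#' @param data list returned by \code{\link{genStudy1}} or
#'   \code{\link{genStudy2}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
writeDataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in setdiff(names(data), "truth")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(data[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(data$truth, p, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(c(paths, p))
}
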
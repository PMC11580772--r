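## Ethogram parsing and dyadic aggregation for small-cage introductions.

#' Read interaction events, cage groupings or long-term tables from CSV
#'
#' Thin readers with schema validation for the standard file layouts:
#' `events.csv` (actor, receiver, behavior, onset_s, duration_s),
#' `cages.csv` (cage, bat, site, ...) and `longterm.csv`
#' (actor, receiver, response, behavior_s, possible_s).
#'
#' @param path CSV file path.
#' @return a validated data.frame.
#' @export
readEvents <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("actor", "receiver", "behavior", "onset_s", "duration_s")
  .requireColumns(ev, need, path)
  validateEvents(ev)
  ev
}

#' @rdname readEvents
#' @export
readCages <- function(path) {
  cg <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(cg, c("cage", "bat"), path)
  cg
}

#' @rdname readEvents
#' @export
readLongterm <- function(path) {
  lt <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(lt, c("actor", "receiver", "response", "behavior_s",
                        "possible_s"), path)
  lt
}

.requireColumns <- function(df, cols, where = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Validate an interaction event table
#'
#' Checks the event invariants: actor differs from receiver, durations are
#' positive, onsets non-negative, behaviours are `affiliative` or
#' `aggressive`, and no event extends beyond the scoring horizon.
#'
#' @param events event data.frame.
#' @param horizonS scoring horizon in seconds (default 6 h).
#' @return invisibly, `events`; errors name the first offending row.
#' @export
validateEvents <- function(events, horizonS = 21600) {
  bad <- function(i, why)
    stop(sprintf("invalid event at row %d: %s", i, why), call. = FALSE)
  chk <- function(cond, why) {
    i <- which(cond)
    if (length(i)) bad(i[1], why)
  }
  chk(events$actor == events$receiver, "actor equals receiver")
  chk(events$duration_s <= 0, "duration_s must be > 0")
  chk(events$onset_s < 0, "onset_s must be >= 0")
  chk(!events$behavior %in% c("affiliative", "aggressive"),
      "behavior must be 'affiliative' or 'aggressive'")
  chk(events$onset_s + events$duration_s > horizonS + 1e-9,
      sprintf("event extends beyond the %g-s scoring horizon", horizonS))
  invisible(events)
}

#' Aggregate events into directed dyad totals
#'
#' Sums event durations per ordered cagemate pair and behaviour class,
#' truncating any event at the scoring horizon. Every ordered pair of
#' cagemates appears in the output; pairs with no events get 0.
#'
#' @param events event data.frame (actor, receiver, behavior, onset_s,
#'   duration_s).
#' @param cages cage-grouping data.frame (cage, bat, ...).
#' @param horizonS scoring horizon in seconds; events with onset at or past
#'   the horizon contribute nothing, events straddling it contribute only
#'   the part before it.
#' @return data.frame with columns actor, receiver, cage, affiliative_s,
#'   aggressive_s, one row per ordered cagemate pair.
#' @export
aggregateDyadInteractions <- function(events, cages, horizonS = 21600) {
  .requireColumns(events, c("actor", "receiver", "behavior", "onset_s",
                            "duration_s"), "events")
  .requireColumns(cages, c("cage", "bat"), "cages")
  cageOf <- setNames(cages$cage, cages$bat)

  unknown <- which(!(events$actor %in% cages$bat) |
                   !(events$receiver %in% cages$bat))
  if (length(unknown))
    stop(sprintf("event at row %d involves a bat not in the cage table (%s -> %s)",
                 unknown[1], events$actor[unknown[1]],
                 events$receiver[unknown[1]]), call. = FALSE)
  cross <- which(cageOf[events$actor] != cageOf[events$receiver])
  if (length(cross))
    stop(sprintf("event at row %d is between non-cagemates (%s -> %s)",
                 cross[1], events$actor[cross[1]], events$receiver[cross[1]]),
         call. = FALSE)

  ## all ordered cagemate pairs
  out <- do.call(rbind, lapply(split(cages$bat, cages$cage), function(b) {
    g <- expand.grid(actor = b, receiver = b, stringsAsFactors = FALSE)
    g[g$actor != g$receiver, ]
  }))
  out$cage <- unname(cageOf[out$actor])
  rownames(out) <- NULL

  trunc <- pmin(events$duration_s,
                pmax(horizonS - events$onset_s, 0))
  key <- paste(events$actor, events$receiver)
  okey <- paste(out$actor, out$receiver)
  for (b in c("affiliative", "aggressive")) {
    sel <- events$behavior == b
    s <- tapply(trunc[sel], key[sel], sum)
    v <- as.numeric(s[okey])
    out[[paste0(b, "_s")]] <- ifelse(is.na(v), 0, v)
  }
  out
}

#' Exact binomial (Clopper-Pearson) incidence interval
#'
#' Computes the incidence proportion with its exact two-sided confidence
#' interval from beta quantiles, as produced by an exact binomial test.
#'
#' @param successes number of positive pairs.
#' @param trials number of pairs at risk (> 0).
#' @param level confidence level (default 0.95).
#' @return list with `proportion`, `lower`, `upper` (all on the 0-1 scale)
#'   and `percent`, a character vector of the three values formatted the way
#'   incidence is conventionally reported (whole percent at or above 10\%,
#'   one decimal below).
#' @examples
#' incidenceCI(30, 35)  # 86% [70%, 95%]
#' @export
incidenceCI <- function(successes, trials, level = 0.95) {
  if (trials <= 0) stop("trials must be > 0", call. = FALSE)
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]", call. = FALSE)
  bt <- binom.test(successes, trials, conf.level = level)
  res <- list(proportion = unname(bt$estimate),
              lower = bt$conf.int[1], upper = bt$conf.int[2])
  res$percent <- vapply(unlist(res[1:3]), formatPercent, character(1))
  res
}

#' Format a proportion as a reported percentage
#'
#' Values at or above 10\% are rounded to a whole percent, values below to
#' one decimal place (e.g. 0.857 -> "86", 0.0089 -> "0.9").
#'
#' @param p proportion in [0, 1].
#' @return character scalar.
#' @export
formatPercent <- function(p) {
  pct <- 100 * p
  if (pct >= 10) sprintf("%d", round(pct)) else sprintf("%.1f", pct)
}

#' Pair-level and directed incidence counts
#'
#' A pair counts as positive for a behaviour if either direction has at
#' least one event; a directed actor-receiver pair counts if that direction
#' has at least one event.
#'
#' @param totals directed dyad totals from
#'   \code{\link{aggregateDyadInteractions}}.
#' @param behavior `"affiliative"` or `"aggressive"`.
#' @return list with `pairPositive`, `pairTotal`, `directedPositive`,
#'   `directedTotal`.
#' @export
incidenceCounts <- function(totals, behavior = c("affiliative", "aggressive")) {
  behavior <- match.arg(behavior)
  col <- paste0(behavior, "_s")
  keyU <- ifelse(totals$actor < totals$receiver,
                 paste(totals$actor, totals$receiver),
                 paste(totals$receiver, totals$actor))
  pairPos <- tapply(totals[[col]] > 0, keyU, any)
  list(pairPositive = sum(pairPos), pairTotal = length(pairPos),
       directedPositive = sum(totals[[col]] > 0),
       directedTotal = nrow(totals))
}

#' Bootstrap confidence interval for a mean duration
#'
#' Arithmetic mean with a seeded nonparametric percentile bootstrap.
#'
#' @param durations numeric vector (nonempty).
#' @param level confidence level.
#' @param nBoot bootstrap resamples (>= 1000 recommended).
#' @param seed integer seed for the resampling RNG.
#' @return list with `mean`, `lower`, `upper`, `nBoot`.
#' @export
meanDurationCI <- function(durations, level = 0.95, nBoot = 5000, seed = 1L) {
  if (!length(durations)) stop("durations must be nonempty", call. = FALSE)
  m <- mean(durations)
  if (length(durations) == 1L || diff(range(durations)) == 0)
    return(list(mean = m, lower = m, upper = m, nBoot = as.integer(nBoot)))
  set.seed(seed)
  n <- length(durations)
  bm <- vapply(seq_len(nBoot),
               function(i) mean(durations[sample.int(n, n, replace = TRUE)]),
               numeric(1))
  a <- (1 - level) / 2
  q <- unname(quantile(bm, c(a, 1 - a)))
  list(mean = m, lower = q[1], upper = q[2], nBoot = as.integer(nBoot))
}
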
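## Study-1 inference: aggregated binomial GLM linking first-interaction
## seconds to long-term cooperation rates, with a cage-constrained
## permutation null that respects the sampling design (only cagemates could
## interact, and each introduced bat had 1-3 possible receivers).

#' Build aggregated-binomial model rows
#'
#' Joins directed first-interaction totals for one behaviour class to the
#' long-term table for one response, giving one row per directed dyad with
#' predictor seconds, long-term behaviour seconds (successes) and possible
#' seconds (trials).
#'
#' @param events,cages,longterm tables as read by \code{\link{readEvents}},
#'   \code{\link{readCages}}, \code{\link{readLongterm}}.
#' @param behavior predictor class, `"affiliative"` or `"aggressive"`.
#' @param response response class present in `longterm$response`
#'   (e.g. `"grooming"` or `"sharing"`).
#' @param horizonS scoring horizon for the predictor totals.
#' @return data.frame with actor, receiver, x_raw, successes, trials.
#' @export
buildAggBinomRows <- function(events, cages, longterm,
                              behavior = c("affiliative", "aggressive"),
                              response = "grooming", horizonS = 21600) {
  behavior <- match.arg(behavior)
  totals <- aggregateDyadInteractions(events, cages, horizonS)
  lt <- longterm[longterm$response == response, ]
  if (!nrow(lt)) stop("no long-term rows for response '", response, "'",
                      call. = FALSE)
  i <- match(paste(lt$actor, lt$receiver), paste(totals$actor, totals$receiver))
  if (anyNA(i))
    stop("long-term rows reference dyads absent from the cage table",
         call. = FALSE)
  data.frame(actor = lt$actor, receiver = lt$receiver,
             x_raw = totals[[paste0(behavior, "_s")]][i],
             successes = lt$behavior_s, trials = lt$possible_s,
             stringsAsFactors = FALSE)
}

## fast aggregated-binomial fit; returns c(intercept, slope) and flags
.fitAggBinom <- function(z, successes, trials) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, z), successes / trials, weights = trials,
            family = binomial()))
  co <- fit$coefficients
  p <- fit$fitted.values
  sep <- any(p < 1e-10 | p > 1 - 1e-10) || any(abs(co) > 20)
  list(coef = unname(co[2]), intercept = unname(co[1]),
       converged = isTRUE(fit$converged) && !sep)
}

#' Fit an aggregated binomial GLM of long-term rates on first interactions
#'
#' Maximum-likelihood logistic regression of successes out of trials on the
#' z-scored predictor (scaled and centred within the supplied data), with
#' intercept. Aggregated binomial means each row contributes
#' `successes` 1s and `trials - successes` 0s.
#'
#' @param rows data.frame from \code{\link{buildAggBinomRows}} (needs
#'   columns x_raw, successes, trials).
#' @return list with `coef` (slope on the logit scale per SD of predictor),
#'   `intercept` and `converged`. A predictor with zero variance is a
#'   degenerate design and errors; complete separation is flagged with a
#'   warning and `converged = FALSE`.
#' @export
fitAggBinomGLM <- function(rows) {
  .requireColumns(rows, c("x_raw", "successes", "trials"), "rows")
  if (nrow(rows) < 2) stop("need at least 2 rows", call. = FALSE)
  if (any(rows$trials <= 0)) stop("trials must be > 0", call. = FALSE)
  if (any(rows$successes < 0 | rows$successes > rows$trials))
    stop("successes must lie in [0, trials]", call. = FALSE)
  s <- sd(rows$x_raw)
  if (!is.finite(s) || s == 0)
    stop("degenerate design: predictor has zero variance", call. = FALSE)
  z <- (rows$x_raw - mean(rows$x_raw)) / s
  fit <- .fitAggBinom(z, rows$successes, rows$trials)
  if (!fit$converged)
    warning("GLM did not converge cleanly (possible complete separation); ",
            "slope estimate may be unreliable", call. = FALSE)
  fit
}

#' Permute event receivers within cages
#'
#' Draws, for each event, a new receiver uniformly from the actor's
#' cagemates, keeping actor, behaviour, onset and duration fixed. This is
#' the null in which each introduced bat directs its behaviour at random
#' toward the 1-3 other bats it was caged with; per-actor total seconds are
#' conserved exactly and no event ever crosses cages.
#'
#' @param events event data.frame.
#' @param cages cage-grouping data.frame.
#' @return event data.frame with permuted receivers (uses the current RNG
#'   stream; seed outside for reproducibility).
#' @export
permuteWithinCages <- function(events, cages) {
  cagemates <- split(cages$bat, cages$cage)
  cageOf <- setNames(cages$cage, cages$bat)
  out <- events
  byActor <- split(seq_len(nrow(events)), events$actor)
  for (a in names(byActor)) {
    pool <- setdiff(cagemates[[cageOf[[a]]]], a)
    idx <- byActor[[a]]
    out$receiver[idx] <- pool[sample.int(length(pool), length(idx),
                                         replace = TRUE)]
  }
  out
}

#' Cage-constrained permutation test of first-interaction effects
#'
#' Fits the observed aggregated binomial GLM of one long-term response on
#' one first-interaction behaviour class, then re-fits it on `nPerm`
#' datasets in which interactions are redirected at random within cages
#' (`permUnit = "events"`, the default) or in which dyadic predictor totals
#' are shuffled among each cage's directed pairs (`permUnit = "totals"`, a
#' sensitivity variant). The predictor is re-standardized within every
#' permuted dataset. One-tailed p-values use the add-one Monte-Carlo
#' convention \eqn{p = (1 + b) / (1 + m)} with b the number of null slopes
#' at least as extreme as the observed one.
#'
#' @inheritParams buildAggBinomRows
#' @param nPerm number of permutations (the original analysis used 5000).
#' @param tail `"upper"` (affiliative predictors: expect positive slopes) or
#'   `"lower"` (aggressive predictors). Defaults by behaviour class.
#' @param permUnit exchangeable unit, `"events"` or `"totals"`.
#' @param seed integer RNG seed.
#' @return a \code{\link{PermutationResult-class}} object. Non-converged
#'   permuted fits are dropped from the null (with the count recorded),
#'   so separation artifacts never contaminate the reference distribution.
#' @export
permutationTest <- function(events, cages, longterm,
                            behavior = c("affiliative", "aggressive"),
                            response = "grooming",
                            nPerm = 5000L,
                            tail = NULL,
                            permUnit = c("events", "totals"),
                            horizonS = 21600,
                            seed = 1L) {
  behavior <- match.arg(behavior)
  permUnit <- match.arg(permUnit)
  if (nPerm < 1) stop("nPerm must be >= 1", call. = FALSE)
  if (is.null(tail))
    tail <- if (behavior == "affiliative") "upper" else "lower"
  tail <- match.arg(tail, c("upper", "lower"))

  rows <- buildAggBinomRows(events, cages, longterm, behavior, response,
                            horizonS)
  obs <- fitAggBinomGLM(rows)
  if (!obs$converged)
    warning("observed fit flagged as non-converged", call. = FALSE)

  ltKey <- paste(rows$actor, rows$receiver)
  nLT <- nrow(rows)
  cageOf <- setNames(cages$cage, cages$bat)
  succ <- rows$successes; trials <- rows$trials

  fitX <- function(xRaw) {
    s <- sd(xRaw)
    if (!is.finite(s) || s == 0) return(NULL)
    .fitAggBinom((xRaw - mean(xRaw)) / s, succ, trials)
  }

  set.seed(seed)
  nullCoefs <- numeric(0)
  nDropped <- 0L

  if (permUnit == "events") {
    ## precompute: behaviour events with truncated durations, actor pools
    ev <- events[events$behavior == behavior, ]
    dur <- pmin(ev$duration_s, pmax(horizonS - ev$onset_s, 0))
    keep <- dur > 0
    ev <- ev[keep, ]; dur <- dur[keep]
    cagemates <- split(cages$bat, cages$cage)
    byActor <- split(seq_len(nrow(ev)), ev$actor)
    pools <- lapply(names(byActor),
                    function(a) setdiff(cagemates[[cageOf[[a]]]], a))
    names(pools) <- names(byActor)

    for (b in seq_len(nPerm)) {
      rec <- character(nrow(ev))
      for (a in names(byActor)) {
        idx <- byActor[[a]]
        pool <- pools[[a]]
        rec[idx] <- pool[sample.int(length(pool), length(idx),
                                    replace = TRUE)]
      }
      x <- numeric(nLT)
      i <- match(paste(ev$actor, rec), ltKey)
      ok <- !is.na(i)
      if (any(ok)) {
        s <- rowsum(dur[ok], i[ok])
        x[as.integer(rownames(s))] <- s[, 1]
      }
      f <- fitX(x)
      if (is.null(f) || !f$converged) nDropped <- nDropped + 1L
      else nullCoefs <- c(nullCoefs, f$coef)
    }
  } else {
    cageRow <- unname(cageOf[rows$actor])
    byCage <- split(seq_len(nLT), cageRow)
    for (b in seq_len(nPerm)) {
      x <- rows$x_raw
      for (idx in byCage) x[idx] <- x[idx][sample.int(length(idx))]
      f <- fitX(x)
      if (is.null(f) || !f$converged) nDropped <- nDropped + 1L
      else nullCoefs <- c(nullCoefs, f$coef)
    }
  }

  if (!length(nullCoefs))
    stop("all permuted fits were degenerate; no null distribution",
         call. = FALSE)

  b <- if (tail == "upper") sum(nullCoefs >= obs$coef)
       else sum(nullCoefs <= obs$coef)
  p <- (1 + b) / (1 + length(nullCoefs))
  q <- unname(quantile(nullCoefs, c(0.025, 0.975)))

  new("PermutationResult",
      observedCoef = obs$coef, nullCoefs = nullCoefs,
      pOneTailed = p, tail = tail, q025 = q[1], q975 = q[2],
      nPerm = as.integer(nPerm), nDropped = nDropped)
}
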
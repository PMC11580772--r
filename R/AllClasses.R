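#' @import methods
#' @importFrom stats quantile median sd var rnorm rpois runif rbinom rnbinom
#'   rlnorm rexp glm glm.fit binomial binom.test qbeta plogis setNames
#'   coef model.matrix aggregate complete.cases
#' @importFrom utils read.csv write.csv head
NULL

## -------------------------------------------------------------------------
## Configuration classes for the synthetic-data generators
## -------------------------------------------------------------------------

#' Configuration for a Study-1-style introduction experiment
#'
#' Describes an experiment in which unfamiliar female bats are introduced in
#' small cages of 2 or 4 animals, their first hours of affiliative and
#' aggressive interactions are scored from video, and long-term cooperative
#' behaviour (grooming, food sharing) is later observed as aggregated-binomial
#' seconds-with / seconds-possible counts.
#'
#' @slot nCages number of introduction cages.
#' @slot cageSizes integer vector (length \code{nCages}) of cage sizes, each
#'   2 or 4.
#' @slot eventRateAffiliative,eventRateAggressive expected events per hour per
#'   directed pair during the scored introduction window.
#' @slot affilDurationMeanS mean affiliative event duration in seconds.
#' @slot horizonS scored introduction window in seconds (default 6 h).
#' @slot obsDays long-term observation span in days (scales possible seconds).
#' @slot baselineLogit intercept of the long-term behaviour logit.
#' @slot effectAffiliative planted slope of standardized first-interaction
#'   seconds on the long-term logit.
#' @slot dyadNoiseSD SD of dyad-level normal noise on the logit scale.
#' @slot seed integer RNG seed; a fixed seed makes output bit-identical.
#' @export
setClass("Study1Config", representation(
  nCages = "integer",
  cageSizes = "integer",
  eventRateAffiliative = "numeric",
  eventRateAggressive = "numeric",
  affilDurationMeanS = "numeric",
  horizonS = "numeric",
  obsDays = "numeric",
  baselineLogit = "numeric",
  effectAffiliative = "numeric",
  dyadNoiseSD = "numeric",
  seed = "integer"
))

setValidity("Study1Config", function(object) {
  msg <- character()
  if (length(object@cageSizes) != object@nCages)
    msg <- c(msg, "cageSizes must have length nCages")
  if (!all(object@cageSizes %in% c(2L, 4L)))
    msg <- c(msg, "cage sizes must be 2 or 4")
  rates <- c(object@eventRateAffiliative, object@eventRateAggressive)
  if (any(rates < 0)) msg <- c(msg, "event rates must be >= 0")
  if (object@horizonS <= 0) msg <- c(msg, "horizonS must be positive")
  if (object@dyadNoiseSD < 0) msg <- c(msg, "dyadNoiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Configuration for a Study-2-style proximity-sensor experiment
#'
#' Describes an experiment in which sensor-tagged bats from several capture
#' sites are released together in a flight cage; pair-wise sensor pings are
#' recorded for 24 h, and long-term dyadic allogrooming is observed as
#' overdispersed counts with an exposure offset, under a forced-proximity
#' treatment crossed with a pre/post period.
#'
#' @slot nBats number of tagged bats.
#' @slot nSites number of capture sites; familiar pairs share a site.
#' @slot pingIntervalS sensor ping interval in seconds.
#' @slot encounterRateFamiliar,encounterRateUnfamiliar encounters per hour per
#'   pair by familiarity class.
#' @slot encounterDurationMeanS mean encounter duration in seconds.
#' @slot rssiNoiseSD SD of per-ping signal-strength noise around the
#'   encounter level (familiarity-independent).
#' @slot betaContact planted slope of standardized first-contact minutes on
#'   the log grooming rate (unfamiliar dyads).
#' @slot betaTreatmentInteraction planted forced-proximity x post-period
#'   interaction on the log grooming rate.
#' @slot phi negative-binomial dispersion (size) parameter.
#' @slot sigmaBat SD of per-bat random intercepts.
#' @slot seed integer RNG seed.
#' @export
setClass("Study2Config", representation(
  nBats = "integer",
  nSites = "integer",
  pingIntervalS = "numeric",
  encounterRateFamiliar = "numeric",
  encounterRateUnfamiliar = "numeric",
  encounterDurationMeanS = "numeric",
  rssiNoiseSD = "numeric",
  betaContact = "numeric",
  betaTreatmentInteraction = "numeric",
  phi = "numeric",
  sigmaBat = "numeric",
  seed = "integer"
))

setValidity("Study2Config", function(object) {
  msg <- character()
  if (object@pingIntervalS <= 0) msg <- c(msg, "pingIntervalS must be > 0")
  if (object@encounterRateFamiliar < 0 || object@encounterRateUnfamiliar < 0)
    msg <- c(msg, "encounter rates must be >= 0")
  if (object@rssiNoiseSD < 0) msg <- c(msg, "rssiNoiseSD must be >= 0")
  if (object@phi <= 0) msg <- c(msg, "phi must be > 0")
  if (object@sigmaBat < 0) msg <- c(msg, "sigmaBat must be >= 0")
  if (object@nBats < object@nSites)
    msg <- c(msg, "need at least one bat per site")
  if (length(msg)) msg else TRUE
})

## -------------------------------------------------------------------------
## Result classes
## -------------------------------------------------------------------------

#' Result of a cage-constrained permutation test
#'
#' Holds the observed aggregated-binomial slope (logit scale, standardized
#' predictor), the null distribution of slopes obtained by permuting event
#' receivers within cages, the one-tailed Monte-Carlo p-value with add-one
#' correction, and the 2.5\%/97.5\% null quantiles.
#'
#' @slot observedCoef observed slope.
#' @slot nullCoefs numeric vector of null slopes (non-converged fits dropped).
#' @slot pOneTailed one-tailed p-value, \eqn{(1 + b) / (1 + m)}.
#' @slot tail \code{"upper"} or \code{"lower"}.
#' @slot q025,q975 null-distribution quantiles.
#' @slot nPerm permutations requested.
#' @slot nDropped permuted fits dropped for non-convergence.
#' @export
setClass("PermutationResult", representation(
  observedCoef = "numeric",
  nullCoefs = "numeric",
  pOneTailed = "numeric",
  tail = "character",
  q025 = "numeric",
  q975 = "numeric",
  nPerm = "integer",
  nDropped = "integer"
))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@pOneTailed <= 0 || object@pOneTailed > 1)
    msg <- c(msg, "p must lie in (0, 1]")
  if (object@q025 > object@q975) msg <- c(msg, "q025 must be <= q975")
  if (length(object@nullCoefs) + object@nDropped != object@nPerm)
    msg <- c(msg, "null coefficients + dropped fits must equal nPerm")
  if (length(msg)) msg else TRUE
})

#' A weighted undirected contact network for one cumulative window
#'
#' @slot nodes data.frame with columns \code{bat} and \code{site}.
#' @slot edges data.frame with columns \code{bat_a}, \code{bat_b},
#'   \code{minutes} (>= 0) and \code{familiar}.
#' @slot windowH cumulative window length in hours.
#' @export
setClass("ContactNetwork", representation(
  nodes = "data.frame",
  edges = "data.frame",
  windowH = "numeric"
))

setValidity("ContactNetwork", function(object) {
  msg <- character()
  if (!all(c("bat", "site") %in% names(object@nodes)))
    msg <- c(msg, "nodes needs columns bat, site")
  if (!all(c("bat_a", "bat_b", "minutes") %in% names(object@edges)))
    msg <- c(msg, "edges needs columns bat_a, bat_b, minutes")
  if (nrow(object@edges) && any(object@edges$minutes < 0))
    msg <- c(msg, "edge weights must be >= 0")
  bad <- setdiff(c(object@edges$bat_a, object@edges$bat_b), object@nodes$bat)
  if (length(bad)) msg <- c(msg, paste("edge endpoints not in nodes:",
                                       paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Posterior summary of a Bayesian NB multi-membership model
#'
#' Stores the pooled MCMC draws for the fixed effects, the random-intercept
#' SD, the dispersion and the per-bat effects, together with convergence
#' diagnostics (potential scale reduction factors and effective sample sizes)
#' and everything needed to reconstruct per-draw linear predictors (design
#' matrix, offset, membership indices).
#'
#' @slot draws numeric matrix, one column per monitored parameter.
#' @slot diagnostics data.frame with columns \code{parameter}, \code{rhat},
#'   \code{ess}.
#' @slot terms character vector of fixed-effect term names (after intercept).
#' @slot X design matrix used in the fit (including intercept).
#' @slot offset numeric vector of log-exposure offsets.
#' @slot memberI,memberJ integer membership indices into the bat effects.
#' @slot bats character vector of bat ids in membership order.
#' @slot response integer response vector.
#' @export
setClass("PosteriorSummary", representation(
  draws = "matrix",
  diagnostics = "data.frame",
  terms = "character",
  X = "matrix",
  offset = "numeric",
  memberI = "integer",
  memberJ = "integer",
  bats = "character",
  response = "integer"
))

setValidity("PosteriorSummary", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@offset))
    msg <- c(msg, "X and offset sizes disagree")
  if (length(object@memberI) != nrow(object@X) ||
      length(object@memberJ) != nrow(object@X))
    msg <- c(msg, "membership indices must match the number of rows")
  if (length(msg)) msg else TRUE
})

## -------------------------------------------------------------------------
## show methods
## -------------------------------------------------------------------------

setMethod("show", "PermutationResult", function(object) {
  cat("Cage-constrained permutation test\n")
  cat(sprintf("  observed slope (logit, standardized x): %.4f\n",
              object@observedCoef))
  cat(sprintf("  null 95%% quantiles: [%.4f, %.4f]\n",
              object@q025, object@q975))
  cat(sprintf("  one-tailed p (%s tail): %.4g  (n_perm = %d, dropped = %d)\n",
              object@tail, object@pOneTailed, object@nPerm, object@nDropped))
})

setMethod("show", "ContactNetwork", function(object) {
  cat(sprintf("ContactNetwork: %d bats, %d positive edges, window %g h\n",
              nrow(object@nodes), sum(object@edges$minutes > 0),
              object@windowH))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf(
    "NB multi-membership posterior: %d draws, %d dyad-rows, %d bats\n",
    nrow(object@draws), nrow(object@X), length(object@bats)))
  cat("  fixed effects:", paste(colnames(object@X), collapse = ", "), "\n")
  rh <- object@diagnostics$rhat
  cat(sprintf("  max Rhat %.4f, min ESS %.0f\n",
              max(rh, na.rm = TRUE),
              min(object@diagnostics$ess, na.rm = TRUE)))
})

## -------------------------------------------------------------------------
## Accessors
## -------------------------------------------------------------------------

#' @describeIn PermutationResult-class observed slope
#' @param object a \code{PermutationResult}
#' @export
observedCoef <- function(object) object@observedCoef

#' @describeIn PermutationResult-class vector of null slopes
#' @export
nullCoefs <- function(object) object@nullCoefs

#' @describeIn PermutationResult-class one-tailed Monte-Carlo p-value
#' @export
pValue <- function(object) object@pOneTailed

#' Extract posterior draws
#'
#' @param object a \code{\link{PosteriorSummary-class}} object.
#' @param pars optional character vector of parameter names.
#' @return numeric matrix of draws (rows = draws).
#' @export
posteriorDraws <- function(object, pars = NULL) {
  stopifnot(is(object, "PosteriorSummary"))
  if (is.null(pars)) return(object@draws)
  missing <- setdiff(pars, colnames(object@draws))
  if (length(missing))
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  object@draws[, pars, drop = FALSE]
}

#' Convergence diagnostics of a fitted model
#'
#' @param object a \code{\link{PosteriorSummary-class}} object.
#' @return data.frame with columns \code{parameter}, \code{rhat}, \code{ess}.
#' @export
convergenceDiagnostics <- function(object) object@diagnostics

#' Fixed-effect terms of a fitted model (excluding the intercept)
#' @param object a \code{\link{PosteriorSummary-class}} object.
#' @export
modelTerms <- function(object) object@terms
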
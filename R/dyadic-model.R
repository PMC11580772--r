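## Bayesian negative-binomial multi-membership regression for undirected
## dyadic count data. Each dyad loads on the random intercepts of both
## member bats; the log of the observation exposure enters as an offset so
## fixed effects act on rates. Sampling is Gibbs/slice MCMC via JAGS.

## Hierarchically centred parameterization: the per-bat effects are drawn
## around half the intercept (each dyad loads two of them), which decouples
## the intercept from the random-effect mean and mixes far better under
## Gibbs sampling than the non-centred form. Reported quantities are the
## identified ones: intercept = 2h and deviations u[b] = v[b] - h.
.nbmmModelString <- function(hasSlopes) {
  slope <- if (hasSlopes) "inprod(Xs[k, ], bs) + " else ""
  bsPrior <- if (hasSlopes)
    "  for (j in 1:P) { bs[j] ~ dnorm(0, pow(priorSlopeSD, -2)) }\n" else ""
  paste0("
model {
  for (k in 1:N) {
    y[k] ~ dnegbin(p[k], phi)
    p[k] <- phi / (phi + mu[k])
    log(mu[k]) <- off[k] + ", slope, "v[bi[k]] + v[bj[k]]
  }
  for (b in 1:B) {
    v[b] ~ dnorm(h, tauU)
    u[b] <- v[b] - h
  }
  h ~ dnorm(0, pow(priorInterceptSD / 2, -2))
  intercept <- 2 * h
", bsPrior, "  sigmaBat ~ dt(0, pow(priorSigmaScale, -2), 3) T(0, )
  tauU <- pow(sigmaBat, -2)
  invSqrtPhi ~ dt(0, 1, 3) T(0, )
  phi <- pow(invSqrtPhi, -2)
}
")
}

#' Standardize first-contact minutes over unfamiliar dyads
#'
#' Centres and scales `x_contact` using the mean and SD over unfamiliar
#' dyads only (the rows the grooming models are fitted to), applying the
#' same transform to every row. With no `unfamiliar` column, all rows are
#' used.
#'
#' @param data dyad observation data.frame with an `x_contact` column.
#' @return `data` with `x_contact` replaced by its z-score; the statistics
#'   used are attached as attribute `zStats`.
#' @export
standardizeContact <- function(data) {
  .requireColumns(data, "x_contact", "data")
  ref <- if ("unfamiliar" %in% names(data)) data$unfamiliar == 1
         else rep(TRUE, nrow(data))
  m <- mean(data$x_contact[ref]); s <- sd(data$x_contact[ref])
  if (!is.finite(s) || s == 0)
    stop("x_contact has zero variance over the reference rows",
         call. = FALSE)
  data$x_contact <- (data$x_contact - m) / s
  attr(data, "zStats") <- c(mean = m, sd = s)
  data
}

.buildDesign <- function(data, terms) {
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "intercept"))
  for (tm in terms) {
    if (grepl(":", tm, fixed = TRUE)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      .requireColumns(data, parts, "data")
      col <- Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
    } else {
      .requireColumns(data, tm, "data")
      col <- as.numeric(data[[tm]])
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- tm
  }
  X
}

#' Fit a Bayesian NB multi-membership model to dyadic counts
#'
#' Models the count response of each undirected dyad as negative binomial
#' with \eqn{\log \mu = \log(\mathrm{exposure}) + X\beta + u_i + u_j},
#' where \eqn{u} are per-bat random intercepts shared across all dyads a
#' bat belongs to, and \eqn{\phi} is the NB dispersion. Priors are weakly
#' informative: Normal(0, `priorSlopeSD`) on standardized fixed effects
#' (wider on the intercept), half-Student-t(3) on the random-effect SD and
#' on \eqn{1/\sqrt{\phi}}.
#'
#' @param data data.frame with columns bat_i, bat_j, the response, the
#'   exposure, and every predictor named in `terms` (interactions written
#'   `"a:b"`).
#' @param terms character vector of fixed-effect terms after the intercept.
#' @param response,exposure column names of the count response and the
#'   positive exposure.
#' @param standardize z-score `x_contact` (over unfamiliar dyads) before
#'   fitting; see \code{\link{standardizeContact}}.
#' @param nChains,nAdapt,nBurn,nIter,thin MCMC settings (total retained
#'   draws = nChains * nIter / thin).
#' @param priorSlopeSD,priorInterceptSD,priorSigmaScale prior scales.
#' @param rhatMax convergence gate: the fit fails loudly when any monitored
#'   parameter's potential scale reduction factor exceeds this.
#' @param seed integer seed (chains get seed + 1, seed + 2, ...).
#' @return a \code{\link{PosteriorSummary-class}} object.
#' @export
fitNBMultiMembership <- function(data,
                                 terms = c("x_contact", "forced_proximity",
                                           "post_treatment",
                                           "forced_proximity:post_treatment"),
                                 response = "groom_minutes",
                                 exposure = "possible_minutes",
                                 standardize = "x_contact" %in% terms,
                                 nChains = 3L, nAdapt = 500L, nBurn = 500L,
                                 nIter = 1000L, thin = 1L,
                                 priorSlopeSD = 2.5, priorInterceptSD = 5,
                                 priorSigmaScale = 2.5,
                                 rhatMax = 1.05, seed = 1L) {
  .requireColumns(data, c("bat_i", "bat_j", response, exposure), "data")
  if (nrow(data) < 10) stop("need at least 10 dyad rows", call. = FALSE)
  if (any(data[[exposure]] <= 0))
    stop("non-positive exposure in column '", exposure, "'", call. = FALSE)
  y <- data[[response]]
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative counts", call. = FALSE)
  if (any(data$bat_i == data$bat_j))
    stop("bat_i must differ from bat_j", call. = FALSE)

  if (standardize) data <- standardizeContact(data)
  X <- .buildDesign(data, terms)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: drop collinear terms", call. = FALSE)

  bats <- sort(unique(c(data$bat_i, data$bat_j)))
  bi <- match(data$bat_i, bats)
  bj <- match(data$bat_j, bats)

  hasSlopes <- length(terms) > 0L
  jagsData <- list(y = as.integer(round(y)), N = nrow(data),
                   off = log(data[[exposure]]),
                   bi = bi, bj = bj, B = length(bats),
                   priorInterceptSD = priorInterceptSD,
                   priorSigmaScale = priorSigmaScale)
  if (hasSlopes) {
    jagsData$Xs <- X[, -1, drop = FALSE]
    jagsData$P <- length(terms)
    jagsData$priorSlopeSD <- priorSlopeSD
  }
  inits <- lapply(seq_len(nChains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch))

  monitors <- c("intercept", if (hasSlopes) "bs", "sigmaBat", "phi", "u")
  jm <- rjags::jags.model(textConnection(.nbmmModelString(hasSlopes)),
                          data = jagsData,
                          inits = inits, n.chains = nChains,
                          n.adapt = nAdapt, quiet = TRUE)
  if (nBurn > 0) update(jm, nBurn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = nIter, thin = thin,
                              progress.bar = "none")

  ## rename bs[j] -> term names, u[b] -> u[batid]
  rename <- function(nms) {
    if (length(terms) == 1L) nms <- sub("^bs$", terms[1], nms)
    for (j in seq_along(terms))
      nms <- sub(sprintf("^bs\\[%d\\]$", j), terms[j], nms)
    for (b in seq_along(bats))
      nms <- sub(sprintf("^u\\[%d\\]$", b), paste0("u[", bats[b], "]"), nms)
    nms
  }
  samp <- lapply(samp, function(ch) {
    colnames(ch) <- rename(colnames(ch)); ch
  })
  samp <- coda::as.mcmc.list(lapply(samp, coda::as.mcmc))

  pars <- colnames(samp[[1]])
  rhat <- rep(NA_real_, length(pars))
  if (nChains >= 2) {
    gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error"))
      rhat <- gd$psrf[match(pars, rownames(gd$psrf)), 1]
  }
  ess <- coda::effectiveSize(samp)[pars]
  diagnostics <- data.frame(parameter = pars, rhat = unname(rhat),
                            ess = unname(ess), stringsAsFactors = FALSE)
  bad <- diagnostics$parameter[!is.na(diagnostics$rhat) &
                               diagnostics$rhat > rhatMax]
  if (length(bad))
    stop("MCMC did not converge: Rhat > ", rhatMax, " for ",
         paste(bad, collapse = ", "),
         "; increase nIter/nBurn or check the model", call. = FALSE)

  draws <- do.call(rbind, lapply(samp, as.matrix))
  new("PosteriorSummary",
      draws = draws, diagnostics = diagnostics, terms = terms,
      X = X, offset = log(data[[exposure]]),
      memberI = as.integer(bi), memberJ = as.integer(bj),
      bats = as.character(bats), response = as.integer(round(y)))
}

#' Percent change per unit of a predictor
#'
#' Transforms log-rate coefficients draw-wise to percent change,
#' \eqn{100(e^\beta - 1)}; for a standardized predictor this is the percent
#' change in the response rate per one SD.
#'
#' @param betaDraws numeric vector of posterior draws (or a single value).
#' @param level credible level for the interval.
#' @return list with `draws`, `median`, `lower`, `upper` (percent scale).
#' @examples
#' percentChange(log(1.32))$median  # 32
#' @export
percentChange <- function(betaDraws, level = 0.95) {
  if (!length(betaDraws)) stop("no draws supplied", call. = FALSE)
  pc <- 100 * (exp(betaDraws) - 1)
  a <- (1 - level) / 2
  q <- unname(quantile(pc, c(a, 1 - a)))
  list(draws = pc, median = median(pc), lower = q[1], upper = q[2])
}

## per-draw expected values on the response scale, D x N
.muDraws <- function(fit) {
  dr <- fit@draws
  beta <- dr[, colnames(fit@X), drop = FALSE]
  U <- dr[, paste0("u[", fit@bats, "]"), drop = FALSE]
  eta <- beta %*% t(fit@X) +
    U[, fit@memberI, drop = FALSE] + U[, fit@memberJ, drop = FALSE] +
    matrix(fit@offset, nrow(dr), length(fit@offset), byrow = TRUE)
  exp(eta)
}

#' Draw-wise Bayesian R-squared from expected-value and dispersion draws
#'
#' For each posterior draw d, \eqn{R^2_d = \mathrm{Var}_k(\mu_{dk}) /
#' (\mathrm{Var}_k(\mu_{dk}) + \overline{\mu_{dk} + \mu_{dk}^2/\phi_d})}:
#' the variance of the fitted means across observations against the mean
#' NB residual variance. Draws with constant fitted values have
#' \eqn{R^2 = 0} by convention.
#'
#' @param muDraws numeric matrix of expected values, draws x observations.
#' @param phiDraws numeric vector of dispersion draws (length = rows of
#'   `muDraws`), or a scalar.
#' @return numeric vector of per-draw values in [0, 1].
#' @export
bayesR2Draws <- function(muDraws, phiDraws) {
  muDraws <- as.matrix(muDraws)
  phiDraws <- rep_len(phiDraws, nrow(muDraws))
  vfit <- apply(muDraws, 1, var)
  vres <- rowMeans(muDraws + muDraws^2 / phiDraws)
  r2 <- ifelse(vfit <= 0, 0, vfit / (vfit + vres))
  pmin(pmax(r2, 0), 1)
}

#' Bayesian R-squared of a fitted NB multi-membership model
#'
#' @param fit a \code{\link{PosteriorSummary-class}} object.
#' @param level credible level.
#' @return list with per-draw `draws`, `median`, `lower`, `upper`.
#' @seealso \code{\link{bayesR2Draws}} for the draw-wise definition.
#' @export
bayesR2 <- function(fit, level = 0.95) {
  stopifnot(is(fit, "PosteriorSummary"))
  r2 <- bayesR2Draws(.muDraws(fit), fit@draws[, "phi"])
  a <- (1 - level) / 2
  q <- unname(quantile(r2, c(a, 1 - a)))
  list(draws = r2, median = median(r2), lower = q[1], upper = q[2])
}

#' Variance share attributed to one dropped term
#'
#' The draw-wise difference between the Bayesian R-squared of the full
#' model and of a reduced model missing exactly one fixed-effect term; the
#' summary is the posterior proportion of variance attributed to that term.
#' Differences can be negative and are reported as-is.
#'
#' @param full,reduced \code{\link{PosteriorSummary-class}} fits to the same
#'   data whose term sets differ by exactly one term.
#' @param level credible level.
#' @return list with `term` (the dropped term), `draws`, `median`,
#'   `lower`, `upper`.
#' @export
r2Partition <- function(full, reduced, level = 0.95) {
  stopifnot(is(full, "PosteriorSummary"), is(reduced, "PosteriorSummary"))
  dropped <- setdiff(full@terms, reduced@terms)
  extra <- setdiff(reduced@terms, full@terms)
  if (length(dropped) != 1L || length(extra) != 0L)
    stop("reduced spec must equal the full spec minus exactly one term",
         call. = FALSE)
  if (nrow(full@X) != nrow(reduced@X))
    stop("full and reduced fits use different data", call. = FALSE)
  r2f <- bayesR2(full)$draws
  r2r <- bayesR2(reduced)$draws
  n <- min(length(r2f), length(r2r))
  d <- r2f[seq_len(n)] - r2r[seq_len(n)]
  a <- (1 - level) / 2
  q <- unname(quantile(d, c(a, 1 - a)))
  list(term = dropped, draws = d, median = median(d),
       lower = q[1], upper = q[2])
}

#' NB multi-membership model of contact minutes on unfamiliarity
#'
#' Fits, per cumulative window, a negative-binomial multi-membership model
#' of each pair's contact minutes (rounded to whole minutes) with
#' unfamiliarity as the sole fixed effect and the window length as
#' exposure; a negative coefficient means unfamiliar pairs spend less time
#' in contact than familiar pairs.
#'
#' @param durations output of \code{\link{firstContactDurations}}.
#' @param windowsH windows (hours) to fit; must be columns of `durations`.
#' @param ... MCMC settings passed to \code{\link{fitNBMultiMembership}}.
#' @return named list of \code{\link{PosteriorSummary-class}} objects, one
#'   per window.
#' @export
familiarityModel <- function(durations, windowsH = c(4, 8, 12, 16, 20, 24),
                             ...) {
  out <- list()
  for (w in windowsH) {
    col <- paste0("w", w)
    if (!col %in% names(durations))
      stop("window ", w, " h not present in durations", call. = FALSE)
    d <- data.frame(bat_i = durations$bat_a, bat_j = durations$bat_b,
                    contact_minutes = as.integer(round(durations[[col]])),
                    possible_minutes = w * 60,
                    unfamiliar = as.integer(!durations$familiar),
                    stringsAsFactors = FALSE)
    out[[paste0("w", w)]] <- fitNBMultiMembership(
      d, terms = "unfamiliar", response = "contact_minutes",
      exposure = "possible_minutes", standardize = FALSE, ...)
  }
  out
}

#' Replicate the first-contact grooming model from deposited data
#'
#' Runs the full Study-2 pipeline (encounter segmentation, contact calling
#' at the given RSSI quantile, cumulative first-contact minutes, NB
#' multi-membership grooming model for unfamiliar pairs) from a directory
#' containing `pings.csv`, `bats.csv` and `grooming.csv` in the package's
#' standard schema, e.g. exported from the study's public data deposit.
#'
#' @param dir directory with the three CSV files.
#' @param windowH first-contact window (hours) used as the predictor.
#' @param quantile RSSI contact quantile (0.95 = contacts, 0.99 = close
#'   contacts).
#' @param ... MCMC settings passed to \code{\link{fitNBMultiMembership}}.
#' @return list with the fitted model (`fit`), `percentChangeContact` and
#'   `percentChangeInteraction` summaries.
#' @export
replicateStudy2 <- function(dir, windowH = 4, quantile = 0.95, ...) {
  for (f in c("pings.csv", "bats.csv", "grooming.csv"))
    if (!file.exists(file.path(dir, f)))
      stop("deposit file not found: ", file.path(dir, f), call. = FALSE)
  pings <- readPings(file.path(dir, "pings.csv"))
  bats <- readBats(file.path(dir, "bats.csv"))
  grooming <- read.csv(file.path(dir, "grooming.csv"),
                       stringsAsFactors = FALSE)
  enc <- segmentEncounters(pings)
  contacts <- callContacts(enc, quantile)
  dur <- firstContactDurations(contacts, bats)
  key <- .pairKey(grooming$bat_i, grooming$bat_j)
  i <- match(key, paste(dur$bat_a, dur$bat_b))
  grooming$x_contact <- dur[[paste0("w", windowH)]][i]
  fit <- fitNBMultiMembership(grooming[grooming$unfamiliar == 1, ], ...)
  list(fit = fit,
       percentChangeContact =
         percentChange(posteriorDraws(fit, "x_contact")[, 1]),
       percentChangeInteraction =
         percentChange(
           posteriorDraws(fit, "forced_proximity:post_treatment")[, 1]))
}
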
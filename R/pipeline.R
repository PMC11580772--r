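## End-to-end orchestration: generate -> Study-1 inference -> Study-2
## pipeline -> report bundle, with explicit seeds and a deterministic
## manifest. The run configuration is a plain list (or a YAML file with the
## same fields); every random stage consumes a seed derived from
## config$seed, recorded in the manifest.

#' Default pipeline configuration
#'
#' Reduced-scale settings suitable for smoke runs and tests; the original
#' analysis scale (5000 permutations, six long chains) is obtained with
#' `paperScale = TRUE`.
#'
#' @param seed master integer seed.
#' @param outDir output directory.
#' @param paperScale use analysis-scale permutations and MCMC.
#' @return a named list understood by \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(seed = 1L, outDir = tempfile("bondtrace_run_"),
                           paperScale = FALSE) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    nPerm = if (paperScale) 5000L else 500L,
    quantile = 0.95,
    windows = c(4, 8, 12, 16, 20, 24),
    mcmc = if (paperScale)
      list(nChains = 6L, nAdapt = 1000L, nBurn = 1000L, nIter = 4000L)
    else list(nChains = 2L, nAdapt = 500L, nBurn = 500L, nIter = 1000L),
    study1 = list(),   # overrides for study1Config()
    study2 = list()    # overrides for study2Config()
  )
}

.readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(pipelineConfig(), user)
  }
  stopifnot(is.list(config))
  utils::modifyList(pipelineConfig(), config)
}

#' Run the full synthetic pipeline and write a report bundle
#'
#' Generates Study-1-style and Study-2-style datasets, writes them as CSV,
#' runs the four cage-constrained permutation tests (affiliative/aggressive
#' by grooming/sharing), the contact pipeline with per-window familiarity
#' contrasts and network metrics, and the NB multi-membership grooming model
#' with percent-change and R-squared partition summaries. All outputs plus a
#' manifest (file hashes, seeds, package version) land in `config$outDir`.
#'
#' @param config a list from \code{\link{pipelineConfig}} (possibly with
#'   overridden entries) or the path to a YAML file with the same fields.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  config <- .readRunConfig(config)
  allowed <- c(4, 8, 12, 16, 20, 24)
  if (!all(config$windows %in% allowed))
    stop("unknown window value(s): ",
         paste(setdiff(config$windows, allowed), collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ## -- generate ------------------------------------------------------------
  cfg1 <- do.call(study1Config, c(config$study1, list(seed = seed)))
  cfg2 <- do.call(study2Config, c(config$study2, list(seed = seed + 1L)))
  d1 <- genStudy1(cfg1)
  d2 <- genStudy2(cfg2)
  dir1 <- file.path(config$outDir, "study1")
  dir2 <- file.path(config$outDir, "study2")
  writeDataset(d1, dir1)
  writeDataset(d2, dir2)
  message("generated datasets under ", config$outDir)

  ## -- study 1 -------------------------------------------------------------
  totals <- aggregateDyadInteractions(d1$events, d1$cages)
  write.csv(totals, file.path(dir1, "dyad_totals.csv"), row.names = FALSE)
  inc <- lapply(c("affiliative", "aggressive"), function(b) {
    cnt <- incidenceCounts(totals, b)
    ci <- incidenceCI(cnt$pairPositive, cnt$pairTotal)
    c(list(behavior = b), cnt, ci[c("proportion", "lower", "upper")])
  })
  permTests <- list()
  k <- 0L
  for (b in c("affiliative", "aggressive"))
    for (r in c("grooming", "sharing")) {
      k <- k + 1L
      pt <- permutationTest(d1$events, d1$cages, d1$longterm, behavior = b,
                            response = r, nPerm = config$nPerm,
                            seed = seed + 10L + k)
      permTests[[paste(b, r, sep = "_")]] <- list(
        observed = observedCoef(pt), p = pValue(pt),
        q025 = pt@q025, q975 = pt@q975, nDropped = pt@nDropped)
      message(sprintf("permutation test %s -> %s: p = %.3f", b, r,
                      pValue(pt)))
    }

  ## -- study 2 -------------------------------------------------------------
  enc <- segmentEncounters(d2$pings, pingIntervalS = cfg2@pingIntervalS)
  contacts <- callContacts(enc, config$quantile)
  dur <- firstContactDurations(contacts, d2$bats, config$windows)
  write.csv(dur, file.path(dir2, "first_contact_minutes.csv"),
            row.names = FALSE)
  metrics <- lapply(config$windows, function(w) {
    m <- networkMetrics(contactNetwork(dur, d2$bats, w))
    c(window_h = w, m)
  })
  contrast <- familiarityContrast(dur, nBoot = 2000, seed = seed + 20L)
  write.csv(contrast, file.path(dir2, "familiarity_contrast.csv"),
            row.names = FALSE)

  g <- d2$grooming
  g$x_contact <- dur[[paste0("w", config$windows[1])]][
    match(.pairKey(g$bat_i, g$bat_j), paste(dur$bat_a, dur$bat_b))]
  unf <- g[g$unfamiliar == 1, ]
  mc <- config$mcmc
  fit <- fitNBMultiMembership(unf, nChains = mc$nChains, nAdapt = mc$nAdapt,
                              nBurn = mc$nBurn, nIter = mc$nIter,
                              rhatMax = 1.2, seed = seed + 30L)
  reduced <- fitNBMultiMembership(
    unf, terms = setdiff(modelTerms(fit), "x_contact"),
    nChains = mc$nChains, nAdapt = mc$nAdapt, nBurn = mc$nBurn,
    nIter = mc$nIter, rhatMax = 1.2, seed = seed + 31L)
  pcContact <- percentChange(posteriorDraws(fit, "x_contact")[, 1])
  pcInter <- percentChange(
    posteriorDraws(fit, "forced_proximity:post_treatment")[, 1])
  part <- r2Partition(fit, reduced)
  r2full <- bayesR2(fit)
  message(sprintf(
    "grooming model: contact effect %+.1f%% [%.1f, %.1f], R2 %.2f",
    pcContact$median, pcContact$lower, pcContact$upper, r2full$median))

  results <- list(
    study1 = list(incidence = inc, permutation_tests = permTests),
    study2 = list(
      network_metrics = metrics,
      contact_threshold_rssi = attr(contacts, "threshold"),
      n_contacts = nrow(contacts), n_encounters = nrow(enc),
      grooming_model = list(
        percent_change_contact = pcContact[c("median", "lower", "upper")],
        percent_change_interaction = pcInter[c("median", "lower", "upper")],
        r2_full = r2full[c("median", "lower", "upper")],
        r2_contact_share = part[c("median", "lower", "upper")])))
  jsonlite::write_json(results, file.path(config$outDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  files <- list.files(config$outDir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$outDir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("bondtrace")),
    seed = seed,
    n_perm = config$nPerm,
    quantile = config$quantile,
    windows = config$windows,
    hashes = as.list(tools::md5sum(sort(files))))
  names(manifest$hashes) <- substring(names(manifest$hashes),
                                      nchar(config$outDir) + 2L)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
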
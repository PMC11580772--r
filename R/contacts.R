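## Proximity-sensor pipeline: ping streams -> encounters -> RSSI-called
## contacts -> cumulative first-contact windows and contact networks.

#' Read sensor pings or bat metadata from CSV
#'
#' `pings.csv` has columns bat_a, bat_b, t_s, rssi; `bats.csv` has columns
#' bat, site.
#'
#' @param path CSV file path.
#' @return a validated data.frame.
#' @export
readPings <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(p, c("bat_a", "bat_b", "t_s", "rssi"), path)
  if (nrow(p) && any(p$bat_a == p$bat_b))
    stop("pings with bat_a == bat_b", call. = FALSE)
  if (nrow(p) && any(p$t_s < 0)) stop("negative ping times", call. = FALSE)
  p
}

#' @rdname readPings
#' @export
readBats <- function(path) {
  b <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(b, c("bat", "site"), path)
  b
}

## canonical unordered pair key
.pairKey <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))

#' Segment a ping stream into encounters
#'
#' Consecutive pings of the same unordered pair separated by at most
#' `maxGapS` seconds form one encounter. Encounter duration is the span
#' from first to last ping, with a minimum of one ping interval for
#' single-ping encounters.
#'
#' @param pings data.frame with bat_a, bat_b, t_s, rssi.
#' @param maxGapS maximum within-encounter inter-ping gap (seconds).
#' @param pingIntervalS nominal ping interval; the duration floor for
#'   singleton encounters.
#' @return data.frame with bat_a, bat_b, start_s, end_s, duration_s,
#'   max_rssi, n_pings (pair members in canonical order).
#' @export
segmentEncounters <- function(pings, maxGapS = 60, pingIntervalS = 2) {
  if (maxGapS < 0) stop("maxGapS must be >= 0", call. = FALSE)
  if (pingIntervalS <= 0) stop("pingIntervalS must be > 0", call. = FALSE)
  .requireColumns(pings, c("bat_a", "bat_b", "t_s", "rssi"), "pings")
  empty <- data.frame(bat_a = character(), bat_b = character(),
                      start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), max_rssi = numeric(),
                      n_pings = integer(), stringsAsFactors = FALSE)
  if (!nrow(pings)) return(empty)

  a <- pmin(pings$bat_a, pings$bat_b)
  b <- pmax(pings$bat_a, pings$bat_b)
  key <- paste(a, b)
  out <- lapply(split(data.frame(a, b, t = pings$t_s, rssi = pings$rssi,
                                 stringsAsFactors = FALSE), key),
    function(d) {
      d <- d[order(d$t), ]
      brk <- c(0, cumsum(diff(d$t) > maxGapS))
      do.call(rbind, lapply(split(d, brk), function(e)
        data.frame(bat_a = e$a[1], bat_b = e$b[1],
                   start_s = e$t[1], end_s = e$t[nrow(e)],
                   duration_s = max(e$t[nrow(e)] - e$t[1], pingIntervalS),
                   max_rssi = max(e$rssi), n_pings = nrow(e),
                   stringsAsFactors = FALSE)))
    })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$bat_a, out$bat_b, out$start_s), ]
}

#' Call contacts by an RSSI quantile threshold
#'
#' A contact is an encounter whose maximum received signal strength is at or
#' above the given empirical quantile of maximum RSSI over \emph{all}
#' encounters in the dataset (both familiarity classes pooled). The top 5\%
#' corresponds to `quantile = 0.95`; the close-contact sensitivity variant
#' uses `quantile = 0.99`. Ties at the threshold are retained.
#'
#' @param encounters data.frame from \code{\link{segmentEncounters}}.
#' @param quantile probability in (0, 1); retain encounters with
#'   `max_rssi >= quantile(max_rssi, quantile)`.
#' @return the retained subset, with the threshold attached as attribute
#'   `threshold`.
#' @export
callContacts <- function(encounters, quantile = 0.95) {
  if (!nrow(encounters)) stop("empty encounter list", call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must lie in (0, 1)", call. = FALSE)
  thr <- stats::quantile(encounters$max_rssi, quantile, names = FALSE)
  out <- encounters[encounters$max_rssi >= thr, ]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Cumulative first-contact durations per pair and window
#'
#' For each unordered pair of bats and each cumulative window `[0, W h)`,
#' sums the minutes of contact-encounter time intersecting the window.
#' Every pair from the metadata appears; pairs with no contacts get 0.
#' Pairs are flagged familiar when both bats share a capture site (a
#' "first contact" is a contact between unfamiliar bats).
#'
#' @param contacts encounter data.frame (typically the output of
#'   \code{\link{callContacts}}; pass all encounters for unfiltered
#'   proximity time).
#' @param bats metadata data.frame with bat, site.
#' @param windowsH increasing vector of window lengths in hours.
#' @return data.frame with bat_a, bat_b, familiar and one `w<W>` minutes
#'   column per window; minutes are non-decreasing across windows.
#' @export
firstContactDurations <- function(contacts, bats,
                                  windowsH = c(4, 8, 12, 16, 20, 24)) {
  if (is.unsorted(windowsH, strictly = TRUE))
    stop("windowsH must be strictly increasing", call. = FALSE)
  .requireColumns(bats, c("bat", "site"), "bats")
  unknown <- setdiff(c(contacts$bat_a, contacts$bat_b), bats$bat)
  if (length(unknown))
    stop("contacts involve unknown bat id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  prs <- t(utils::combn(sort(bats$bat), 2L))
  out <- data.frame(bat_a = prs[, 1], bat_b = prs[, 2],
                    stringsAsFactors = FALSE)
  siteOf <- setNames(bats$site, bats$bat)
  out$familiar <- siteOf[out$bat_a] == siteOf[out$bat_b]

  key <- if (nrow(contacts)) .pairKey(contacts$bat_a, contacts$bat_b)
         else character()
  okey <- paste(out$bat_a, out$bat_b)
  for (w in windowsH) {
    col <- paste0("w", w)
    if (nrow(contacts)) {
      ov <- pmax(pmin(contacts$start_s + contacts$duration_s, w * 3600) -
                 contacts$start_s, 0)
      s <- tapply(ov, key, sum) / 60
      v <- as.numeric(s[okey])
      out[[col]] <- ifelse(is.na(v), 0, v)
    } else out[[col]] <- 0
  }
  rownames(out) <- NULL
  out
}

#' Build a contact network for one window
#'
#' @param durations output of \code{\link{firstContactDurations}}.
#' @param bats metadata data.frame with bat, site.
#' @param windowH one of the window lengths present in `durations`.
#' @return a \code{\link{ContactNetwork-class}} object whose edges carry the
#'   contact minutes accumulated within the window.
#' @export
contactNetwork <- function(durations, bats, windowH) {
  col <- paste0("w", windowH)
  if (!col %in% names(durations))
    stop("window ", windowH, " h not present in durations", call. = FALSE)
  edges <- durations[, c("bat_a", "bat_b", "familiar")]
  edges$minutes <- durations[[col]]
  new("ContactNetwork", nodes = bats[, c("bat", "site")],
      edges = edges[, c("bat_a", "bat_b", "minutes", "familiar")],
      windowH = windowH)
}

#' Network density and categorical assortativity by capture site
#'
#' Density is the proportion of unordered pairs with positive contact time.
#' Assortativity is the weighted categorical (discrete) assortativity
#' coefficient \eqn{r = (\sum_i e_{ii} - \sum_i a_i b_i) /
#' (1 - \sum_i a_i b_i)} computed on the site-mixing matrix with edge
#' weights as multiplicities; +1 means all contact time is within-site.
#'
#' @param net a \code{\link{ContactNetwork-class}} object.
#' @return list with `density` and `assortativity` (NA when the network has
#'   no positive edges or the denominator vanishes).
#' @export
networkMetrics <- function(net) {
  stopifnot(is(net, "ContactNetwork"))
  n <- nrow(net@nodes)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  e <- net@edges[net@edges$minutes > 0, ]
  dens <- nrow(e) / (n * (n - 1) / 2)
  if (!nrow(e)) return(list(density = 0, assortativity = NA_real_))

  siteOf <- setNames(net@nodes$site, net@nodes$bat)
  sites <- sort(unique(net@nodes$site))
  m <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  for (k in seq_len(nrow(e))) {
    si <- siteOf[[e$bat_a[k]]]; sj <- siteOf[[e$bat_b[k]]]
    w <- e$minutes[k]
    ## undirected: each edge contributes to both stub directions
    m[si, sj] <- m[si, sj] + w
    m[sj, si] <- m[sj, si] + w
  }
  m <- m / sum(m)
  ai <- rowSums(m); bi <- colSums(m)
  denom <- 1 - sum(ai * bi)
  r <- if (abs(denom) < 1e-12) NA_real_ else (sum(diag(m)) - sum(ai * bi)) / denom
  list(density = dens, assortativity = unname(r))
}

#' Familiar vs unfamiliar contact time with bootstrap intervals
#'
#' Per window and familiarity class, the mean contact minutes across pairs
#' with a seeded percentile bootstrap over pairs (the pair is the
#' resampling unit).
#'
#' @param durations output of \code{\link{firstContactDurations}} (needs a
#'   `familiar` column).
#' @param nBoot bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return data.frame with window_h, familiar, mean, lower, upper, n_pairs.
#' @export
familiarityContrast <- function(durations, nBoot = 5000, level = 0.95,
                                seed = 1L) {
  wcols <- grep("^w[0-9]+$", names(durations), value = TRUE)
  if (!length(wcols)) stop("no window columns in durations", call. = FALSE)
  if (!any(durations$familiar) || !any(!durations$familiar))
    stop("both familiarity classes must be nonempty", call. = FALSE)
  set.seed(seed)
  a <- (1 - level) / 2
  res <- list()
  for (col in wcols) {
    for (fam in c(TRUE, FALSE)) {
      v <- durations[[col]][durations$familiar == fam]
      if (diff(range(v)) == 0) lo <- up <- mean(v)
      else {
        bm <- vapply(seq_len(nBoot), function(i)
          mean(v[sample.int(length(v), length(v), replace = TRUE)]),
          numeric(1))
        q <- unname(quantile(bm, c(a, 1 - a)))
        lo <- q[1]; up <- q[2]
      }
      res[[length(res) + 1L]] <- data.frame(
        window_h = as.numeric(sub("^w", "", col)), familiar = fam,
        mean = mean(v), lower = lo, upper = up, n_pairs = length(v))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
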
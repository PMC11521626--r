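#' Behaviour from saltwater-immersion scores
#'
#' Loggers sample wet/dry every 3 s and sum to a 10-minute score from 0
#' (completely dry) to 200 (completely immersed). At sea, score 0 is flight,
#' 200 is rest on the water, anything in between is foraging. Colony
#' attendance is recognised separately: a continuous daytime dry spell of
#' 6 h or more is a burrow stay, and night visits are classified by a
#' two-component Gaussian EM mixture over nightly wet-event counts (arrival
#' and departure only happen in darkness, so a dry night alone cannot
#' separate colony attendance from night flight).
#'
#' @name immersion
NULL

#' Number of 3-s samples per 10-min bin (the maximum immersion score, 200)
#' @export
MAX_IMMERSION_SCORE <- 10 * 60 / 3

#' Classify at-sea behaviour states
#'
#' @param scores integer immersion scores in 0--200 (colony bins already
#'   masked out by the caller).
#' @return character vector: "dry" (flight), "wet" (rest), "intermediate"
#'   (foraging).
#' @export
classify_states <- function(scores) {
  bad <- which(is.na(scores) | scores < 0 | scores > MAX_IMMERSION_SCORE)
  if (length(bad)) {
    stop("immersion score out of [0, 200] at bin ", bad[1])
  }
  ifelse(scores == 0, "dry",
         ifelse(scores == MAX_IMMERSION_SCORE, "wet", "intermediate"))
}

# maximal runs of TRUE; returns data.frame(start_idx, end_idx, n)
.runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             n = r$lengths[keep])
}

#' Detect daytime burrow stays
#'
#' Maximal runs of score-0 bins lying entirely within [sunrise, sunset] and
#' lasting at least `min_dry_hours` are colony (burrow) intervals.
#'
#' @param trace data.frame `bin_start` (POSIXct UTC, 10-min spacing),
#'   `score`.
#' @param sun data.frame `date`, `sunrise`, `sunset` (e.g. from
#'   [sunrise_sunset()] at the colony).
#' @param min_dry_hours minimum continuous dry spell (default 6).
#' @return data.frame `start`, `end` (POSIXct), `date`, `n_bins`.
#' @export
detect_daytime_burrow <- function(trace, sun, min_dry_hours = 6) {
  min_bins <- ceiling(min_dry_hours * 6)
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      date = as.Date(character()), n_bins = integer())
  d <- as.Date(trace$bin_start, tz = "UTC")
  i <- match(d, sun$date)
  daylight <- !is.na(i) & trace$bin_start >= sun$sunrise[i] &
    (trace$bin_start + 600) <= sun$sunset[i]
  runs <- .runs_of(trace$score == 0 & daylight)
  runs <- runs[runs$n >= min_bins, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  data.frame(start = trace$bin_start[runs$start_idx],
             end = trace$bin_start[runs$end_idx] + 600,
             date = as.Date(trace$bin_start[runs$start_idx], tz = "UTC"),
             n_bins = runs$n)
}

#' Count nightly wet events
#'
#' A bin is "wet" if any immersion was recorded (score > 0); the night count
#' is the number of wet bins between sunset and the next sunrise.
#'
#' @param trace data.frame `bin_start`, `score`.
#' @param night_start,night_end POSIXct sunset and next sunrise.
#' @return integer count, or NA if the night interval is empty (polar day).
#' @export
count_night_wet_events <- function(trace, night_start, night_end) {
  if (is.na(night_start) || is.na(night_end) || night_end <= night_start) {
    return(NA_integer_)
  }
  sel <- trace$bin_start >= night_start & trace$bin_start < night_end
  if (!any(sel)) return(NA_integer_)
  sum(trace$score[sel] > 0)
}

#' Nightly wet-event summaries for a trace
#'
#' @param trace data.frame `bin_start`, `score`.
#' @param sun data.frame `date`, `sunrise`, `sunset` at the relevant
#'   location; night i is [sunset_i, sunrise_{i+1}).
#' @return data.frame `night_date`, `wet_event_count`.
#' @export
night_summaries <- function(trace, sun) {
  n <- nrow(sun) - 1
  if (n < 1) return(data.frame(night_date = as.Date(character()),
                               wet_event_count = integer()))
  counts <- vapply(seq_len(n), function(i)
    count_night_wet_events(trace, sun$sunset[i], sun$sunrise[i + 1]),
    integer(1))
  data.frame(night_date = sun$date[seq_len(n)], wet_event_count = counts)
}

#' Two-component Gaussian mixture by EM
#'
#' Univariate two-component normal mixture fit by
#' expectation-maximisation: means initialised at the 25th and 75th
#' percentiles, common initial SD, equal initial weights; E and M steps
#' iterate until the log-likelihood gain drops below `tol`. Components are
#' ordered so the drier (smaller-mean) component comes first.
#'
#' @param counts numeric (nightly wet-event counts), length >= 20, not all
#'   identical.
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @return object of class `mixture_fit`: `means` (mu_dry < mu_sea), `sds`,
#'   `weights`, `loglik` (per-iteration vector), `iterations`, `converged`.
#' @export
fit_night_mixture <- function(counts, tol = 1e-8, max_iter = 1000) {
  x <- counts[!is.na(counts)]
  if (length(x) < 20) stop("need at least 20 nights, got ", length(x))
  if (length(unique(x)) == 1) stop("degenerate mixture: all counts identical")
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (mu[1] == mu[2]) mu <- range(x)
  s <- rep(max(stats::sd(x) / 2, 1e-3), 2)
  w <- c(0.5, 0.5)
  ll <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll_new <- sum(log(tot))
    r1 <- d1 / tot
    if (is.finite(ll) && ll_new - ll < tol) {
      ll <- ll_new
      ll_trace <- c(ll_trace, ll_new)
      converged <- TRUE
      break
    }
    ll <- ll_new
    ll_trace <- c(ll_trace, ll_new)
    n1 <- sum(r1); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) stop("degenerate mixture: empty component")
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    s <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                sum((1 - r1) * (x - mu[2])^2) / n2))
    if (any(s < 1e-6)) stop("degenerate mixture: variance collapse")
    w <- c(n1, n2) / length(x)
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); s <- rev(s); w <- rev(w)
  }
  structure(list(means = mu, sds = s, weights = w, loglik = ll_trace,
                 iterations = it, converged = converged, n = length(x)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture (EM), n =", x$n, "\n",
      sprintf(" dry: mu = %.3f sd = %.3f w = %.3f\n",
              x$means[1], x$sds[1], x$weights[1]),
      sprintf(" sea: mu = %.3f sd = %.3f w = %.3f\n",
              x$means[2], x$sds[2], x$weights[2]),
      "loglik", sprintf("%.4f", utils::tail(x$loglik, 1)),
      "after", x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Posterior probability of the drier component
#'
#' @param fit a `mixture_fit`.
#' @param counts values to score.
#' @return posterior probability that each count belongs to the drier
#'   (colony) component.
#' @export
posterior_dry <- function(fit, counts) {
  d1 <- fit$weights[1] * stats::dnorm(counts, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * stats::dnorm(counts, fit$means[2], fit$sds[2])
  tot <- d1 + d2
  tot[tot == 0] <- .Machine$double.xmin
  d1 / tot
}

#' Classify night colony visits
#'
#' A night is a colony visit when it has a higher posterior probability of
#' belonging to the drier mixture component (posterior > 0.5).
#'
#' @param summaries data.frame from [night_summaries()].
#' @param fit a converged `mixture_fit`.
#' @return `summaries` with `posterior_dry_component` and `is_visit` added.
#' @export
classify_night_visits <- function(summaries, fit) {
  if (!fit$converged) stop("mixture fit did not converge")
  p <- posterior_dry(fit, summaries$wet_event_count)
  summaries$posterior_dry_component <- p
  summaries$is_visit <- !is.na(p) & p > 0.5
  summaries
}

#' Detect incubation stints
#'
#' Evidence of a breeding attempt: any maximal run of completely dry bins
#' lasting at least `min_days` (432 bins at 10 min for 3 days).
#'
#' @param trace data.frame `bin_start`, `score`.
#' @param min_days minimum stint length in days (default 3).
#' @return list `evidence` (logical) and `intervals` (data.frame start, end,
#'   n_bins).
#' @export
detect_incubation <- function(trace, min_days = 3) {
  min_bins <- min_days * 144
  runs <- .runs_of(trace$score == 0)
  runs <- runs[runs$n >= min_bins, , drop = FALSE]
  intervals <- if (nrow(runs)) {
    data.frame(start = trace$bin_start[runs$start_idx],
               end = trace$bin_start[runs$end_idx] + 600,
               n_bins = runs$n)
  } else {
    data.frame(start = as.POSIXct(character(), tz = "UTC"),
               end = as.POSIXct(character(), tz = "UTC"), n_bins = integer())
  }
  list(evidence = nrow(runs) > 0, intervals = intervals)
}

#' Day-length-standardised foraging effort
#'
#' Hours at sea spent foraging (intermediate daylight bins, colony bins
#' excluded) divided by the day length at the reference position -- the mean
#' monthly position in the non-breeding season, the colony in August.
#' Proportions above 1 (night foraging spilling over) are flagged, never
#' clipped.
#'
#' @param trace data.frame `bin_start`, `score`.
#' @param sun data.frame `date`, `sunrise`, `sunset`, `day_length` at the
#'   reference position.
#' @param colony_mask logical per bin: TRUE where the bird was at the colony
#'   (burrow or visit); excluded from "at sea".
#' @return object of class `foraging_effort`: data.frame `date`,
#'   `foraging_hours`, `daylight_hours`, `proportion`, `flagged`, plus the
#'   period mean as attribute `mean_proportion`.
#' @export
foraging_effort <- function(trace, sun, colony_mask = NULL) {
  if (is.null(colony_mask)) colony_mask <- rep(FALSE, nrow(trace))
  d <- as.Date(trace$bin_start, tz = "UTC")
  i <- match(d, sun$date)
  daylight <- !is.na(i) & trace$bin_start >= sun$sunrise[i] &
    trace$bin_start < sun$sunset[i]
  state <- classify_states(trace$score)
  forage <- daylight & !colony_mask & state == "intermediate"
  fh <- tapply(forage, d, sum) * 10 / 60
  days <- as.Date(names(fh))
  dl <- sun$day_length[match(days, sun$date)]
  prop <- ifelse(is.na(dl) | dl <= 0, NA_real_, as.numeric(fh) / dl)
  out <- data.frame(date = days, foraging_hours = as.numeric(fh),
                    daylight_hours = dl, proportion = prop,
                    flagged = !is.na(prop) & prop > 1)
  attr(out, "mean_proportion") <- mean(prop, na.rm = TRUE)
  class(out) <- c("foraging_effort", "data.frame")
  out
}

#' Count colony visits in a month
#'
#' Distinct nights classified as visits, plus days holding a daytime burrow
#' interval whose adjoining nights were not already counted (a continuous
#' night-day-night stay counts once per visit night).
#'
#' @param visits data.frame from [classify_night_visits()].
#' @param burrow data.frame from [detect_daytime_burrow()] (may be empty).
#' @param month month number (default 8, August).
#' @param year optional calendar year restriction.
#' @param include_daytime count daytime-only burrow stays too (default TRUE).
#' @return integer count, or NA if the month is not covered.
#' @export
count_colony_visits <- function(visits, burrow = NULL, month = 8,
                                year = NULL, include_daytime = TRUE) {
  sel <- as.integer(format(visits$night_date, "%m")) == month
  if (!is.null(year)) {
    sel <- sel & as.integer(format(visits$night_date, "%Y")) == year
  }
  v <- visits[sel, , drop = FALSE]
  if (!nrow(v)) return(NA_integer_)
  nights <- v$night_date[v$is_visit]
  n <- length(unique(nights))
  if (include_daytime && !is.null(burrow) && nrow(burrow)) {
    bsel <- as.integer(format(burrow$date, "%m")) == month
    if (!is.null(year)) {
      bsel <- bsel & as.integer(format(burrow$date, "%Y")) == year
    }
    bd <- unique(burrow$date[bsel])
    # a burrow day adjoining a counted visit night is the same stay
    extra <- bd[!(bd %in% nights | (bd - 1) %in% nights)]
    n <- n + length(extra)
  }
  as.integer(n)
}
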
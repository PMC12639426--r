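# CGM traces, meal logs, and the two trial endpoints: the postprandial blood
# glucose peak (PBGP) within 3 h of the first bite, and the 3-h incremental
# area under the curve (iAUC) above the fasting baseline taken 30 min before
# the meal.

#' Continuous glucose monitoring trace
#'
#' A single participant's interstitial glucose series on a nominal 5-min grid.
#' Timestamps must be strictly increasing and glucose finite and positive.
#' Grid gaps (consecutive timestamps differing from the nominal interval by
#' more than 50%) are detected and flagged.
#'
#' @param participant_id Participant identifier.
#' @param time `POSIXct` timestamps (timezone-naive ISO-8601 on input,
#'   handled as UTC; minute resolution).
#' @param glucose Glucose in mmol/L.
#' @param nominal_interval Sampling interval in minutes (default 5).
#' @return An object of class `cgm_trace`.
#' @export
cgm_trace <- function(participant_id, time, glucose, nominal_interval = 5) {
  if (length(time) != length(glucose)) stop_domain("time/glucose length mismatch")
  if (any(!is.finite(glucose)) || any(glucose <= 0)) {
    bad <- which(!is.finite(glucose) | glucose <= 0)[1]
    stop_domain("participant %s: nonpositive or non-finite glucose at %s",
                participant_id, format(time[bad]))
  }
  dt <- diff(as.numeric(time)) / 60
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop_domain("participant %s: timestamps not strictly increasing at %s",
                participant_id, format(time[bad]))
  }
  gaps <- which(abs(dt - nominal_interval) > 0.5 * nominal_interval)
  structure(
    list(participant_id = as.character(participant_id),
         samples = data.frame(time = time, glucose = glucose),
         nominal_interval = nominal_interval,
         gap_after = gaps),
    class = "cgm_trace"
  )
}

#' @export
print.cgm_trace <- function(x, ...) {
  cat(sprintf("CGM trace for %s: %d samples at %g-min nominal interval (%s to %s)%s\n",
              x$participant_id, nrow(x$samples), x$nominal_interval,
              format(min(x$samples$time)), format(max(x$samples$time)),
              if (length(x$gap_after)) sprintf(", %d gap(s)", length(x$gap_after)) else ""))
  invisible(x)
}

parse_times <- function(x) {
  x <- as.character(x)
  t <- rep(as.POSIXct(NA), length(x))
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(t)
    if (!any(miss)) break
    t[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  if (any(is.na(t))) {
    stop_domain("unparseable timestamp(s), first: '%s'", x[which(is.na(t))[1]])
  }
  attr(t, "tzone") <- "UTC"
  t
}

#' Read CGM traces from delimited text
#'
#' Expects a header `participant_id,timestamp,glucose_mmol_per_L`. Rows must
#' be in time order within each participant; out-of-order or duplicated
#' timestamps are an error (naming the first offender), as are nonpositive
#' glucose values.
#'
#' @param path Delimited text file.
#' @param sep Field separator.
#' @param nominal_interval Minutes between samples (default 5).
#' @return Named list of [cgm_trace()] objects, one per participant.
#' @export
read_cgm <- function(path, sep = ",", nominal_interval = 5) {
  if (!file.exists(path)) stop_domain("CGM file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("participant_id", "timestamp", "glucose_mmol_per_L")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_domain("CGM file %s lacks columns: %s", path, paste(missing, collapse = ", "))
  }
  df$time <- parse_times(df$timestamp)
  out <- lapply(split(df, df$participant_id), function(d) {
    dt <- diff(as.numeric(d$time))
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1L
      stop_domain("participant %s: rows out of time order or duplicated at %s",
                  d$participant_id[1], format(d$time[bad]))
    }
    cgm_trace(d$participant_id[1], d$time, d$glucose_mmol_per_L,
              nominal_interval = nominal_interval)
  })
  out[order(names(out))]
}

#' Read a meal-event log
#'
#' Delimited text with header `participant_id,period,day,food_code,first_bite`
#' (first_bite an ISO-8601 timestamp).
#'
#' @param path Delimited text file.
#' @param sep Field separator.
#' @return Data frame of meal events with parsed `first_bite` times.
#' @export
read_meal_log <- function(path, sep = ",") {
  if (!file.exists(path)) stop_domain("meal log not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("participant_id", "period", "day", "food_code", "first_bite")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_domain("meal log %s lacks columns: %s", path, paste(missing, collapse = ", "))
  }
  df$first_bite <- parse_times(df$first_bite)
  df$participant_id <- as.character(df$participant_id)
  df$food_code <- as.character(df$food_code)
  df
}

# Snap a first-bite time to the nearest trace sample and lay the post-meal
# window on the nominal grid, interpolating interior gaps of at most
# `max_gap` consecutive missing grid points. Returns grid times, glucose
# (NA where unrecoverable), the snap offset in minutes, and QC flags.
window_on_grid <- function(trace, first_bite, horizon_min, max_gap = 2) {
  st <- trace$samples
  tnum <- as.numeric(st$time)
  fb <- as.numeric(first_bite)
  i0 <- which.min(abs(tnum - fb))
  offset <- (tnum[i0] - fb) / 60
  if (abs(offset) > trace$nominal_interval / 2 + 1e-9) {
    stop_domain("participant %s: first bite %s is not near any CGM sample (offset %.1f min)",
                trace$participant_id, format(first_bite), offset)
  }
  t0 <- tnum[i0]
  step <- trace$nominal_interval * 60
  grid <- seq(t0, t0 + horizon_min * 60, by = step)
  idx <- match(round(grid), round(tnum))
  g <- st$glucose[idx]
  flags <- character(0)
  if (abs(offset) > 1e-9) flags <- c(flags, sprintf("snap_offset_min=%.2f", offset))
  miss <- is.na(g)
  if (any(miss)) {
    r <- rle(miss)
    runs <- r$lengths[r$values]
    # leading/trailing missing points cannot be interpolated
    interior_ok <- !miss[1] && !miss[length(miss)] && all(runs <= max_gap)
    if (interior_ok) {
      g <- stats::approx(grid[!miss], g[!miss], xout = grid)$y
      flags <- c(flags, sprintf("interpolated=%d", sum(miss)))
    } else {
      flags <- c(flags, sprintf("gap_run=%d", max(runs)))
    }
  }
  coverage <- mean(!is.na(g))
  if (coverage < 0.75) {
    stop_domain("participant %s: window after %s covers only %.0f%% of expected samples",
                trace$participant_id, format(first_bite), 100 * coverage)
  }
  if (any(is.na(g))) {
    stop_domain("participant %s: CGM gap longer than %d samples in the window after %s",
                trace$participant_id, max_gap, format(first_bite))
  }
  list(time = grid, glucose = g, offset = offset, flags = flags)
}

#' Postprandial blood glucose peak
#'
#' The maximum glucose over the window from the first bite (snapped to the
#' nearest grid sample) to `horizon_min` minutes after it. The peak is an
#' absolute maximum; it may equal the pre-meal value. The time of the
#' (earliest) peak is reported as an attribute.
#'
#' @param trace A [cgm_trace()].
#' @param first_bite `POSIXct` first-bite time.
#' @param horizon_min Window length in minutes (default 180).
#' @return Peak glucose in mmol/L, with attributes `peak_time` and `qc_flags`.
#' @export
compute_pbgp <- function(trace, first_bite, horizon_min = 180) {
  stopifnot(inherits(trace, "cgm_trace"))
  w <- window_on_grid(trace, first_bite, horizon_min)
  i <- which.max(w$glucose)   # earliest index at ties
  structure(w$glucose[i],
            peak_time = as.POSIXct(w$time[i], tz = "UTC", origin = "1970-01-01"),
            qc_flags = w$flags)
}

#' 3-h incremental area under the glucose curve
#'
#' Trapezoidal integral over `[first_bite, first_bite + horizon_min]` of the
#' glucose increment above the fasting baseline, the single sample nearest to
#' 30 min before the first bite (within +-2.5 min). Excursions below baseline
#' contribute zero under the default positive-increment convention; set
#' `net_auc = TRUE` for the signed (net) alternative.
#'
#' @param trace A [cgm_trace()].
#' @param first_bite `POSIXct` first-bite time.
#' @param horizon_min Window length in minutes (default 180).
#' @param baseline_offset_min Minutes before the first bite at which the
#'   fasting baseline is read (default 30).
#' @param net_auc If `TRUE`, negative increments are not clamped to zero.
#' @return iAUC in mmol/L.min, with attributes `baseline` and `qc_flags`.
#' @export
compute_iauc3h <- function(trace, first_bite, horizon_min = 180,
                           baseline_offset_min = 30, net_auc = FALSE) {
  stopifnot(inherits(trace, "cgm_trace"))
  tnum <- as.numeric(trace$samples$time)
  tb <- as.numeric(first_bite) - baseline_offset_min * 60
  ib <- which.min(abs(tnum - tb))
  if (abs(tnum[ib] - tb) > 2.5 * 60 + 1e-9) {
    stop_domain("participant %s: no baseline sample within 2.5 min of %d min before %s",
                trace$participant_id, baseline_offset_min, format(first_bite))
  }
  baseline <- trace$samples$glucose[ib]
  w <- window_on_grid(trace, first_bite, horizon_min)
  inc <- w$glucose - baseline
  if (!net_auc) inc <- pmax(inc, 0)
  dt <- diff(w$time) / 60
  auc <- sum(dt * (utils::head(inc, -1) + utils::tail(inc, -1)) / 2)
  structure(auc, baseline = baseline, qc_flags = w$flags)
}

#' Extract trial outcomes from traces and a meal log
#'
#' Computes one outcome record (PBGP, iAUC, baseline, QC flags) per meal
#' event. Events without a matching trace abort the run (listing the
#' offenders) unless `skip_unmatched = TRUE`.
#'
#' @param traces Named list of [cgm_trace()] objects (names = participant ids).
#' @param meal_log Data frame as returned by [read_meal_log()] (columns
#'   `participant_id, period, food_code, first_bite`; `day` optional).
#' @param horizon_min Endpoint window in minutes.
#' @param skip_unmatched Drop unmatched events (with a warning) instead of
#'   erroring.
#' @param net_auc Passed to [compute_iauc3h()].
#' @return Data frame with columns `participant_id, food_code, period, pbgp,
#'   iauc3h, baseline, qc_flags`.
#' @export
extract_outcomes <- function(traces, meal_log, horizon_min = 180,
                             skip_unmatched = FALSE, net_auc = FALSE) {
  unmatched <- !(meal_log$participant_id %in% names(traces))
  if (any(unmatched)) {
    msg <- paste(sprintf("%s (period %s)", meal_log$participant_id[unmatched],
                         meal_log$period[unmatched]), collapse = "; ")
    if (!skip_unmatched) stop_domain("meal events without a CGM trace: %s", msg)
    warning(sprintf("skipping meal events without a CGM trace: %s", msg),
            call. = FALSE)
    meal_log <- meal_log[!unmatched, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(meal_log)), function(i) {
    ev <- meal_log[i, ]
    tr <- traces[[ev$participant_id]]
    pb <- compute_pbgp(tr, ev$first_bite, horizon_min)
    ia <- compute_iauc3h(tr, ev$first_bite, horizon_min, net_auc = net_auc)
    data.frame(participant_id = ev$participant_id, food_code = ev$food_code,
               period = ev$period, pbgp = as.numeric(pb),
               iauc3h = as.numeric(ia), baseline = attr(ia, "baseline"),
               qc_flags = paste(unique(c(attr(pb, "qc_flags"),
                                         attr(ia, "qc_flags"))), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an outcome table as delimited text
#' @param outcomes Data frame from [extract_outcomes()] or
#'   [simulate_outcomes()].
#' @param path Output path.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_outcomes <- function(outcomes, path, sep = ",") {
  utils::write.table(outcomes, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
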
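#' Per-delivery record of exams, contractions and interventions
#'
#' Bundles one delivery's pelvic-exam sequence (time in decimal hours,
#' cervical dilation in cm, effacement in percent, fetal station on the
#' integer -3..+3 scale; missing values allowed before cleaning), the
#' contraction onset times produced upstream from uterine-pressure
#' analysis, and the delivery-level clinical flags.
#'
#' @param delivery_id identifier.
#' @param exams data.frame with columns `time`, `dilation`, `effacement`,
#'   `station` (time-sorted; sorted here if not).
#' @param contraction_onsets numeric vector of onset times (hours).
#' @param induced logical.
#' @param epidural_time,rom_time event times in hours, `NA` if absent.
#' @param delivery_time time of delivery in hours.
#' @return an object of class `delivery_record`.
#' @export
delivery_record <- function(delivery_id, exams, contraction_onsets = numeric(0),
                            induced = FALSE, epidural_time = NA_real_,
                            rom_time = NA_real_, delivery_time) {
  stopifnot(is.data.frame(exams),
            all(c("time", "dilation", "effacement", "station") %in% names(exams)),
            is.numeric(delivery_time), length(delivery_time) == 1)
  exams <- exams[order(exams$time), , drop = FALSE]
  rownames(exams) <- NULL
  structure(list(delivery_id = as.character(delivery_id), exams = exams,
                 contraction_onsets = sort(as.numeric(contraction_onsets)),
                 induced = isTRUE(induced),
                 epidural_time = as.numeric(epidural_time),
                 rom_time = as.numeric(rom_time),
                 delivery_time = as.numeric(delivery_time)),
            class = "delivery_record")
}

## Exclusion signal used by the cleaning pipeline: callers can catch
## condition class "laborgp_excluded" to drop a delivery with a reason.
exclude_delivery <- function(delivery_id, reason) {
  stop(structure(class = c("laborgp_excluded", "error", "condition"),
                 list(message = paste0("delivery ", delivery_id,
                                       " excluded: ", reason),
                      call = NULL)))
}

#' Restrict to the final 20-hour window and re-reference times
#'
#' Drops exams outside `[delivery_time - window, delivery_time]` (both
#' ends included) and shifts all times so that the first retained exam —
#' the reference time t0 — is at zero.  Contraction onsets before t0 are
#' dropped since cumulative counts start at t0.
#'
#' @param delivery a raw [delivery_record()].
#' @param window window length in hours before delivery (default 20).
#' @return the re-referenced `delivery_record`.
#' @export
window_and_reference <- function(delivery, window = 20) {
  stopifnot(inherits(delivery, "delivery_record"))
  lo <- delivery$delivery_time - window
  keep <- delivery$exams$time >= lo & delivery$exams$time <= delivery$delivery_time
  if (!any(keep)) exclude_delivery(delivery$delivery_id,
                                   "no exam inside the 20-h window")
  exams <- delivery$exams[keep, , drop = FALSE]
  t0 <- exams$time[1]
  exams$time <- exams$time - t0
  onsets <- delivery$contraction_onsets - t0
  onsets <- onsets[onsets >= 0 & onsets <= delivery$delivery_time - t0]
  out <- delivery
  out$exams <- exams
  rownames(out$exams) <- NULL
  out$contraction_onsets <- onsets
  out$epidural_time <- delivery$epidural_time - t0
  out$rom_time <- delivery$rom_time - t0
  out$delivery_time <- delivery$delivery_time - t0
  out
}

#' Remove descending-dilation and closely spaced exams
#'
#' Single left-to-right pass: an exam is dropped if its dilation is
#' strictly below the last retained exam's dilation (missing dilation is
#' retained and not compared).  A second pass then drops any exam within
#' 5 minutes of the previously retained exam.
#'
#' @param exams time-sorted exam data.frame.
#' @param min_gap minimum inter-exam gap in hours (default 5 minutes).
#' @return the filtered exam data.frame (a subsequence of the input).
#' @export
filter_exams <- function(exams, min_gap = 5 / 60) {
  if (nrow(exams) == 0) return(exams)
  keep <- logical(nrow(exams))
  last_dil <- -Inf
  for (i in seq_len(nrow(exams))) {
    d <- exams$dilation[i]
    if (!is.na(d) && d < last_dil) next
    keep[i] <- TRUE
    if (!is.na(d)) last_dil <- d
  }
  exams <- exams[keep, , drop = FALSE]
  if (nrow(exams) > 1) {
    keep2 <- logical(nrow(exams))
    keep2[1] <- TRUE
    last_t <- exams$time[1]
    for (i in 2:nrow(exams)) {
      if (exams$time[i] - last_t > min_gap) {
        keep2[i] <- TRUE
        last_t <- exams$time[i]
      }
    }
    exams <- exams[keep2, , drop = FALSE]
  }
  rownames(exams) <- NULL
  exams
}

#' Linearly interpolate isolated missing exam fields
#'
#' A missing dilation, effacement or station value is filled by the
#' time-linear interpolant between the nearest earlier and nearest later
#' exams with that field observed; exams for which interpolation is not
#' possible (no valid neighbor on one side) are removed.
#'
#' @param exams time-sorted exam data.frame.
#' @return exam data.frame with no missing fields.
#' @export
interpolate_missing <- function(exams) {
  if (nrow(exams) == 0) return(exams)
  for (f in c("dilation", "effacement", "station")) {
    v <- exams[[f]]
    miss <- which(is.na(v))
    obs <- which(!is.na(v))
    for (i in miss) {
      lo <- obs[obs < i]; hi <- obs[obs > i]
      if (length(lo) && length(hi)) {
        a <- max(lo); b <- min(hi)
        w <- (exams$time[i] - exams$time[a]) / (exams$time[b] - exams$time[a])
        exams[[f]][i] <- v[a] + w * (v[b] - v[a])
      }
    }
  }
  complete <- stats::complete.cases(exams[c("dilation", "effacement", "station")])
  out <- exams[complete, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative contraction count since t0
#'
#' Number of contraction onsets in the closed interval `[0, t]` (times
#' relative to t0).
#'
#' @param onsets sorted onset times in hours since t0.
#' @param t query time(s) in hours since t0.
#' @return integer count(s).
#' @export
cumulative_contractions <- function(onsets, t) {
  if (any(t < 0)) stop("cumulative contraction count queried before t0")
  vapply(t, function(tt) sum(onsets >= 0 & onsets <= tt), numeric(1))
}

#' Intervention flags at an exam time
#'
#' Epidural and rupture-of-membranes presence flags: 1 if the event time
#' is recorded and at or before the exam time.
#'
#' @param delivery a re-referenced [delivery_record()].
#' @param exam_time time(s) in hours since t0.
#' @return data.frame with columns `epidural` and `rom` (0/1).
#' @export
annotate_flags <- function(delivery, exam_time) {
  flag <- function(ev) as.integer(!is.na(ev) & ev <= exam_time)
  data.frame(epidural = flag(delivery$epidural_time),
             rom = flag(delivery$rom_time))
}

#' Full cleaning pipeline for one delivery
#'
#' Applies, in order: the 20-h window and t0 re-referencing, the
#' descending-dilation filter, the 5-minute-gap filter, linear
#' interpolation of isolated missing fields, and removal of exams that
#' remain incomplete.  Signals exclusion (condition class
#' `laborgp_excluded`) if fewer than two exams survive.
#'
#' @param delivery a raw [delivery_record()].
#' @param window window length in hours.
#' @return a cleaned `delivery_record`.
#' @export
preprocess_delivery <- function(delivery, window = 20) {
  d <- window_and_reference(delivery, window)
  d$exams <- interpolate_missing(filter_exams(d$exams))
  if (nrow(d$exams) < 2)
    exclude_delivery(d$delivery_id, "fewer than 2 exams after cleaning")
  d
}

#' Clean a list of deliveries, dropping excluded ones with a message
#'
#' @param deliveries list of raw [delivery_record()]s.
#' @param window window length in hours.
#' @param quiet suppress per-delivery exclusion messages.
#' @return list of cleaned `delivery_record`s.
#' @export
preprocess_deliveries <- function(deliveries, window = 20, quiet = TRUE) {
  out <- list()
  for (d in deliveries) {
    cl <- tryCatch(preprocess_delivery(d, window),
                   laborgp_excluded = function(e) {
                     if (!quiet) message(conditionMessage(e))
                     NULL
                   })
    if (!is.null(cl)) out[[length(out) + 1L]] <- cl
  }
  out
}

#' Build causal transition samples from a cleaned delivery
#'
#' One sample per exam after the first: predictors are the previous
#' exam's dilation, station and effacement, plus the cumulative
#' contraction count and intervention flags evaluated at the target
#' exam's time (both available in real time before the exam result is
#' known), the induction indicator and the elapsed time since the
#' previous exam; targets are the current exam's dilation and station.
#'
#' @param delivery a cleaned [delivery_record()].
#' @return data.frame of transition samples (possibly 0 rows).
#' @export
build_transitions <- function(delivery) {
  ex <- delivery$exams
  n <- nrow(ex)
  cols <- c("delivery_id", "exam_time", "elapsed", "prev_dilation",
            "prev_station", "prev_effacement", "cum_contractions",
            "epidural", "rom", "induced", "target_dilation",
            "target_station")
  if (n < 2) {
    empty <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(empty) <- cols
    return(empty)
  }
  k <- 2:n
  fl <- annotate_flags(delivery, ex$time[k])
  data.frame(delivery_id = delivery$delivery_id,
             exam_time = ex$time[k],
             elapsed = ex$time[k] - ex$time[k - 1],
             prev_dilation = ex$dilation[k - 1],
             prev_station = ex$station[k - 1],
             prev_effacement = ex$effacement[k - 1],
             cum_contractions = cumulative_contractions(
               delivery$contraction_onsets, ex$time[k]),
             epidural = fl$epidural,
             rom = fl$rom,
             induced = as.integer(delivery$induced),
             target_dilation = ex$dilation[k],
             target_station = ex$station[k],
             stringsAsFactors = FALSE)
}

#' Preprocess deliveries and pool their transition samples
#'
#' @param deliveries list of raw [delivery_record()]s.
#' @param window window length in hours.
#' @return pooled transitions data.frame.
#' @export
build_transition_table <- function(deliveries, window = 20) {
  cleaned <- preprocess_deliveries(deliveries, window)
  do.call(rbind, lapply(cleaned, build_transitions))
}

## ---- CSV interface ---------------------------------------------------

.parse_times <- function(x, times) {
  if (times == "hours") return(as.numeric(x))
  as.numeric(as.POSIXct(x, tz = "UTC")) / 3600
}

#' Read the three-table CSV delivery dialect
#'
#' `exams.csv`: delivery_id, timestamp, dilation, effacement, station.
#' `deliveries.csv`: delivery_id, delivery_timestamp, induced,
#' epidural_timestamp, rom_timestamp.  `contractions.csv`: delivery_id,
#' onset_timestamp.  Timestamps are decimal hours or ISO-8601.
#'
#' @param exams_csv,deliveries_csv,contractions_csv file paths.
#' @param times `"hours"` or `"iso8601"`.
#' @return list of raw [delivery_record()]s.
#' @export
read_delivery_tables <- function(exams_csv, deliveries_csv,
                                 contractions_csv = NULL,
                                 times = c("hours", "iso8601")) {
  times <- match.arg(times)
  ex <- utils::read.csv(exams_csv, stringsAsFactors = FALSE)
  dl <- utils::read.csv(deliveries_csv, stringsAsFactors = FALSE)
  ct <- if (!is.null(contractions_csv))
    utils::read.csv(contractions_csv, stringsAsFactors = FALSE)
  else data.frame(delivery_id = character(0), onset_timestamp = numeric(0))
  lapply(seq_len(nrow(dl)), function(i) {
    id <- as.character(dl$delivery_id[i])
    exi <- ex[as.character(ex$delivery_id) == id, , drop = FALSE]
    delivery_record(
      delivery_id = id,
      exams = data.frame(time = .parse_times(exi$timestamp, times),
                         dilation = as.numeric(exi$dilation),
                         effacement = as.numeric(exi$effacement),
                         station = as.numeric(exi$station)),
      contraction_onsets = .parse_times(
        ct$onset_timestamp[as.character(ct$delivery_id) == id], times),
      induced = as.logical(dl$induced[i]),
      epidural_time = .parse_times(dl$epidural_timestamp[i], times),
      rom_time = .parse_times(dl$rom_timestamp[i], times),
      delivery_time = .parse_times(dl$delivery_timestamp[i], times))
  })
}

#' Write deliveries in the CSV dialect read by [read_delivery_tables()]
#'
#' @param deliveries list of [delivery_record()]s.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_delivery_tables <- function(deliveries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- do.call(rbind, lapply(deliveries, function(d)
    data.frame(delivery_id = d$delivery_id, timestamp = d$exams$time,
               dilation = d$exams$dilation, effacement = d$exams$effacement,
               station = d$exams$station)))
  dl <- do.call(rbind, lapply(deliveries, function(d)
    data.frame(delivery_id = d$delivery_id,
               delivery_timestamp = d$delivery_time,
               induced = d$induced,
               epidural_timestamp = d$epidural_time,
               rom_timestamp = d$rom_time)))
  ct <- do.call(rbind, lapply(deliveries, function(d)
    if (length(d$contraction_onsets))
      data.frame(delivery_id = d$delivery_id,
                 onset_timestamp = d$contraction_onsets)
    else NULL))
  paths <- file.path(dir, c("exams.csv", "deliveries.csv", "contractions.csv"))
  utils::write.csv(ex, paths[1], row.names = FALSE)
  utils::write.csv(dl, paths[2], row.names = FALSE)
  utils::write.csv(ct, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write pooled transitions with a fixed column order
#'
#' @param transitions transitions data.frame.
#' @param path output CSV path.
#' @export
write_transitions <- function(transitions, path) {
  cols <- c("delivery_id", "exam_time", "elapsed", "prev_dilation",
            "prev_station", "prev_effacement", "cum_contractions",
            "epidural", "rom", "induced", "target_dilation",
            "target_station")
  utils::write.csv(transitions[cols], path, row.names = FALSE)
}
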
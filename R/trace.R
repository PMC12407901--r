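#' Construct a current-clamp recording trace
#'
#' Open-circuit transepithelial voltage with intermittent bipolar current
#' injections (+/- 0.5 nA in the standard protocol) and ordered protocol
#' event annotations ("dilution", "compound_added", ...).
#'
#' @param time_s Sample times, seconds, strictly increasing (irregular
#'   sampling allowed).
#' @param voltage_mV Transepithelial voltage, mV.
#' @param current_nA Injected current, nA; 0 between pulses.
#' @param events Data frame with columns `time_s`, `label`, ordered in time;
#'   may be empty.
#' @param area_cm2 Membrane area, cm^2; default 0.33 (6.5 mm Transwell
#'   insert).
#' @return An object of class `"recording_trace"`.
#' @export
recording_trace <- function(time_s, voltage_mV, current_nA,
                            events = data.frame(time_s = numeric(),
                                                label = character()),
                            area_cm2 = 0.33) {
  n <- length(time_s)
  stopifnot(length(voltage_mV) == n, length(current_nA) == n)
  if (n && any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (!is.finite(area_cm2) || area_cm2 <= 0) stop("area_cm2 must be > 0")
  if (!all(c("time_s", "label") %in% names(events)))
    stop("events needs columns time_s, label")
  if (nrow(events) > 1 && is.unsorted(events$time_s))
    stop("events must be ordered in time")
  structure(list(time_s = as.numeric(time_s),
                 voltage_mV = as.numeric(voltage_mV),
                 current_nA = as.numeric(current_nA),
                 events = events, area_cm2 = area_cm2),
            class = "recording_trace")
}

#' @export
print.recording_trace <- function(x, ...) {
  cat(sprintf("Current-clamp recording: %d samples over %.1f s, area %.2f cm^2\n",
              length(x$time_s), diff(range(x$time_s)), x$area_cm2))
  if (nrow(x$events)) {
    cat("events:\n")
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}

#' Read a recording trace from CSV
#'
#' Trace columns: `time_s`, `voltage_mV`, `current_nA`. Events ship in a
#' sidecar CSV with columns `time_s`, `label`.
#'
#' @param path Trace CSV path.
#' @param events_path Optional events CSV path.
#' @param area_cm2 Membrane area, cm^2.
#' @return A [recording_trace()].
#' @export
read_trace <- function(path, events_path = NULL, area_cm2 = 0.33) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "voltage_mV", "current_nA")
  if (!all(need %in% names(df)))
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  ev <- if (!is.null(events_path)) {
    if (!file.exists(events_path)) stop("events file not found: ", events_path)
    utils::read.csv(events_path, stringsAsFactors = FALSE)
  } else data.frame(time_s = numeric(), label = character())
  recording_trace(df$time_s, df$voltage_mV, df$current_nA, ev, area_cm2)
}

#' Detect current-injection pulses and pair them by polarity
#'
#' Finds contiguous runs of non-zero injected current, classifies their
#' polarity, and pairs each positive pulse with the adjacent negative pulse
#' (either order). Pulses that straddle a protocol event are rejected, and
#' the survivor of a broken pair is kept as an unpaired single-polarity
#' pulse.
#'
#' @param trace A [recording_trace()].
#' @param current_tol Currents with `abs(current) <= current_tol` nA count
#'   as zero.
#' @return Data frame of class `"pulse_set"`, one row per pulse: `pulse_id`,
#'   `pair_id` (`NA` if unpaired), `polarity` (+1/-1), `i_start`/`i_end`
#'   (sample indices), `t_start`/`t_end`, `amp_nA`, `ok`, `reason`. Empty
#'   (with a warning) if no pulses are found.
#' @export
detect_pulses <- function(trace, current_tol = 1e-9) {
  stopifnot(inherits(trace, "recording_trace"))
  on <- abs(trace$current_nA) > current_tol
  empty <- data.frame(pulse_id = integer(), pair_id = integer(),
                      polarity = integer(), i_start = integer(),
                      i_end = integer(), t_start = numeric(),
                      t_end = numeric(), amp_nA = numeric(),
                      ok = logical(), reason = character())
  class(empty) <- c("pulse_set", "data.frame")
  if (!any(on)) {
    warning("no current pulses found in trace")
    return(empty)
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  amp <- mapply(function(a, b) stats::median(trace$current_nA[a:b]),
                starts, ends)
  pulses <- data.frame(pulse_id = seq_along(starts), pair_id = NA_integer_,
                       polarity = as.integer(sign(amp)),
                       i_start = starts, i_end = ends,
                       t_start = trace$time_s[starts],
                       t_end = trace$time_s[ends],
                       amp_nA = amp, ok = TRUE, reason = "",
                       stringsAsFactors = FALSE)
  # reject pulses straddling a protocol event
  if (nrow(trace$events)) {
    for (i in seq_len(nrow(pulses))) {
      hit <- trace$events$time_s > pulses$t_start[i] &
        trace$events$time_s < pulses$t_end[i]
      if (any(hit)) {
        pulses$ok[i] <- FALSE
        pulses$reason[i] <- paste0("straddles event '",
                                   trace$events$label[which(hit)[1]], "'")
      }
    }
  }
  # pair adjacent opposite-polarity pulses among accepted ones
  idx <- which(pulses$ok)
  pid <- 0L
  j <- 1L
  while (j < length(idx)) {
    a <- idx[j]; b <- idx[j + 1L]
    if (pulses$polarity[a] * pulses$polarity[b] == -1L) {
      pid <- pid + 1L
      pulses$pair_id[c(a, b)] <- pid
      j <- j + 2L
    } else j <- j + 1L
  }
  class(pulses) <- c("pulse_set", "data.frame")
  pulses
}

.pulse_tail_median <- function(trace, i_start, i_end, tail_s) {
  t_end <- trace$time_s[i_end]
  sel <- i_start:i_end
  sel <- sel[trace$time_s[sel] >= t_end - tail_s]
  stats::median(trace$voltage_mV[sel])
}

#' Extract a transepithelial conductance series from pulse deflections
#'
#' For each paired +/- pulse the voltage deflection is taken between the
#' stable tails of the two pulse plateaus (total current step 2 * amp),
#' which cancels slow baseline drift to first order. Unpaired pulses fall
#' back to tail-minus-preceding-baseline with the single-pulse amplitude.
#' Ohm's law gives `Rt = dV/dI` (mV/nA = MOhm) and
#' `Gt = 1e-3 / (Rt * area)` in mS/cm^2.
#'
#' @param trace A [recording_trace()].
#' @param pulses A `"pulse_set"`; defaults to [detect_pulses()] on the
#'   trace.
#' @param tail_s Length of the stable tail used for each plateau median,
#'   seconds.
#' @return Data frame of class `"conductance_series"`: `time_s` (pulse-pair
#'   midpoint), `gt_mS_cm2`, `pair_id`, `ok`, `reason`. Zero-deflection
#'   pulses are flagged and excluded (`ok = FALSE`, `gt = NA`).
#' @examples
#' # 2 mV deflection for a 1 nA step across 0.33 cm^2 -> 1.515e-3 mS/cm^2
#' @export
compute_gt <- function(trace, pulses = detect_pulses(trace), tail_s = 1) {
  stopifnot(inherits(trace, "recording_trace"))
  out <- data.frame(time_s = numeric(), gt_mS_cm2 = numeric(),
                    pair_id = integer(), ok = logical(),
                    reason = character(), stringsAsFactors = FALSE)
  add_row <- function(time_s, gt, pair_id, ok, reason) {
    rbind(out, data.frame(time_s = time_s, gt_mS_cm2 = gt, pair_id = pair_id,
                          ok = ok, reason = reason,
                          stringsAsFactors = FALSE))
  }
  if (!nrow(pulses)) {
    class(out) <- c("conductance_series", "data.frame")
    return(out)
  }
  for (pid in sort(unique(pulses$pair_id[!is.na(pulses$pair_id)]))) {
    pp <- pulses[!is.na(pulses$pair_id) & pulses$pair_id == pid, ]
    pos <- pp[pp$polarity > 0, ][1, ]; neg <- pp[pp$polarity < 0, ][1, ]
    v_pos <- .pulse_tail_median(trace, pos$i_start, pos$i_end, tail_s)
    v_neg <- .pulse_tail_median(trace, neg$i_start, neg$i_end, tail_s)
    dv <- v_pos - v_neg
    di <- pos$amp_nA - neg$amp_nA
    tm <- mean(c(pos$t_start, neg$t_end))
    if (abs(dv) < .Machine$double.eps * 100) {
      out <- add_row(tm, NA_real_, pid, FALSE,
                     "zero deflection (infinite conductance)")
    } else {
      rt <- dv / di                                  # MOhm
      out <- add_row(tm, 1e-3 / (rt * trace$area_cm2), pid, TRUE, "")
    }
  }
  # single-polarity fallback for accepted unpaired pulses
  lone <- pulses[pulses$ok & is.na(pulses$pair_id), ]
  for (i in seq_len(nrow(lone))) {
    p <- lone[i, ]
    pre <- which(trace$time_s < p$t_start &
                   trace$time_s >= p$t_start - tail_s &
                   abs(trace$current_nA) <= 1e-9)
    if (!length(pre)) next
    dv <- .pulse_tail_median(trace, p$i_start, p$i_end, tail_s) -
      stats::median(trace$voltage_mV[pre])
    if (abs(dv) < .Machine$double.eps * 100) {
      out <- add_row(mean(c(p$t_start, p$t_end)), NA_real_, NA_integer_,
                     FALSE, "zero deflection (infinite conductance)")
    } else {
      rt <- dv / p$amp_nA
      out <- add_row(mean(c(p$t_start, p$t_end)),
                     1e-3 / (rt * trace$area_cm2), NA_integer_, TRUE,
                     "single-polarity fallback")
    }
  }
  out <- out[order(out$time_s), ]
  rownames(out) <- NULL
  class(out) <- c("conductance_series", "data.frame")
  out
}

#' Per-protocol-step plateau voltage and conductance
#'
#' Splits the recording at its protocol events and, for each inter-event
#' segment, reports the median pulse-free voltage and the median accepted
#' conductance over the last `window_s` seconds of the segment (the
#' equilibrated plateau). Pulse windows (plus a small margin) are excised
#' before voltage statistics so plateau values are invariant to pulse
#' placement. Segments shorter than the window use the whole segment, with
#' a warning.
#'
#' @param trace A [recording_trace()].
#' @param gt Optional `"conductance_series"`; defaults to
#'   [compute_gt()] on the trace.
#' @param window_s Plateau window length, seconds.
#' @param pulse_margin_s Margin excised around each pulse, seconds.
#' @return Data frame of class `"protocol_summary"`, one row per segment:
#'   `segment`, `label` (event starting the segment; `"start"` for the
#'   first), `t_start`, `t_end`, `window_s_used`, `v_plateau_mV`,
#'   `gt_plateau_mS_cm2`, `n_gt`.
#' @export
step_plateaus <- function(trace, gt = NULL, window_s = 60,
                          pulse_margin_s = 0.5) {
  stopifnot(inherits(trace, "recording_trace"))
  # pulse-free traces are legitimate here; silence the no-pulse warning
  if (is.null(gt)) gt <- suppressWarnings(compute_gt(trace))
  bounds <- c(trace$time_s[1], trace$events$time_s,
              trace$time_s[length(trace$time_s)])
  labels <- c("start", trace$events$label)
  pulses <- suppressWarnings(detect_pulses(trace))
  in_pulse <- rep(FALSE, length(trace$time_s))
  for (i in seq_len(nrow(pulses))) {
    in_pulse <- in_pulse |
      (trace$time_s >= pulses$t_start[i] - pulse_margin_s &
         trace$time_s <= pulses$t_end[i] + pulse_margin_s)
  }
  out <- lapply(seq_len(length(bounds) - 1L), function(k) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    seg_len <- t1 - t0
    w <- window_s
    if (seg_len < window_s) {
      warning(sprintf("segment %d ('%s') shorter than window (%.1f < %.1f s); using whole segment",
                      k, labels[k], seg_len, window_s))
      w <- seg_len
    }
    sel_v <- trace$time_s >= t1 - w & trace$time_s <= t1 & !in_pulse
    sel_g <- gt$ok & gt$time_s >= t1 - w & gt$time_s <= t1
    data.frame(segment = k, label = labels[k], t_start = t0, t_end = t1,
               window_s_used = w,
               v_plateau_mV = stats::median(trace$voltage_mV[sel_v]),
               gt_plateau_mS_cm2 = if (any(sel_g))
                 stats::median(gt$gt_mS_cm2[sel_g]) else NA_real_,
               n_gt = sum(sel_g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("protocol_summary", "data.frame")
  out
}

#' Dose-response conductance change
#'
#' The conductance added by a compound at one dose: plateau conductance
#' after addition minus plateau conductance before.
#'
#' @param pre_plateau,post_plateau Plateau conductances, mS/cm^2.
#' @return `post_plateau - pre_plateau`, mS/cm^2.
#' @export
dose_response_delta_gt <- function(pre_plateau, post_plateau) {
  if (any(!is.finite(pre_plateau)) || any(!is.finite(post_plateau)))
    stop("plateau conductances must be finite")
  post_plateau - pre_plateau
}

#' Reduce a recording to one selectivity-measurement row
#'
#' Convenience wrapper running pulse detection, conductance extraction and
#' plateau summarization on an ion-selectivity protocol recording (events
#' `"dilution"` then `"compound_added"`), returning the row consumed by
#' [fit_selectivity()]. The untreated values come from the segment between
#' the two events, the treated values from the final segment.
#'
#' @param trace A [recording_trace()].
#' @param v_junction_mV Junction potential measured post-lysis, mV.
#' @param replicate_id Replicate label.
#' @param window_s Plateau window, seconds.
#' @return One-row data frame with columns `replicate_id`, `g_frt`,
#'   `g_total`, `v_frt_raw`, `v_t_raw`, `v_junction`.
#' @export
trace_to_measurement <- function(trace, v_junction_mV, replicate_id = "r1",
                                 window_s = 60) {
  sm <- step_plateaus(trace, window_s = window_s)
  i_dil <- which(sm$label == "dilution")
  i_cmp <- which(sm$label == "compound_added")
  if (!length(i_dil) || !length(i_cmp))
    stop("trace must carry 'dilution' and 'compound_added' events")
  data.frame(replicate_id = replicate_id,
             g_frt = sm$gt_plateau_mS_cm2[i_dil],
             g_total = sm$gt_plateau_mS_cm2[i_cmp],
             v_frt_raw = sm$v_plateau_mV[i_dil],
             v_t_raw = sm$v_plateau_mV[i_cmp],
             v_junction = v_junction_mV,
             stringsAsFactors = FALSE)
}
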
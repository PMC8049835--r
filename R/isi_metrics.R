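# Spike detection, interspike intervals, burst-phase segmentation, firing
# pattern classification, and parameter sweeps.

#' Detect spikes as prominent local maxima of V
#'
#' Local maxima above `threshold` whose prominence (peak height above the
#' higher of the two flanking minima) reaches `min_prominence`.  Peak times
#' are refined by quadratic interpolation through the three samples around
#' each maximum.
#'
#' @param traj `prebotc_traj` (or data frame with columns t and V).
#' @param threshold detection threshold (mV); default -35.
#' @param min_prominence minimal peak prominence (mV); default 1.  The
#'   terminal spikes of the decaying-envelope phase are small; a low cutoff
#'   keeps the spike run continuous, as in the published ISI diagrams.
#' @return An object of class `prebotc_spikes`: list with `peak_times`,
#'   `peak_values` (interpolated), and the settings used.  May be empty.
#' @export
detect_spikes <- function(traj, threshold = -35, min_prominence = 1) {
  t <- traj$t; v <- traj$V
  n <- length(v)
  emptyres <- structure(list(peak_times = numeric(0), peak_values = numeric(0),
                             threshold = threshold,
                             min_prominence = min_prominence),
                        class = "prebotc_spikes")
  if (n < 3) return(emptyres)
  d <- diff(v)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  pk <- pk[v[pk] >= threshold]
  if (!length(pk)) return(emptyres)
  # prominence: climb from each peak to the flanking minima between
  # neighbouring candidate peaks
  bounds <- c(1, pk, n)
  keep <- logical(length(pk))
  for (i in seq_along(pk)) {
    lmin <- min(v[bounds[i]:pk[i]])
    rmin <- min(v[pk[i]:bounds[i + 2]])
    keep[i] <- (v[pk[i]] - max(lmin, rmin)) >= min_prominence
  }
  pk <- pk[keep]
  if (!length(pk)) return(emptyres)
  # quadratic interpolation of the apex
  tt <- t[pk]; vv <- v[pk]
  ok <- pk > 1 & pk < n
  i0 <- pk[ok]
  y1 <- v[i0 - 1]; y2 <- v[i0]; y3 <- v[i0 + 1]
  denom <- y1 - 2 * y2 + y3
  shift <- ifelse(abs(denom) > 0, 0.5 * (y1 - y3) / denom, 0)
  shift <- pmax(pmin(shift, 1), -1)
  dt <- (t[i0 + 1] - t[i0 - 1]) / 2
  tt[ok] <- t[i0] + shift * dt
  vv[ok] <- y2 - 0.25 * (y1 - y3) * shift
  structure(list(peak_times = tt, peak_values = vv, threshold = threshold,
                 min_prominence = min_prominence),
            class = "prebotc_spikes")
}

#' @export
print.prebotc_spikes <- function(x, ...) {
  cat("<prebotc_spikes> ", length(x$peak_times), " spikes",
      if (length(x$peak_times))
        paste0(", t in [", signif(min(x$peak_times), 6), ", ",
               signif(max(x$peak_times), 6), "] ms"),
      "\n", sep = "")
  invisible(x)
}

#' Interspike intervals
#'
#' Successive differences of spike peak times, optionally log10-transformed
#' (the convention used for ISI bifurcation diagrams).
#'
#' @param train `prebotc_spikes`.
#' @param log10 return log10 of the intervals in ms?
#' @return Numeric vector (empty for fewer than two spikes).
#' @export
spike_isi <- function(train, log10 = FALSE) {
  if (length(train$peak_times) < 2) return(numeric(0))
  isi <- diff(train$peak_times)
  if (log10) base::log10(isi) else isi
}

#' Segment one burst cycle into its four phases
#'
#' Phase 1 is the low-potential quiescent stage (a spike-free gap with mean
#' V below the quiescence ceiling); phase 2 runs from the burst's first
#' spike through the decaying-envelope spike run, up to the small-amplitude
#' stage; phase 3 is the small-amplitude passage near the depolarized focus
#' (the longest spike-free span with mean V above the ceiling, or, when
#' spiking never pauses, the envelope minimum); phase 4 is the regrowing
#' spike run closing the cycle.  Phases absent from a pattern are reported
#' with zero duration.
#'
#' @param traj full-system `prebotc_traj`.
#' @param train spikes from [detect_spikes()]; detected internally if NULL.
#' @param quiescence_ceiling mV bound separating low rest from the
#'   depolarized passage (see [classify_pattern()]).
#' @param gap_min minimal spike-free gap (ms) treated as a phase boundary.
#' @return Data frame with one row per phase (phase, t_start, t_end,
#'   duration) for the first complete cycle after the trajectory start.
#' @export
segment_phases <- function(traj, train = NULL, quiescence_ceiling = -35,
                           gap_min = 200) {
  if (is.null(train)) train <- detect_spikes(traj)
  st <- train$peak_times
  empty <- data.frame(phase = 1:4, t_start = NA_real_, t_end = NA_real_,
                      duration = 0)
  if (length(st) < 4) return(empty)
  gapdur <- diff(st)
  big <- which(gapdur > gap_min)
  if (!length(big)) return(empty)
  gap_mean <- vapply(big, function(i) {
    mean(traj$V[traj$t > st[i] & traj$t < st[i + 1]])
  }, numeric(1))
  low <- big[gap_mean < quiescence_ceiling]
  if (length(low) < 2) return(empty)    # need one cycle bracketed by rests
  # cycle: from the end of one low-quiescent gap to the end of the next
  b0 <- st[low[1] + 1]                  # first spike of the burst
  b1 <- st[low[2]]                      # last spike of the burst
  p1 <- c(st[low[1]], b0)
  inb <- big[big > low[1] & big < low[2]]
  inb <- inb[st[inb] >= b0]
  if (length(inb)) {
    # phase 3 = longest depolarized spike-free span inside the burst
    i3 <- inb[which.max(gapdur[inb])]
    p3 <- c(st[i3], st[i3 + 1])
  } else {
    # continuous spiking: split at the envelope minimum
    sel <- train$peak_times >= b0 & train$peak_times <= b1
    i3v <- which.min(train$peak_values[sel])
    t3 <- train$peak_times[sel][i3v]
    p3 <- c(t3, t3)
  }
  out <- data.frame(phase = 1:4,
                    t_start = c(p1[1], b0, p3[1], p3[2]),
                    t_end = c(p1[2], p3[1], p3[2], b1))
  out$duration <- pmax(out$t_end - out$t_start, 0)
  out
}

#' Classify the firing pattern of a trajectory
#'
#' Deterministic labels from phase presence:
#' `bursting_low_quiescence` when a spike-free low-potential span exists;
#' `bursting_high_quiescence` when spiking episodes are separated by a
#' depolarized spike-free plateau instead; `continuous_spiking` when spiking
#' never pauses; `quiescent` when there are no spikes at all.
#'
#' @param traj full-system `prebotc_traj` covering at least two burst
#'   periods (or 2 s for non-bursting patterns).
#' @param quiescence_ceiling mV bound separating the low-potential rest
#'   (which rises with stimulation, from about -54 mV unstimulated to about
#'   -42 mV near the transition) from the depolarized plateau near -24 mV;
#'   default -35 sits between the two clusters at every condition studied.
#' @param low_gap_min minimal spike-free span (ms) accepted as a
#'   low-potential quiescent phase.
#' @param plateau_min minimal spike-free span (ms) accepted as a
#'   depolarized plateau.
#' @param threshold,min_prominence spike detection settings.
#' @return One of `"bursting_low_quiescence"`, `"continuous_spiking"`,
#'   `"bursting_high_quiescence"`, `"quiescent"`.
#' @export
classify_pattern <- function(traj, quiescence_ceiling = -35,
                             low_gap_min = 200, plateau_min = 300,
                             threshold = -35, min_prominence = 1) {
  if (diff(range(traj$t)) < 2000)
    stop("trajectory window too short to classify")
  train <- detect_spikes(traj, threshold = threshold,
                         min_prominence = min_prominence)
  st <- train$peak_times
  if (length(st) < 2) return("quiescent")
  gap_starts <- st[-length(st)]
  gap_ends <- st[-1]
  gapdur <- gap_ends - gap_starts
  has_low <- FALSE
  has_plateau <- FALSE
  for (i in which(gapdur >= min(low_gap_min, plateau_min))) {
    sel <- traj$t > gap_starts[i] & traj$t < gap_ends[i]
    mv <- mean(traj$V[sel])
    if (gapdur[i] >= low_gap_min && mv < quiescence_ceiling) has_low <- TRUE
    if (gapdur[i] >= plateau_min && mv >= quiescence_ceiling)
      has_plateau <- TRUE
  }
  if (has_low) return("bursting_low_quiescence")
  if (has_plateau) return("bursting_high_quiescence")
  "continuous_spiking"
}

#' Sweep a stimulation parameter and classify each attractor
#'
#' Simulates the full system for every value on the grid, collects the
#' log10-ISI multiset and the firing-pattern label per value, and reports
#' grid-bracketed label transitions.
#'
#' @param param one of `"Iextz"`, `"k1"`, `"alpha"`, `"beta"`.
#' @param values numeric grid (sorted internally).
#' @param base base `prebotc_params`; `param` is overridden per point.
#' @param t_end,transient,dt_out simulation window settings per point.
#' @param ... classification settings passed to [classify_pattern()].
#' @return An object of class `prebotc_sweep`: list with `param`, `values`,
#'   `labels`, `isi` (list of log10-ISI vectors), and `transitions`
#'   (data frame of bracketing value pairs and the label change).
#' @export
pattern_sweep <- function(param = c("Iextz", "k1", "alpha", "beta"),
                          values, base = botc_params(),
                          t_end = 52000, transient = 20000, dt_out = 0.1,
                          ...) {
  param <- match.arg(param)
  values <- sort(values)
  labels <- character(length(values))
  isi <- vector("list", length(values))
  for (i in seq_along(values)) {
    p <- base
    p[[param]] <- values[i]
    lab <- tryCatch({
      tr <- simulate_full(sim_config(p, t_end = t_end, transient = transient,
                                     dt_out = dt_out))
      isi[[i]] <- spike_isi(detect_spikes(tr), log10 = TRUE)
      classify_pattern(tr, ...)
    }, error = function(e) paste0("failed: ", conditionMessage(e)))
    labels[i] <- lab
  }
  tr_idx <- which(labels[-1] != labels[-length(labels)])
  transitions <- data.frame(lower = values[tr_idx], upper = values[tr_idx + 1],
                            from = labels[tr_idx], to = labels[tr_idx + 1])
  structure(list(param = param, values = values, labels = labels, isi = isi,
                 transitions = transitions),
            class = "prebotc_sweep")
}

#' @export
print.prebotc_sweep <- function(x, ...) {
  cat("<prebotc_sweep> ", x$param, ": ", length(x$values), " points\n",
      sep = "")
  if (nrow(x$transitions)) {
    cat("  transitions:\n")
    print(x$transitions)
  }
  invisible(x)
}

#' Locate a classification transition by bisection
#'
#' Assumes the predicate flips once on `[lo, hi]` and bisects down to the
#' stated grid resolution; each probe is one full simulation.  Returns the
#' smallest grid value at which `predicate` is TRUE.
#'
#' @param param swept parameter name (as in [pattern_sweep()]).
#' @param lo,hi bracketing values with `predicate(lo) == FALSE` and
#'   `predicate(hi) == TRUE` (checked).
#' @param step grid resolution of the answer.
#' @param predicate function(label) -> logical applied to the
#'   [classify_pattern()] label.
#' @param base base `prebotc_params`.
#' @param t_end,transient,dt_out simulation window per probe.
#' @param ... classification settings passed to [classify_pattern()].
#' @return Transition value (multiple of `step` within the bracket).
#' @export
locate_transition <- function(param, lo, hi, step, predicate,
                              base = botc_params(),
                              t_end = 52000, transient = 20000,
                              dt_out = 0.1, ...) {
  eval_at <- function(v) {
    p <- base
    p[[param]] <- v
    tr <- simulate_full(sim_config(p, t_end = t_end, transient = transient,
                                   dt_out = dt_out))
    predicate(classify_pattern(tr, ...))
  }
  f_lo <- eval_at(lo)
  f_hi <- eval_at(hi)
  if (f_lo || !f_hi)
    stop("predicate does not flip on [lo, hi]: lo=", f_lo, " hi=", f_hi)
  while ((hi - lo) > step * 1.001) {
    mid <- lo + floor((hi - lo) / (2 * step)) * step
    if (mid <= lo) mid <- lo + step
    if (eval_at(mid)) hi <- mid else lo <- mid
  }
  hi
}
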
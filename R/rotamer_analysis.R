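# Rotamer-state classification of chi1 traces, occupancies and counting of
# sustained violations of the native (catalytically competent) state.

#' Define rotamer classification windows
#'
#' Disjoint angular windows on the chi1 circle, one flagged native.  The
#' defaults describe a catalytic-histidine analog: the in-site
#' (catalytically competent) well near 190 degrees and the out-of-site well
#' near 285 degrees, each with a 45-degree halfwidth — generous margins
#' around wells whose intrinsic spreads are roughly 9 and 12 degrees, since
#' classification boundaries (unlike well positions) are an analysis choice.
#'
#' @param states data.frame with columns `label`, `center` (degrees) and
#'   `halfwidth` (degrees).
#' @param native label of the native state.
#' @return an object of class `rotamer_windows`.
#' @export
rotamer_windows <- function(states = data.frame(
                              label = c("in_site", "out_site"),
                              center = c(190, 285),
                              halfwidth = c(45, 45)),
                            native = "in_site") {
  req <- c("label", "center", "halfwidth")
  if (!all(req %in% names(states)))
    stop_chisno("states needs columns label, center, halfwidth",
                "chisno_config_error")
  if (any(states$halfwidth <= 0))
    stop_chisno("halfwidths must be positive", "chisno_config_error")
  if (anyDuplicated(states$label))
    stop_chisno("state labels must be unique", "chisno_config_error")
  if (!native %in% states$label)
    stop_chisno("native label not among the states", "chisno_config_error")
  n <- nrow(states)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (circ_dist(states$center[i], states$center[j]) <
          states$halfwidth[i] + states$halfwidth[j])
        stop_chisno(sprintf("windows '%s' and '%s' overlap on the circle",
                            states$label[i], states$label[j]),
                    "chisno_config_error")
    }
  }
  structure(list(states = states, native = native), class = "rotamer_windows")
}

#' @export
print.rotamer_windows <- function(x, ...) {
  cat("<rotamer_windows>\n")
  for (i in seq_len(nrow(x$states)))
    cat(sprintf("  %s%s: %g +/- %g deg\n",
                x$states$label[i],
                if (x$states$label[i] == x$native) " (native)" else "",
                x$states$center[i], x$states$halfwidth[i]))
  invisible(x)
}

#' Classify chi1 frames into rotamer states
#'
#' Labels each frame by the window containing its angle under circular
#' (mod-360) containment, so windows may straddle any stacking cut; frames
#' in no window are labeled `"other"`.
#'
#' @param series a [dihedral_series()] or `stacked_series`.
#' @param windows a [rotamer_windows()].
#' @return an object of class `state_trace`: `times`, `labels`, `native`,
#'   and `dt` (median frame spacing, ns).
#' @export
classify_states <- function(series, windows = rotamer_windows()) {
  if (!inherits(windows, "rotamer_windows"))
    stop_chisno("expected rotamer_windows", "chisno_config_error")
  a <- series$angles %% 360
  labels <- rep("other", length(a))
  for (i in seq_len(nrow(windows$states))) {
    inside <- circ_dist(a, windows$states$center[i]) <= windows$states$halfwidth[i]
    labels[inside] <- windows$states$label[i]
  }
  dt <- if (length(series$times) > 1L) stats::median(diff(series$times)) else 0
  structure(
    list(times = series$times, labels = labels, native = windows$native,
         state_labels = windows$states$label, dt = dt,
         residue_id = series$residue_id %||% NA_integer_),
    class = "state_trace"
  )
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("<state_trace> %d frames; native '%s'; occupancies: %s\n",
              length(x$labels), x$native,
              paste(sprintf("%s=%.2f", names(occupancy(x)), occupancy(x)),
                    collapse = " ")))
  invisible(x)
}

#' State occupancies of a trace
#'
#' @param trace a [classify_states()] result.
#' @return named numeric vector of per-label fractions (all window labels
#'   plus `"other"`), summing to 1.
#' @export
occupancy <- function(trace) {
  if (length(trace$labels) == 0L)
    stop_chisno("empty trace", "chisno_empty_input")
  labs <- c(trace$state_labels, "other")
  counts <- vapply(setNames(labs, labs),
                   function(l) sum(trace$labels == l), numeric(1))
  counts / length(trace$labels)
}

# maximal runs with their durations; a run of frames t[i..j] lasts
# (t[j] - t[i]) + dt, each frame standing for one sampling interval
trace_runs <- function(trace) {
  r <- rle(trace$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(label = r$values,
             start = starts, end = ends,
             duration = trace$times[ends] - trace$times[starts] + trace$dt)
}

#' Count sustained violations of the native rotamer state
#'
#' A violation event is a maximal run of consecutive non-native frames whose
#' duration is at least `min_dwell` — the operational counterpart of marking
#' sustained excursions of a catalytic side chain out of its competent
#' rotamer, while ignoring single-frame flicker.
#'
#' @param trace a [classify_states()] result.
#' @param min_dwell minimum event duration, ns (default 1).
#' @return integer count of violation events.
#' @export
count_violations <- function(trace, min_dwell = 1) {
  if (min_dwell < 0)
    stop_chisno("min_dwell must be non-negative", "chisno_config_error")
  # a violation run may pass through several non-native states; merge them
  r <- rle(trace$labels == trace$native)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- trace$times[ends] - trace$times[starts] + trace$dt
  # small slack so durations assembled from floating-point frame times are
  # not rejected at the exact threshold
  sum(!r$values & dur >= min_dwell - 1e-9)
}

#' Mean dwell time in the native state
#'
#' @param trace a [classify_states()] result.
#' @return mean duration (ns) of maximal native runs, or `NA` if the trace
#'   never visits the native state.
#' @export
native_dwell <- function(trace) {
  runs <- trace_runs(trace)
  native <- runs$duration[runs$label == trace$native]
  if (length(native) == 0L) NA_real_ else mean(native)
}

#' Summarize rotamer stability across traces
#'
#' Per-trace native occupancy, violation counts and mean native dwell, plus
#' group means by variant and condition for comparative ordering between
#' enzyme variants.
#'
#' @param traces list of [classify_states()] results.
#' @param meta optional data.frame (one row per trace) with columns among
#'   `variant`, `condition`, `replicate`, `residue_id`.
#' @param min_dwell minimum violation duration, ns.
#' @return an object of class `stability_summary`: `per_trace` and
#'   `by_group` data.frames.
#' @export
summarize_stability <- function(traces, meta = NULL, min_dwell = 1) {
  if (length(traces) == 0L)
    stop_chisno("need at least one trace", "chisno_empty_input")
  if (is.null(meta))
    meta <- data.frame(variant = "WT", condition = "(all)",
                       replicate = seq_along(traces))
  if (nrow(meta) != length(traces))
    stop_chisno("meta must have one row per trace", "chisno_schema_error")
  if (is.null(meta$variant)) meta$variant <- "WT"
  if (is.null(meta$condition)) meta$condition <- "(all)"
  per_trace <- cbind(meta, data.frame(
    native_occupancy = vapply(traces, function(tr) occupancy(tr)[[tr$native]],
                              numeric(1)),
    n_violations = vapply(traces, count_violations, numeric(1),
                          min_dwell = min_dwell),
    mean_native_dwell = vapply(traces, native_dwell, numeric(1))
  ))
  by_group <- stats::aggregate(
    per_trace[c("native_occupancy", "n_violations")],
    by = list(variant = per_trace$variant, condition = per_trace$condition),
    FUN = mean
  )
  names(by_group)[names(by_group) == "n_violations"] <- "mean_violations"
  structure(list(per_trace = per_trace, by_group = by_group,
                 min_dwell = min_dwell),
            class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  cat(sprintf("<stability_summary> %d traces, min_dwell = %g ns\n",
              nrow(x$per_trace), x$min_dwell))
  print(x$by_group)
  invisible(x)
}
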
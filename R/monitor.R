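#' Relative impedance variation over the perfusion
#'
#' Converts an impedance trace to its relative variation over the initial
#' (thrombus-free) value: `dZ(t) = 100 * (|Z|(t) - Z0) / Z0`, with `Z0` the
#' mean of the first `baseline_window` samples (a single sample by default;
#' use a wider window for noisy logs).
#'
#' @param series a data frame with columns `time_s` and `zmag_ohm`, times
#'   strictly increasing (see [read_trace()]).
#' @param baseline_window number of leading samples averaged into `Z0`.
#' @return a tibble of class `delta_z_series` with columns `time_s`,
#'   `delta_z_pct` and attribute `baseline_ohm`.
#' @export
delta_z <- function(series, baseline_window = 1) {
  stopifnot(is.data.frame(series))
  if (!all(c("time_s", "zmag_ohm") %in% names(series))) {
    abort("`series` must have columns `time_s` and `zmag_ohm`")
  }
  if (nrow(series) < 2) abort("impedance series must have at least 2 samples")
  if (any(diff(series$time_s) <= 0)) abort("times must be strictly increasing")
  z0 <- mean(head(series$zmag_ohm, baseline_window))
  if (!is.finite(z0) || z0 <= 0) abort("baseline impedance must be > 0")
  out <- new_tibble(
    list(
      time_s = series$time_s,
      delta_z_pct = 100 * (series$zmag_ohm - z0) / z0
    ),
    nrow = nrow(series),
    class = "delta_z_series"
  )
  attr(out, "baseline_ohm") <- z0
  out
}

#' First time the relative impedance reaches a level
#'
#' Scans for the first sample at or above `level` percent and interpolates
#' linearly between it and the preceding sample; `NA` when the level is
#' never reached.
#'
#' @param dz a [delta_z()] tibble.
#' @param level threshold level, percent (default 10, the classification
#'   landmark).
#' @return crossing time in seconds, or `NA_real_`.
#' @export
crossing_time <- function(dz, level = 10) {
  stopifnot(is.data.frame(dz))
  d <- dz$delta_z_pct
  t <- dz$time_s
  i <- which(d >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  t[i - 1] + (level - d[i - 1]) * (t[i] - t[i - 1]) / (d[i] - d[i - 1])
}

group_bands <- function() {
  tibble(
    group = 1:4,
    lower = c(-Inf, 10, 20, 40),
    upper = c(10, 20, 40, Inf),
    crossing_bound = c(NA, 240, 180, 120)
  )
}

#' Classify blood behavior from a full perfusion trace
#'
#' Assigns one of the four adhesion/aggregation behaviors from the final
#' relative impedance increase at the end of perfusion (t = 300 s):
#' group 1 below 10% (minimal adhesion, no 10% crossing), group 2 in
#' `[10, 20)`% (regular adhesion/aggregation), group 3 in `[20, 40)`%
#' (strong aggregation), group 4 at or above 40% (massive, occlusion-prone
#' aggregation). Bands are half-open on the right, so a trace ending exactly
#' at 10.0% is group 2.
#'
#' The 10%-crossing time provides an independent consistency check: group 2
#' traces cross within 240 s, group 3 within 180 s, group 4 within 120 s
#' (vacuous for group 1). The final level is the primary key because the
#' four bands partition the axis while the crossing bounds overlap;
#' inconsistent traces are flagged, not rejected.
#'
#' @param dz a [delta_z()] tibble covering `[0, 300]` s (tolerance one
#'   sample; shorter traces are classified on the available data with a
#'   truncation warning).
#' @param end_time nominal end of perfusion, seconds.
#' @return a one-row tibble: `group`, `final_delta_z`,
#'   `crossing_time_10pct`, `consistent`, `truncated`.
#' @export
classify_trace <- function(dz, end_time = 300) {
  stopifnot(is.data.frame(dz))
  t_last <- max(dz$time_s)
  dt <- stats::median(diff(dz$time_s))
  truncated <- t_last < end_time - dt - 1e-9
  if (truncated) {
    warn(sprintf(
      "trace ends at %.1f s (< %g s): classifying on the available data", t_last, end_time
    ))
  }
  final <- dz$delta_z_pct[nrow(dz)]
  bands <- group_bands()
  g <- bands$group[final >= bands$lower & final < bands$upper]
  tc <- crossing_time(dz, 10)
  bound <- bands$crossing_bound[g]
  consistent <- if (g == 1L) is.na(tc) else !is.na(tc) && tc <= bound
  tibble(
    group = as.integer(g),
    final_delta_z = final,
    crossing_time_10pct = tc,
    consistent = consistent,
    truncated = truncated
  )
}

#' Real-time provisional classification
#'
#' Early-decision rule usable while the perfusion is still running, built
#' from the per-group 10%-crossing bounds: a trace that has crossed 10% by
#' 120 s is heading for group 4, by 180 s for group 3, by 240 s for group 2.
#' A trace that has not crossed cannot be told apart from the groups whose
#' crossing window is still open, so the prediction is a candidate set that
#' narrows as time passes; groups 1 and 2 separate only at the end of
#' perfusion.
#'
#' @param dz a [delta_z()] tibble.
#' @param t_now current time, seconds (<= 300); only samples up to `t_now`
#'   are used.
#' @return a one-row tibble: `t_now`, `group` (`NA` while undecided),
#'   `candidates` (string such as `"1|2"`), `decided`.
#' @export
predict_group <- function(dz, t_now) {
  stopifnot(is.data.frame(dz))
  if (t_now > 300) abort("`t_now` must be <= 300 s")
  seen <- dz[dz$time_s <= t_now, , drop = FALSE]
  tc <- if (nrow(seen) >= 2) crossing_time(seen, 10) else NA_real_
  if (!is.na(tc)) {
    g <- if (tc <= 120) 4L else if (tc <= 180) 3L else 2L
    return(tibble(t_now = t_now, group = g, candidates = as.character(g), decided = TRUE))
  }
  if (t_now >= 300) {
    res <- classify_trace(dz)
    return(tibble(t_now = t_now, group = res$group,
                  candidates = as.character(res$group), decided = TRUE))
  }
  cand <- c(1L, 2L)
  if (t_now < 180) cand <- c(cand, 3L)
  if (t_now < 120) cand <- c(cand, 4L)
  cand <- sort(cand)
  tibble(
    t_now = t_now, group = NA_integer_,
    candidates = paste(cand, collapse = "|"), decided = FALSE
  )
}

#' Detect abrupt detachment events in a perfusion trace
#'
#' A detachment (embolization) shows as a sudden sustained fall of the
#' relative impedance. An event is a maximal time interval `[t1, t2]` no
#' longer than `max_window` over which the trace decreases quasi-
#' monotonically (each step may rise by at most `step_tol` percentage
#' points) by at least `min_drop` percentage points in total, and whose two
#' boundary steps are genuine falls (below `-step_tol`) — without the
#' boundary condition a sharp drop flanked by flat signal would smear into
#' a family of sliding windows instead of one event with the drop's own
#' endpoints. Intervals contained in a larger qualifying interval are
#' suppressed; events are returned in time order.
#'
#' @param dz a [delta_z()] tibble.
#' @param min_drop minimum total fall, percentage points.
#' @param max_window maximum event duration, seconds.
#' @param step_tol largest per-step rise tolerated inside an event,
#'   percentage points.
#' @return a tibble with one row per event: `t1`, `t2`, `drop`.
#' @export
detect_detachment <- function(dz, min_drop = 5, max_window = 10, step_tol = 0.2) {
  stopifnot(is.data.frame(dz))
  t <- dz$time_s
  d <- dz$delta_z_pct
  n <- length(t)
  if (n < 2) return(tibble(t1 = numeric(0), t2 = numeric(0), drop = numeric(0)))
  tolerated <- c(FALSE, diff(d) <= step_tol)
  falling <- c(FALSE, diff(d) < -step_tol)
  best_j <- rep(NA_integer_, n)
  for (i in seq_len(n - 1)) {
    if (!falling[i + 1]) next             # events open on a genuine fall
    j <- i
    while (j < n && tolerated[j + 1] && t[j + 1] - t[i] <= max_window) j <- j + 1
    if (j == i) next
    cand <- seq(i + 1, j)
    ok <- cand[d[i] - d[cand] >= min_drop & falling[cand]]  # and close on one
    if (length(ok)) best_j[i] <- max(ok)
  }
  keep <- which(!is.na(best_j))
  if (!length(keep)) return(tibble(t1 = numeric(0), t2 = numeric(0), drop = numeric(0)))
  # suppress intervals contained in an earlier-starting qualifying interval
  runmax <- -Inf
  sel <- logical(length(keep))
  for (m in seq_along(keep)) {
    if (best_j[keep[m]] > runmax) {
      sel[m] <- TRUE
      runmax <- best_j[keep[m]]
    }
  }
  i1 <- keep[sel]
  i2 <- best_j[i1]
  tibble(t1 = t[i1], t2 = t[i2], drop = d[i1] - d[i2])
}

#' Plot a relative-impedance trace with group bands
#'
#' @param object a [delta_z()] tibble.
#' @param events optional [detect_detachment()] result drawn as shaded
#'   intervals.
#' @param ... unused.
#' @method autoplot delta_z_series
#' @export
autoplot.delta_z_series <- function(object, events = NULL, ...) {
  bands <- group_bands()
  bands$ymin <- c(min(-1, min(object$delta_z_pct)), 10, 20, 40)
  bands$ymax <- c(10, 20, 40, max(45, max(object$delta_z_pct) + 2))
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$delta_z_pct)) +
    ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE, alpha = 0.08,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$ymin, ymax = .data$ymax,
                   fill = factor(.data$group))
    ) +
    ggplot2::geom_hline(yintercept = 10, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta * Z ~ ("%")),
                  fill = "group band") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE, alpha = 0.25, fill = "red",
      ggplot2::aes(xmin = .data$t1, xmax = .data$t2, ymin = -Inf, ymax = Inf)
    )
  }
  p
}
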
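#' Fast traveling-wave speed by time-shift correlation
#'
#' Estimates the speed of the fast oscillation waves that sweep through
#' recruited tissue.  Thirty vertices are sampled uniformly on the
#' shortest surface path between the vertices closest to the innermost and
#' outermost electrode contacts; their q1 time series over a 1 s window
#' are time-shifted by \code{d_g / u} for every candidate speed \code{u}
#' on a grid (50 to 1000 mm/s, 200 points), and the speed maximizing the
#' mean pairwise Pearson correlation of the aligned series is returned.
#'
#' @param result a [simulate_field()] result with q1 recorded.
#' @param surface,electrode geometry used in the simulation.
#' @param t_start start of the analysis window (s).  When NULL, candidate
#'   windows starting 0.5, 1.5, 2.5, ... s after the whole path is
#'   recruited are scanned and the one with the highest mean pairwise
#'   correlation of the aligned series is kept — an automated stand-in
#'   for picking the window where the travelling waves are clearest.
#' @param window_s window length (s).
#' @param n_path number of path sample vertices.
#' @param v_range,n_grid speed grid (mm/s).
#' @return object of class \code{wave_speed_estimate}: list with
#'   \code{speed} (mm/s), \code{grid}, \code{correlation} (profile),
#'   \code{max_correlation}, \code{saturated} (argmax on a grid edge),
#'   \code{low_confidence} (max correlation below 0.3), \code{t_start},
#'   \code{path} (the sampled vertices and their distances).
#' @export
estimate_fast_wave_speed <- function(result, surface, electrode,
                                     t_start = NULL, window_s = 1,
                                     n_path = 30, v_range = c(50, 1000),
                                     n_grid = 200) {
  if (is.null(result$q1))
    stop("q1 was not recorded; rerun simulate_field(record_q1 = TRUE)")
  v_first <- nearest_vertex(surface, electrode$positions[1, ])
  v_last <- nearest_vertex(surface, electrode$positions[nrow(electrode$positions), ])
  path <- shortest_path_vertices(surface, v_first, v_last, n_points = n_path)
  if (is.null(t_start)) {
    rec <- recruitment_times(result)[path$vertices]
    if (anyNA(rec))
      stop("path not fully recruited; cannot pick an analysis window")
    cand <- max(rec) + 0.5 + 0:4
    cand <- cand[cand + window_s <= max(result$t)]
    if (!length(cand))
      stop("recording too short after full recruitment for a ", window_s,
           " s analysis window")
    if (length(cand) > 1) {
      ests <- lapply(cand, function(ts)
        estimate_fast_wave_speed(result, surface, electrode, t_start = ts,
                                 window_s = window_s, n_path = n_path,
                                 v_range = v_range, n_grid = n_grid))
      return(ests[[which.max(vapply(ests, `[[`, numeric(1),
                                    "max_correlation"))]])
    }
    t_start <- cand
  }
  if (t_start + window_s > max(result$t))
    stop("analysis window [", t_start, ", ", t_start + window_s,
         "] s exceeds the recording (", round(max(result$t), 2), " s)")
  w <- which(result$t >= t_start & result$t <= t_start + window_s)
  q1m <- result$q1[w, path$vertices, drop = FALSE]
  tw <- result$t[w]
  grid <- seq(v_range[1], v_range[2], length.out = n_grid)
  prof <- vapply(grid, function(u) {
    sh <- vapply(seq_len(n_path), function(i)
      approx(tw - path$distances[i] / u, q1m[, i], xout = tw)$y,
      numeric(length(tw)))
    ok <- complete.cases(sh)
    if (sum(ok) < 4) return(NA_real_)
    cm <- suppressWarnings(cor(sh[ok, , drop = FALSE]))
    mean(cm[upper.tri(cm)], na.rm = TRUE)
  }, numeric(1))
  i <- which.max(prof)
  structure(list(speed = grid[i], grid = grid, correlation = prof,
                 max_correlation = prof[i],
                 saturated = i == 1L || i == n_grid,
                 low_confidence = prof[i] < 0.3,
                 t_start = t_start,
                 path = path[c("vertices", "distances")]),
            class = "wave_speed_estimate")
}

#' @export
print.wave_speed_estimate <- function(x, ...) {
  cat(sprintf("fast-wave speed: %.1f mm/s (mean pairwise corr %.2f)%s%s\n",
              x$speed, x$max_correlation,
              if (x$saturated) " [saturated at grid edge]" else "",
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Seizure spread velocity as a function of coupling strength
#'
#' For each coupling gain gamma_11, simulates seizure spread on a
#' rectangular cortical sheet (default 40 x 20 mm) with an epileptogenic
#' strip of width 10 mm along one narrow side, and measures the spread
#' velocity between two midline probes placed 10 and 30 mm beyond the
#' strip edge: velocity = probe separation / recruitment-time difference.
#' Simulations halt shortly after the far probe is recruited.
#'
#' @param params an [epileptor_params()]; gamma_11 is overridden per run.
#' @param gamma11_values positive coupling gains to sweep.
#' @param domain sheet length and width (mm).
#' @param ez_width width of the epileptogenic strip (mm).
#' @param probes probe distances from the strip edge (mm).
#' @param edge_length mesh resolution (mm).
#' @param duration_s maximum simulated time per run (s).
#' @return object of class \code{velocity_sweep}: data.frame with
#'   \code{gamma_11}, \code{velocity} (mm/s; NA when the far probe is
#'   never recruited), \code{t_probe1}, \code{t_probe2}.
#' @export
spread_velocity_sweep <- function(params, gamma11_values,
                                  domain = c(40, 20), ez_width = 10,
                                  probes = c(10, 30), edge_length = 0.8,
                                  duration_s = 40) {
  stopifnot(all(gamma11_values > 0), length(probes) == 2)
  sheet <- .grid_sheet(domain[1], domain[2], edge_length)
  kernel <- build_local_kernel(sheet, b = params$b)
  u0 <- ifelse(sheet$vertices[, 1] <= ez_width,
               params$u0_ez, params$u0_surround)
  mid <- domain[2] / 2
  p1 <- nearest_vertex(sheet, c(ez_width + probes[1], mid, 0))
  p2 <- nearest_vertex(sheet, c(ez_width + probes[2], mid, 0))
  dx <- sheet$vertices[p2, 1] - sheet$vertices[p1, 1]
  rows <- lapply(gamma11_values, function(g11) {
    p <- params; p$gamma_11 <- g11
    r <- simulate_field(sheet, p, u0, duration_s, output_hz = 128,
                        kernel = kernel, record_u1 = TRUE,
                        stop_vertices = p2, stop_extra_s = 0.5)
    rec <- recruitment_times(r)
    t1 <- rec[p1]; t2 <- rec[p2]
    vel <- if (is.na(t1) || is.na(t2) || t2 <= t1) NA_real_ else dx / (t2 - t1)
    data.frame(gamma_11 = g11, velocity = vel, t_probe1 = t1, t_probe2 = t2)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(domain = domain, ez_width = ez_width,
                              probes = probes, edge_length = edge_length,
                              probe_separation = dx)
  class(out) <- c("velocity_sweep", "data.frame")
  out
}

#' Calibrate gamma_11 against a target spread velocity
#'
#' Monotone linear interpolation of a [spread_velocity_sweep()]: returns
#' the coupling gain whose interpolated spread velocity equals the target.
#' The sweep must bracket the target.
#'
#' @param sweep a [spread_velocity_sweep()] result.
#' @param target_velocity desired spread velocity (mm/s).
#' @return the interpolated gamma_11.
#' @export
calibrate_gamma11 <- function(sweep, target_velocity) {
  ok <- is.finite(sweep$velocity)
  if (sum(ok) < 2) stop("sweep has fewer than two finite velocities")
  v <- sweep$velocity[ok]; g <- sweep$gamma_11[ok]
  o <- order(g); v <- v[o]; g <- g[o]
  if (any(diff(v) <= 0))
    warning("sweep velocities are not strictly increasing in gamma_11")
  if (target_velocity < min(v) || target_velocity > max(v))
    stop("target velocity ", signif(target_velocity, 4),
         " mm/s outside the sweep range [", signif(min(v), 4), ", ",
         signif(max(v), 4), "]; extend the sweep")
  approx(v, g, xout = target_velocity, ties = "ordered")$y
}

#' Ictal propagation velocity from onset times
#'
#' The data-side counterpart of the model spread velocity: the geodesic
#' distance between the surface vertices closest to the first and last
#' electrode contacts, divided by the onset-time difference of the first
#' and last channels.
#'
#' @param onsets a [detect_onsets()] result whose first and last channels
#'   are detected.
#' @param surface,electrode geometry.
#' @return velocity in mm/s.
#' @export
estimate_data_velocity <- function(onsets, surface, electrode) {
  n <- nrow(onsets)
  if (!onsets$detected[1] || !onsets$detected[n])
    stop("first or last channel has no detected onset")
  dt <- onsets$onset_s[n] - onsets$onset_s[1]
  if (dt <= 0)
    stop("non-positive onset difference between first and last channel (",
         signif(dt, 3), " s); propagation direction inconsistent")
  v1 <- nearest_vertex(surface, electrode$positions[1, ])
  v2 <- nearest_vertex(surface, electrode$positions[nrow(electrode$positions), ])
  gd <- geodesic_distances(surface, v1)$distances[v2]
  if (!is.finite(gd)) stop("contacts lie on disconnected mesh components")
  gd / dt
}
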
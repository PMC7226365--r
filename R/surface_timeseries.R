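# ---------------------------------------------------------------------------
# Per-frame scalar series: Shrake-Rupley SASA, hydrogen-bond counts, and
# Savitzky-Golay smoothing.
# ---------------------------------------------------------------------------

#' Construct a per-frame time series
#'
#' @param values Numeric vector, one value per frame.
#' @param time_per_frame ns between frames.
#' @param label Quantity label.
#' @param units Unit string recorded with the series (e.g. "A^2", "count").
#' @param smoothed Logical; set by [savgol_smooth()].
#' @param window,degree Smoothing parameters when `smoothed` is TRUE.
#' @return Object of class `"time_series"`.
#' @export
time_series <- function(values, time_per_frame, label = "", units = "",
                        smoothed = FALSE, window = NA_integer_,
                        degree = NA_integer_) {
  structure(list(values = as.numeric(values),
                 time_per_frame = time_per_frame,
                 label = label, units = units, smoothed = isTRUE(smoothed),
                 window = window, degree = degree),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s [%s], %d frames%s\n", x$label, x$units,
              length(x$values),
              if (x$smoothed) sprintf(" (SG-smoothed %d/%d)", x$window,
                                      x$degree) else ""))
  invisible(x)
}

#' Time axis of a series (ns)
#' @param ts A [time_series()].
#' @return Numeric vector of frame times, frame 1 at t = 0.
#' @export
series_time <- function(ts) (seq_along(ts$values) - 1) * ts$time_per_frame

#' Convert a time series to a data.frame
#' @param x A time series. @param ... Unused.
#' @return data.frame with `frame`, `time_ns`, `value` columns.
#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(frame = seq_along(x$values), time_ns = series_time(x),
             value = x$values)
}

# Deterministic quasi-uniform unit sphere points (golden-spiral /
# Fibonacci lattice).  Same point set every call at a given n.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley SASA of a selection in one frame
#'
#' For each selected atom, `n_points` golden-spiral test points are placed
#' on the sphere of radius `r_a + probe`; a point is exposed iff it lies
#' strictly outside every other context atom's expanded sphere.  The atom
#' contribution is `(exposed / n_points) * 4 pi (r_a + probe)^2`.
#'
#' @param frame n x 3 coordinate matrix.
#' @param sel_idx Atom indices whose area is summed.
#' @param context_idx Atom indices that occlude (must contain `sel_idx`).
#' @param radii Per-atom radii for the full topology (A).
#' @param probe Probe radius, A (water: 1.4).
#' @param n_points Test points per atom (>= 100).
#' @return SASA in A^2 (sum over the selection).
#' @export
sasa_frame <- function(frame, sel_idx, context_idx, radii, probe = 1.4,
                       n_points = 960) {
  if (probe <= 0) stop("probe radius must be positive")
  if (n_points < 100) stop("n_points must be >= 100")
  if (!length(sel_idx)) {
    warning("empty SASA selection; returning 0")
    return(0)
  }
  if (!all(sel_idx %in% context_idx)) {
    stop("selection must be a subset of the context")
  }
  sphere <- golden_spiral_points(n_points)
  total <- 0
  cx <- frame[context_idx, , drop = FALSE]
  cr <- radii[context_idx] + probe
  for (a in sel_idx) {
    ra <- radii[a] + probe
    pts <- sphere * ra
    pts <- sweep(pts, 2, frame[a, ], "+")
    exposed <- rep(TRUE, n_points)
    # neighbours whose expanded spheres can reach this atom's shell
    d2 <- rowSums(sweep(cx, 2, frame[a, ])^2)
    nb <- which(d2 < (ra + cr)^2 & context_idx != a)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(pts[exposed, , drop = FALSE], 2, cx[j, ])^2)
      exposed[exposed] <- dj2 > cr[j]^2      # strict: boundary is buried
    }
    total <- total + sum(exposed) / n_points * 4 * pi * ra^2
  }
  total
}

#' SASA time series over a trajectory
#'
#' @param traj A trajectory.
#' @param sel Selection whose area is reported.
#' @param context Occluding selection (default: all atoms); must contain
#'   `sel`.
#' @param probe,n_points See [sasa_frame()].
#' @return A [time_series()] in A^2.
#' @export
sasa_series <- function(traj, sel, context = selection(), probe = 1.4,
                        n_points = 960) {
  si <- resolve_selection(sel, traj$topology)
  ci <- resolve_selection(context, traj$topology)
  radii <- traj$topology$atoms$vdw_radius
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    sasa_frame(get_frame(traj, t), si, ci, radii, probe, n_points)
  }, numeric(1))
  time_series(vals, traj$time_per_frame, label = "SASA", units = "A^2")
}

#' Savitzky-Golay smoothing of a per-frame series
#'
#' Least-squares local polynomial fit on a sliding window; interior points
#' get the exact central SG coefficients, edges are handled by mirror
#' padding so the series length is preserved.  The defaults (window 51,
#' degree 3) are the usual choice for 2500-frame trajectories.
#'
#' @param series A [time_series()] or bare numeric vector.
#' @param window Odd window length in frames, <= series length.
#' @param degree Polynomial degree, < window.
#' @return Smoothed series of the same class and length.
#' @export
savgol_smooth <- function(series, window = 51, degree = 3) {
  vals <- if (inherits(series, "time_series")) series$values else
    as.numeric(series)
  n <- length(vals)
  if (window %% 2 != 1) stop("window must be odd")
  if (window > n) stop("window exceeds series length")
  if (degree >= window) stop("degree must be smaller than window")
  h <- (window - 1) / 2
  # mirror padding: reflect about the first/last point (excluding it)
  padded <- c(vals[(h + 1):2], vals, vals[(n - 1):(n - h)])
  coef <- signal::sgolay(p = degree, n = window)[h + 1, ]
  sm <- stats::filter(padded, rev(coef), sides = 2)
  sm <- as.numeric(sm)[(h + 1):(h + n)]
  if (inherits(series, "time_series")) {
    time_series(sm, series$time_per_frame, label = series$label,
                units = series$units, smoothed = TRUE, window = window,
                degree = degree)
  } else {
    sm
  }
}

#' Hydrogen-bond count time series
#'
#' Counts donor/acceptor pairs per frame using the geometric criterion
#' D...A <= `d_cut` and, when an explicit hydrogen is attached to the
#' donor, D-H...A angle >= `angle_cut`.  Donors with no attached hydrogen
#' are scored on distance alone and the series is flagged
#' `distance_only_donors`.
#'
#' @param traj A trajectory.
#' @param donors Selection of donor heavy atoms.
#' @param acceptors Selection of acceptor heavy atoms.
#' @param d_cut Donor-acceptor distance cutoff, A.
#' @param angle_cut D-H...A angle cutoff, degrees.
#' @return A [time_series()] of counts; attribute `distance_only_donors`
#'   gives the number of donors scored without an explicit H.
#' @export
hbond_count_series <- function(traj, donors, acceptors, d_cut = 3.5,
                               angle_cut = 140) {
  top <- traj$topology
  di <- resolve_selection(donors, top)
  ai <- resolve_selection(acceptors, top)
  a <- top$atoms
  hyd <- which(is_hydrogen(a$element, a$atom_name))
  # attach hydrogens to donors: same residue and within 1.25 A in frame 1
  f1 <- get_frame(traj, 1)
  donor_h <- lapply(di, function(d) {
    same_res <- hyd[a$chain_id[hyd] == a$chain_id[d] &
                    a$residue_number[hyd] == a$residue_number[d]]
    if (!length(same_res)) return(integer(0))
    dd <- sqrt(rowSums(sweep(f1[same_res, , drop = FALSE], 2, f1[d, ])^2))
    same_res[dd <= 1.25]
  })
  n_no_h <- sum(vapply(donor_h, length, integer(1)) == 0)
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    fr <- get_frame(traj, t)
    cnt <- 0L
    for (k in seq_along(di)) {
      d <- di[k]
      for (acc in ai) {
        if (acc == d) next
        rda <- sqrt(sum((fr[acc, ] - fr[d, ])^2))
        if (rda > d_cut) next
        hs <- donor_h[[k]]
        if (!length(hs)) {
          cnt <- cnt + 1L
        } else {
          for (hh in hs) {
            v1 <- fr[d, ] - fr[hh, ]
            v2 <- fr[acc, ] - fr[hh, ]
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                       (vnorm(v1) * vnorm(v2))))) * 180 / pi
            if (ang >= angle_cut) {
              cnt <- cnt + 1L
              break
            }
          }
        }
      }
    }
    as.numeric(cnt)
  }, numeric(1))
  out <- time_series(vals, traj$time_per_frame, label = "H-bonds",
                     units = "count")
  attr(out, "distance_only_donors") <- n_no_h
  out
}

#' Write a raw/smoothed series pair as CSV
#'
#' @param raw Raw [time_series()].
#' @param smoothed Optional smoothed companion (same length).
#' @param path Output CSV.
#' @return Invisibly, `path`.
#' @export
write_series_csv <- function(raw, path, smoothed = NULL) {
  df <- as.data.frame(raw)
  names(df)[3] <- sprintf("value_%s", gsub("[^A-Za-z0-9]", "", raw$units))
  if (!is.null(smoothed)) df$smoothed_value <- smoothed$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
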
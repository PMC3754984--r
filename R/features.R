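# Multi-parameter signal extraction from full SPR angular spectra: the
# main SPR peak angular position and minimum intensity, the TIR angular
# position and its intensity, and waveguide nodes.

# cached central Savitzky-Golay smoothing kernels, keyed by "n:p"
.sg_cache <- new.env(parent = emptyenv())

.sg_kernel <- function(np, p = 2) {
  key <- paste(np, p, sep = ":")
  k <- .sg_cache[[key]]
  if (is.null(k)) {
    k <- signal::sgolay(p = p, n = np)[(np + 1L) / 2L, ]
    .sg_cache[[key]] <- k
  }
  k
}

# Savitzky-Golay smoothing (order-2 local polynomial) with window given
# in degrees; ends are left unsmoothed.
.sg_smooth <- function(y, step, window_deg = 0.25, order = 2) {
  np <- max(order + 3L, round(window_deg / step))
  if (np %% 2L == 0L) np <- np + 1L
  if (np >= length(y)) return(y)
  sm <- stats::filter(y, .sg_kernel(np, order), sides = 2)
  sm <- as.numeric(sm)
  bad <- is.na(sm)
  sm[bad] <- y[bad]
  sm
}

#' Locate the main SPR reflectance minimum
#'
#' Finds the global reflectance minimum of a spectrum inside a search
#' window and refines it below grid resolution with a local quadratic
#' (parabolic) fit around the grid minimum.  The default window is the
#' upper half of the scan range, where the main SPR dip of a
#' Kretschmann sensor lies; waveguide nodes near the TIR edge are
#' thereby excluded from the search.
#'
#' The refinement fits a parabola by least squares to all samples
#' within `fit_halfwidth` degrees of the grid minimum (at least the
#' three bracketing points, which reduces to classic three-point
#' parabolic interpolation).  The wider fit makes the vertex estimate
#' robust to intensity noise on instrument-resolution grids.
#'
#' @param spectrum An [angular_spectrum()].
#' @param window Numeric length-2 vector `c(lo, hi)` in degrees, or
#'   `NULL` for the upper half of the scan.
#' @param fit_halfwidth Half-width in degrees of the quadratic
#'   refinement window (default 0.25).
#' @return A list with `angle` (degrees), `intensity` (reflectance at
#'   the refined vertex) and `flags` (character vector; possible values
#'   `"peak-at-window-edge"` and `"no-peak"`).  When two grid minima
#'   tie, the lower angle wins.
#' @export
find_spr_minimum <- function(spectrum, window = NULL, fit_halfwidth = 0.25) {
  stopifnot(inherits(spectrum, "angular_spectrum"))
  ang <- spectrum$angles
  if (is.null(window)) window <- c((min(ang) + max(ang)) / 2, max(ang))
  stopifnot(is.numeric(window), length(window) == 2L)
  if (window[2L] <= window[1L])
    stop("empty search window", call. = FALSE)
  sel <- which(ang >= window[1L] & ang <= window[2L])
  if (length(sel) < 3L)
    stop("search window must contain at least 3 samples", call. = FALSE)
  a <- ang[sel]
  r <- spectrum$reflectance[sel]
  flags <- character(0)
  i <- which.min(r)                       # ties: which.min takes the first
  if (i == 1L || i == length(r)) {
    flags <- c(flags, "peak-at-window-edge")
    if (all(diff(r) <= 0) || all(diff(r) >= 0)) flags <- c(flags, "no-peak")
    return(list(angle = a[i], intensity = r[i], flags = flags))
  }
  w <- which(abs(a - a[i]) <= fit_halfwidth)
  if (length(w) < 3L) w <- (i - 1L):(i + 1L)
  x <- a[w] - a[i]
  fit <- stats::lm.fit(cbind(1, x, x^2), r[w])
  b <- fit$coefficients
  if (!is.finite(b[3L]) || b[3L] <= 0) {   # no curvature: keep grid minimum
    return(list(angle = a[i], intensity = r[i], flags = c(flags, "no-peak")))
  }
  xv <- -b[2L] / (2 * b[3L])
  # keep the vertex inside the fitted neighbourhood
  xv <- min(max(xv, min(x)), max(x))
  list(angle = a[i] + xv,
       intensity = unname(b[1L] + b[2L] * xv + b[3L] * xv^2),
       flags = flags)
}

#' Locate the total-internal-reflection (TIR) angular position
#'
#' The TIR angular position is operationalized as the angle of maximum
#' positive slope of the smoothed reflectance in the region below the
#' main SPR peak.  Smoothing is an order-2 Savitzky-Golay filter with a
#' 0.25 degree window; it is applied only inside this function, so all
#' other feature extraction sees the raw samples.  If no rising edge is
#' found (flat spectrum) and prism/bulk indices are supplied, the
#' analytic critical angle `asin(n_bulk / n_prism)` is returned instead
#' (plus the spectrum's instrument angle offset, when present).
#'
#' @param spectrum An [angular_spectrum()].
#' @param peak_angle Angle of the main SPR minimum in degrees; computed
#'   with [find_spr_minimum()] when `NULL`.
#' @param n_prism,n_bulk Optional refractive indices enabling the
#'   analytic fallback.
#' @param smooth_window Savitzky-Golay window in degrees.
#' @param peak_margin Degrees below `peak_angle` excluded from the
#'   slope search, keeping the dip's own rising flank out (default 1).
#' @return A list with `angle`, `intensity` (raw reflectance linearly
#'   interpolated at the TIR angle) and `flags` (possibly
#'   `"no-tir-found"` or `"tir-analytic-fallback"`).
#' @export
find_tir_angle <- function(spectrum, peak_angle = NULL,
                           n_prism = NULL, n_bulk = NULL,
                           smooth_window = 0.25, peak_margin = 1) {
  stopifnot(inherits(spectrum, "angular_spectrum"))
  ang <- spectrum$angles
  if (is.null(peak_angle)) peak_angle <- find_spr_minimum(spectrum)$angle
  step <- stats::median(diff(ang))
  sm <- .sg_smooth(spectrum$reflectance, step, smooth_window)
  slope <- diff(sm) / diff(ang)
  mid <- (ang[-1L] + ang[-length(ang)]) / 2
  sel <- which(mid < peak_angle - peak_margin)
  fallback <- function(flag) {
    if (!is.null(n_prism) && !is.null(n_bulk)) {
      off <- attr(spectrum, "angle_offset")
      ca <- critical_angle(n_prism, n_bulk) + if (is.null(off)) 0 else off
      ca <- min(max(ca, min(ang)), max(ang))
      list(angle = ca, intensity = intensity_at_angle(spectrum, ca),
           flags = c(flag, "tir-analytic-fallback"))
    } else {
      list(angle = NA_real_, intensity = NA_real_,
           flags = c(flag, "no-tir-found"))
    }
  }
  if (length(sel) < 2L) return(fallback("tir-region-outside-scan"))
  smax <- max(slope[sel])
  # require a genuine rising edge: more than numerical flatness
  if (!is.finite(smax) || smax <= 1e-6) return(fallback("tir-flat-spectrum"))
  j <- sel[which.max(slope[sel])]
  a <- mid[j]
  # sub-grid refinement: parabolic vertex of the slope maximum, so the
  # TIR angle varies continuously rather than in grid quanta
  if (j > 1L && j < length(slope)) {
    y <- slope[(j - 1L):(j + 1L)]
    den <- y[1L] - 2 * y[2L] + y[3L]
    if (is.finite(den) && den < 0) {
      sh <- (y[1L] - y[3L]) / (2 * den)
      a <- a + min(max(sh, -1), 1) * step
      a <- min(max(a, min(ang)), max(ang))
    }
  }
  list(angle = a, intensity = intensity_at_angle(spectrum, a),
       flags = character(0))
}

#' Interpolate reflectance at an arbitrary angle
#'
#' Linear interpolation between the two bracketing grid samples.
#'
#' @param spectrum An [angular_spectrum()].
#' @param angle Query angle in degrees; must lie within the sampled
#'   range.
#' @return Interpolated reflectance value(s).
#' @export
intensity_at_angle <- function(spectrum, angle) {
  stopifnot(inherits(spectrum, "angular_spectrum"))
  if (any(angle < min(spectrum$angles) | angle > max(spectrum$angles)))
    stop("angle outside the sampled range", call. = FALSE)
  stats::approx(spectrum$angles, spectrum$reflectance, xout = angle,
                method = "linear", ties = "ordered")$y
}

#' Detect waveguide nodes near the TIR region
#'
#' Thick, weakly guiding sample layers (thickness approaching the
#' wavelength) support waveguide modes that appear as additional
#' reflectance dips in the vicinity of the TIR angle.  This finds local
#' minima with prominence above a threshold in the window from
#' `tir_angle - below` up to `peak_angle - margin`, so nodes sitting on
#' or just below the TIR rising edge are included while the main SPR
#' dip itself is excluded.
#'
#' @param spectrum An [angular_spectrum()].
#' @param tir_angle,peak_angle TIR and main-peak angles in degrees
#'   (`tir_angle < peak_angle`).
#' @param prominence Minimum prominence (reflectance units) for a dip
#'   to count as a node (default 0.005).
#' @param below Degrees below `tir_angle` included in the search; the
#'   default `Inf` searches down to the scan start, so an emerging
#'   node's full left-side context enters its prominence.
#' @param margin Degrees below `peak_angle` excluded (default 1).
#' @return A data frame with columns `angle` and `reflectance`, ordered
#'   by angle; zero rows when no nodes are present.
#' @export
detect_waveguide_nodes <- function(spectrum, tir_angle, peak_angle,
                                   prominence = 0.005, below = Inf,
                                   margin = 1) {
  stopifnot(inherits(spectrum, "angular_spectrum"))
  if (!is.finite(tir_angle) || !is.finite(peak_angle) ||
      tir_angle >= peak_angle)
    stop("tir_angle must lie below peak_angle", call. = FALSE)
  ang <- spectrum$angles
  sel <- which(ang > tir_angle - below & ang < peak_angle - margin)
  empty <- data.frame(angle = numeric(0), reflectance = numeric(0))
  if (length(sel) < 3L) return(empty)
  r <- spectrum$reflectance[sel]
  dm <- diff(sign(diff(r)))
  mi <- which(dm > 0) + 1L
  if (!length(mi)) return(empty)
  # prominence against the running maxima on either side
  lmax <- cummax(r)
  rmax <- rev(cummax(rev(r)))
  keep <- pmin(lmax[mi], rmax[mi]) - r[mi] >= prominence
  mi <- mi[keep]
  data.frame(angle = ang[sel][mi], reflectance = r[mi])
}

#' Extract the full multi-parameter feature set from one spectrum
#'
#' Combines [find_spr_minimum()], [find_tir_angle()] and
#' [detect_waveguide_nodes()] into the four-parameter signal set used
#' for living-cell sensing, plus the list of waveguide nodes.
#'
#' @param spectrum An [angular_spectrum()].
#' @param window Search window for the SPR minimum (see
#'   [find_spr_minimum()]).
#' @param n_prism,n_bulk Optional indices for the analytic TIR
#'   fallback.
#' @param node_prominence Prominence threshold for waveguide nodes.
#' @param tir_at Optional fixed angle (degrees) at which the TIR
#'   intensity is read instead of the tracked TIR angle.
#' @return An object of class `"spr_features"`: a list with
#'   `peak_angle`, `peak_intensity`, `tir_angle`, `tir_intensity`,
#'   `waveguide_nodes` (data frame) and `flags`.
#' @export
spectrum_features <- function(spectrum, window = NULL,
                              n_prism = NULL, n_bulk = NULL,
                              node_prominence = 0.005, tir_at = NULL) {
  pk <- find_spr_minimum(spectrum, window = window)
  ti <- find_tir_angle(spectrum, peak_angle = pk$angle,
                       n_prism = n_prism, n_bulk = n_bulk)
  tir_intensity <- ti$intensity
  if (!is.null(tir_at)) tir_intensity <- intensity_at_angle(spectrum, tir_at)
  nodes <- if (is.finite(ti$angle) && ti$angle < pk$angle) {
    detect_waveguide_nodes(spectrum, ti$angle, pk$angle,
                           prominence = node_prominence)
  } else {
    data.frame(angle = numeric(0), reflectance = numeric(0))
  }
  structure(list(peak_angle = pk$angle, peak_intensity = pk$intensity,
                 tir_angle = ti$angle, tir_intensity = tir_intensity,
                 waveguide_nodes = nodes,
                 flags = c(pk$flags, ti$flags)),
            class = "spr_features")
}

#' @export
print.spr_features <- function(x, ...) {
  cat(sprintf(paste0("<spr_features> peak %.4f deg (R = %.4f), ",
                     "TIR %.4f deg (R = %.4f), %d node(s)%s\n"),
              x$peak_angle, x$peak_intensity, x$tir_angle, x$tir_intensity,
              nrow(x$waveguide_nodes),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.spr_features <- function(x, ...) {
  data.frame(peak_angle_deg = x$peak_angle,
             peak_intensity = x$peak_intensity,
             tir_angle_deg = x$tir_angle,
             tir_intensity = x$tir_intensity,
             n_nodes = nrow(x$waveguide_nodes),
             flags = paste(x$flags, collapse = ";"))
}
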
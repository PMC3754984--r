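# Sensogram construction, baseline-referenced delta traces,
# angle-vs-intensity trajectory summaries and mechanistic response
# classification.

#' Build a sensogram from a feature table
#'
#' A sensogram is the time series of the multi-parameter SPR feature
#' set, together with the injection windows of the stimulation
#' protocol.
#'
#' @param features Data frame with columns `time_s`, `peak_angle_deg`,
#'   `peak_intensity`, `tir_angle_deg`, `tir_intensity` and optionally
#'   `n_nodes`, `flags`; times must be strictly ascending.
#' @param injections Data frame with columns `start_s`, `end_s`,
#'   `label`, `concentration` (one row per injection), or `NULL`.
#' @return An object of class `"spr_sensogram"`.
#' @export
sensogram <- function(features, injections = NULL) {
  need <- c("time_s", "peak_angle_deg", "peak_intensity",
            "tir_angle_deg", "tir_intensity")
  if (!is.data.frame(features) || !all(need %in% names(features)))
    stop("features must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(features) < 2L || any(diff(features$time_s) <= 0))
    stop("timestamps must be strictly ascending (>= 2 rows)", call. = FALSE)
  if (!is.null(injections)) {
    ni <- c("start_s", "end_s")
    if (!is.data.frame(injections) || !all(ni %in% names(injections)))
      stop("injections must contain start_s and end_s", call. = FALSE)
    rng <- range(features$time_s)
    if (any(injections$start_s < rng[1L] | injections$end_s > rng[2L]) ||
        any(injections$end_s <= injections$start_s))
      stop("every injection window must lie within the recorded time range",
           call. = FALSE)
  }
  structure(list(features = features, injections = injections),
            class = "spr_sensogram")
}

#' @export
print.spr_sensogram <- function(x, ...) {
  cat(sprintf("<spr_sensogram> %d scans, %.6g-%.6g s, %d injection(s)\n",
              nrow(x$features), min(x$features$time_s),
              max(x$features$time_s),
              if (is.null(x$injections)) 0L else nrow(x$injections)))
  invisible(x)
}

#' Extract features from a time series of angular spectra
#'
#' Applies [spectrum_features()] to every spectrum and assembles the
#' sensogram.  Spectra must carry ascending timestamps.
#'
#' @param spectra List of [angular_spectrum()] objects with timestamps.
#' @param injections Optional injection table (see [sensogram()]).
#' @param tir_mode `"tracked"` reads the TIR intensity at the per-scan
#'   TIR angle; `"fixed"` reads it at `tir_at` (defaulting to the first
#'   scan's TIR angle), emulating a fixed-angle intensity trace.
#' @param tir_at Fixed angle in degrees for `tir_mode = "fixed"`.
#' @param ... Further arguments passed to [spectrum_features()].
#' @return An `"spr_sensogram"` object.
#' @export
features_over_time <- function(spectra, injections = NULL,
                               tir_mode = c("tracked", "fixed"),
                               tir_at = NULL, ...) {
  tir_mode <- match.arg(tir_mode)
  if (!is.list(spectra) || length(spectra) < 2L)
    stop("need at least two spectra", call. = FALSE)
  ts <- vapply(spectra, function(s) {
    if (is.null(s$timestamp)) NA_real_ else s$timestamp
  }, numeric(1))
  if (anyNA(ts)) stop("all spectra must carry timestamps", call. = FALSE)
  if (any(diff(ts) <= 0))
    stop("spectrum timestamps must be strictly ascending", call. = FALSE)
  if (tir_mode == "fixed" && is.null(tir_at)) {
    tir_at <- spectrum_features(spectra[[1L]], ...)$tir_angle
  }
  n <- length(spectra)
  pa <- pi_ <- ta <- ti <- numeric(n)
  nn <- integer(n)
  fl <- character(n)
  for (i in seq_len(n)) {
    f <- spectrum_features(spectra[[i]],
                           tir_at = if (tir_mode == "fixed") tir_at, ...)
    pa[i] <- f$peak_angle; pi_[i] <- f$peak_intensity
    ta[i] <- f$tir_angle; ti[i] <- f$tir_intensity
    nn[i] <- nrow(f$waveguide_nodes)
    fl[i] <- paste(f$flags, collapse = ";")
  }
  feats <- data.frame(time_s = ts, peak_angle_deg = pa,
                      peak_intensity = pi_, tir_angle_deg = ta,
                      tir_intensity = ti, n_nodes = nn, flags = fl)
  sensogram(feats, injections)
}

.delta_traces <- c("d_peak_angle", "d_peak_intensity",
                   "d_tir_angle", "d_tir_intensity")

#' Baseline-referenced feature changes over time
#'
#' Subtracts, from each feature trace, the median of its pre-injection
#' baseline window, yielding the delta traces that stimulation
#' experiments are read from.  A robust noise scale (1.4826 x MAD of
#' the running-median-smoothed pre-injection trace) is attached per
#' trace; classification thresholds default to three times this scale.
#'
#' @param sg An `"spr_sensogram"` with at least one injection.
#' @param injection_index Which injection to reference against.
#' @param pre_window Length in seconds of the pre-injection baseline
#'   window (`NULL` = everything before the injection).  At least 30 s
#'   of pre-injection data are required.
#' @param smooth_k Odd window length (samples) of the running-median
#'   smoother used for the noise estimate and downstream extrema.
#' @return An object of class `"spr_deltas"`: a data frame with
#'   `time_s` and the four delta traces, plus attributes `baseline`,
#'   `noise`, `injection` and `smooth_k`.
#' @export
baseline_deltas <- function(sg, injection_index = 1L, pre_window = NULL,
                            smooth_k = 5L) {
  stopifnot(inherits(sg, "spr_sensogram"))
  if (is.null(sg$injections) || nrow(sg$injections) < injection_index)
    stop("sensogram has no injection ", injection_index, call. = FALSE)
  inj <- sg$injections[injection_index, ]
  f <- sg$features
  pre <- f$time_s < inj$start_s
  if (!is.null(pre_window)) pre <- pre & f$time_s >= inj$start_s - pre_window
  if (sum(pre) < 2L || diff(range(f$time_s[pre])) < 30)
    stop("need at least 30 s of pre-injection baseline", call. = FALSE)
  src <- c("peak_angle_deg", "peak_intensity", "tir_angle_deg",
           "tir_intensity")
  baseline <- vapply(src, function(v) stats::median(f[[v]][pre]), numeric(1))
  names(baseline) <- .delta_traces
  out <- data.frame(time_s = f$time_s)
  noise <- numeric(length(src))
  for (i in seq_along(src)) {
    d <- f[[src[i]]] - baseline[i]
    out[[.delta_traces[i]]] <- d
    smd <- .runmed(d[pre], smooth_k)
    noise[i] <- 1.4826 * stats::mad(smd, constant = 1)
  }
  names(noise) <- .delta_traces
  structure(out, baseline = baseline, noise = noise,
            injection = inj, smooth_k = smooth_k, class = c("spr_deltas",
                                                            "data.frame"))
}

.runmed <- function(x, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (length(x) < k) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# signed value of largest magnitude
.signed_extremum <- function(x) x[which.max(abs(x))]

#' Summarize the angle-vs-intensity trajectory of one stimulation
#'
#' Condenses the delta traces of one injection/rinse cycle into the
#' quantities the response classification runs on: the signed extrema
#' of the peak-angle and peak-intensity changes, the slope of the
#' intensity-vs-angle trajectory (total least squares on the
#' stimulation-window points), the fraction of the angular excursion
#' recovered after rinsing, and whether the angular change reversed
#' sign during stimulation.
#'
#' Traces are smoothed with a short running median before extrema are
#' taken, so single-scan outliers do not masquerade as responses.  The
#' end-of-rinse level is the median of the final `tail_window` seconds.
#'
#' @param deltas An `"spr_deltas"` object from [baseline_deltas()].
#' @param lag Flow-cell transit lag in seconds added to the injection
#'   window to form the stimulation window (default 60).
#' @param stimulation_only If `TRUE` (default) the trajectory slope
#'   uses stimulation-window points only; otherwise the full
#'   injection-plus-rinse cycle.
#' @param tail_window Seconds at the end of the record that define the
#'   post-rinse level (default 60).
#' @return An object of class `"spr_trajectory"`: list with
#'   `delta_angle_extremum`, `delta_intensity_extremum`, `slope`,
#'   `recovery_fraction`, `reversal`, `flags` and attribute `noise`.
#' @export
trajectory <- function(deltas, lag = 60, stimulation_only = TRUE,
                       tail_window = 60) {
  stopifnot(inherits(deltas, "spr_deltas"))
  inj <- attr(deltas, "injection")
  k <- attr(deltas, "smooth_k")
  noise <- attr(deltas, "noise")
  t <- deltas$time_s
  stim <- t >= inj$start_s & t <= inj$end_s + lag
  if (!any(stim)) stop("stimulation window contains no samples",
                       call. = FALSE)
  da <- .runmed(deltas$d_peak_angle, k)
  di <- .runmed(deltas$d_peak_intensity, k)
  flags <- character(0)
  if (all(abs(da[stim]) < .Machine$double.eps^0.5) &&
      all(abs(di[stim]) < .Machine$double.eps^0.5)) {
    return(structure(list(delta_angle_extremum = 0,
                          delta_intensity_extremum = 0, slope = 0,
                          recovery_fraction = 1, reversal = FALSE,
                          flags = "degenerate-window"),
                     noise = noise, class = "spr_trajectory"))
  }
  ext_a <- .signed_extremum(da[stim])
  # intensity change read coherently at the time of the angular
  # extremum: the trajectory couples the two traces point-by-point, so
  # this is the intensity coordinate of the trajectory's far end (and
  # is far less noise-prone than an independent extremum search)
  ext_i <- di[stim][which.max(abs(da[stim]))]
  sel <- if (stimulation_only) stim else t >= inj$start_s
  slope <- .tls_slope(deltas$d_peak_angle[sel], deltas$d_peak_intensity[sel])
  tail_sel <- t >= max(t) - tail_window
  end_a <- stats::median(da[tail_sel])
  recovery <- if (abs(ext_a) > 0) max(0, 1 - abs(end_a) / abs(ext_a)) else 1
  thr_a <- 3 * noise[["d_peak_angle"]]
  reversal <- min(da[stim]) < -thr_a && max(da[stim]) > thr_a
  structure(list(delta_angle_extremum = ext_a,
                 delta_intensity_extremum = ext_i,
                 slope = slope,
                 recovery_fraction = recovery,
                 reversal = reversal,
                 flags = flags),
            noise = noise, class = "spr_trajectory")
}

# total-least-squares slope of y against x: orientation of the first
# principal axis of the centred point cloud
.tls_slope <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  if (sxx == 0 && syy == 0) return(0)
  if (sxy == 0) return(if (sxx >= syy) 0 else Inf)
  # eigenvector of the 2x2 scatter matrix for the larger eigenvalue
  lam <- (sxx + syy + sqrt((sxx - syy)^2 + 4 * sxy^2)) / 2
  sxy / (lam - syy)
}

#' @export
print.spr_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<spr_trajectory> d_angle %+.4g deg, d_intensity ",
                     "%+.4g, slope %.4g /deg, recovery %.3g, reversal %s%s\n"),
              x$delta_angle_extremum, x$delta_intensity_extremum, x$slope,
              x$recovery_fraction, x$reversal,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Decision thresholds for response classification
#'
#' @param angle,intensity Noise thresholds (degrees / reflectance
#'   units) below which a change does not count as a response; `NULL`
#'   defaults to three times the robust baseline noise carried by the
#'   trajectory summary, but never below the detection floors.
#' @param angle_floor,intensity_floor Detection floors applied when the
#'   thresholds are derived from the baseline noise (defaults 0.01 deg
#'   and 0.001 reflectance units, the practical resolution of the
#'   simulated instrument): a perfectly quiet baseline must not turn
#'   arbitrarily small residual couplings into "responses".
#' @param recovery Minimum recovery fraction for a "full return to
#'   baseline" (default 0.8).
#' @param slope_horizontal Largest trajectory slope magnitude
#'   (reflectance units per degree) still considered horizontal
#'   (default 0.02); an intensity excursion below
#'   `slope_horizontal * |delta-angle extremum|` counts as "no
#'   intensity change" relative to the angular response.
#' @return A list of thresholds for [classify_response()].
#' @export
response_thresholds <- function(angle = NULL, intensity = NULL,
                                angle_floor = 0.01,
                                intensity_floor = 0.001,
                                recovery = 0.8, slope_horizontal = 0.02) {
  list(angle = angle, intensity = intensity, angle_floor = angle_floor,
       intensity_floor = intensity_floor, recovery = recovery,
       slope_horizontal = slope_horizontal)
}

#' Classify a stimulation response into a mechanistic scenario
#'
#' Maps the trajectory summary onto the four mechanistic response
#' scenarios of living-cell SPR sensing:
#' \describe{
#'   \item{paracellular-like}{negative peak-angle change, essentially
#'     unchanged peak minimum intensity, full return to baseline after
#'     rinsing (slight cell contraction without intracellular mass
#'     redistribution).}
#'   \item{transcellular-like}{negative change in both peak angle and
#'     peak minimum intensity (contraction plus mass redistribution),
#'     typically with incomplete recovery as analyte is retained.}
#'   \item{accumulation-only}{positive peak-angle change with
#'     unchanged intensity (simple analyte accumulation, no
#'     morphological change).}
#'   \item{spreading}{positive change in both (accumulation with mass
#'     redistribution towards the sensor).}
#' }
#' Responses below the noise thresholds are `"no-response"`; patterns
#' that fit no scenario (e.g. opposite-sign extrema without a flagged
#' reversal) are `"no-response"` with an `"ambiguous"` flag.
#'
#' @param summary An `"spr_trajectory"` from [trajectory()].
#' @param thresholds A [response_thresholds()] list.
#' @return The scenario label (character), with attributes
#'   `thresholds` (values actually used) and `flags`.
#' @export
classify_response <- function(summary, thresholds = response_thresholds()) {
  stopifnot(inherits(summary, "spr_trajectory"))
  noise <- attr(summary, "noise")
  ext_a <- summary$delta_angle_extremum
  ext_i <- summary$delta_intensity_extremum
  thr_a <- thresholds$angle
  if (is.null(thr_a))
    thr_a <- max(thresholds$angle_floor, 3 * noise[["d_peak_angle"]])
  thr_i <- thresholds$intensity
  if (is.null(thr_i))
    thr_i <- max(thresholds$intensity_floor,
                 3 * noise[["d_peak_intensity"]],
                 thresholds$slope_horizontal * abs(ext_a))
  used <- list(angle = unname(thr_a), intensity = unname(thr_i),
               recovery = thresholds$recovery,
               slope_horizontal = thresholds$slope_horizontal)
  flags <- summary$flags
  label <- if (abs(ext_a) <= thr_a && abs(ext_i) <= thr_i) {
    "no-response"
  } else if (ext_a < 0) {
    if (abs(ext_i) <= thr_i &&
        summary$recovery_fraction >= thresholds$recovery) {
      "paracellular-like"
    } else if (ext_i < -thr_i) {
      "transcellular-like"
    } else {
      flags <- c(flags, "ambiguous")
      "no-response"
    }
  } else {
    if (abs(ext_i) <= thr_i) {
      "accumulation-only"
    } else if (ext_i > thr_i) {
      "spreading"
    } else {
      flags <- c(flags, "ambiguous")
      "no-response"
    }
  }
  structure(label, thresholds = used, flags = flags)
}

#' One-call classification of a sensogram
#'
#' Convenience wrapper: [baseline_deltas()] then [trajectory()] then
#' [classify_response()].
#'
#' @param sg An `"spr_sensogram"`.
#' @param injection_index Injection to analyse.
#' @param thresholds A [response_thresholds()] list.
#' @param ... Passed to [trajectory()].
#' @return The scenario label (see [classify_response()]), with the
#'   trajectory summary attached as attribute `summary`.
#' @export
classify_sensogram <- function(sg, injection_index = 1L,
                               thresholds = response_thresholds(), ...) {
  d <- baseline_deltas(sg, injection_index)
  s <- trajectory(d, ...)
  out <- classify_response(s, thresholds)
  attr(out, "summary") <- s
  out
}
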
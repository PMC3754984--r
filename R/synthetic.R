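# Synthetic drug-stimulation experiments: scenario-driven time courses
# of cell-model optical parameters, rendered through the optics engine
# into noisy instrument-style angular-scan series with ground-truth
# labels.

.scenarios <- c("paracellular", "transcellular", "accumulation-only",
                "spreading")

# per-scenario default excursions (index / extinction units).  The
# evanescent-field index amplitudes are sized so that noiseless
# peak-angle extrema fall in the 0.02-0.3 degree range of visible
# living-cell responses; sign patterns encode the mechanistic scenario.
.scenario_defaults <- function(scenario) {
  switch(scenario,
    "paracellular" = list(amp_n_ef = -8e-4, amp_k_ef = 0,
                          persistent_offset_n_ef = 0, dose_K = 0.05),
    "transcellular" = list(amp_n_ef = -2e-3, amp_k_ef = -1.2e-3,
                           persistent_offset_n_ef = 4e-4, dose_K = 1),
    "accumulation-only" = list(amp_n_ef = 1e-3, amp_k_ef = 0,
                               persistent_offset_n_ef = 0, dose_K = 1),
    "spreading" = list(amp_n_ef = 1.5e-3, amp_k_ef = 1e-3,
                       persistent_offset_n_ef = 0, dose_K = 1),
    stop("unknown scenario '", scenario, "'", call. = FALSE))
}

#' Specify a synthetic drug-stimulation scenario
#'
#' A scenario describes how the optical parameters of the cell model
#' move during an injection/rinse cycle: signed excursion amplitudes
#' for the evanescent-field and cell-body sections, first-order on/off
#' kinetics, an optional persistent post-rinse offset (analyte retained
#' in the monolayer) and an optional delayed reversal term (high-dose
#' behaviour).  Amplitudes are scaled by a saturating dose law
#' `concentration_scale / (concentration_scale + dose_K)`: the
#' paracellular scenario uses a small `dose_K` so its response is
#' already saturated at all tested concentrations, while the other
#' scenarios remain concentration dependent.
#'
#' Sign patterns are fixed per scenario: paracellular (`amp_n_ef < 0`,
#' no extinction change, no offset), transcellular (`amp_n_ef < 0`,
#' `amp_k_ef < 0`, positive offset), accumulation-only
#' (`amp_n_ef > 0`, no extinction change), spreading (`amp_n_ef > 0`,
#' `amp_k_ef > 0`).
#'
#' @param scenario One of `"paracellular"`, `"transcellular"`,
#'   `"accumulation-only"`, `"spreading"`.
#' @param concentration_scale Dimensionless dose multiplier (default
#'   1).
#' @param amp_n_ef,amp_k_ef,amp_n_cell,amp_k_cell Signed parameter
#'   excursions; `NULL` takes the scenario default.
#' @param persistent_offset_n_ef Post-rinse residual on `n_ef`; `NULL`
#'   takes the scenario default.
#' @param reversal_amp Amplitude (>= 0) of a delayed opposing
#'   first-order term during injection (high-dose transcellular runs).
#' @param tau_on,tau_off Kinetic time constants in seconds.
#' @param injection_start,injection_duration Injection window in
#'   seconds (duration must lie in the 6-10 min protocol envelope).
#' @param rinse_duration Rinse length in seconds after the injection
#'   (10-20 min envelope).
#' @param baseline Pre-injection baseline length in seconds.
#' @param scan_period Seconds between angular scans (default 4).
#' @param noise_sd Gaussian intensity noise, reflectance units
#'   (default 0.002).
#' @param seed Integer seed for the rendering noise.
#' @param model Baseline [cell_monolayer_model()].
#' @return A list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(scenario = .scenarios,
                          concentration_scale = 1,
                          amp_n_ef = NULL, amp_k_ef = NULL,
                          amp_n_cell = 0, amp_k_cell = 0,
                          persistent_offset_n_ef = NULL,
                          reversal_amp = 0,
                          tau_on = 60, tau_off = 120,
                          injection_start = 120,
                          injection_duration = 360,
                          rinse_duration = 600,
                          baseline = injection_start,
                          scan_period = 4, noise_sd = 0.002, seed = 1L,
                          model = cell_monolayer_model()) {
  scenario <- match.arg(scenario)
  def <- .scenario_defaults(scenario)
  if (is.null(amp_n_ef)) amp_n_ef <- def$amp_n_ef
  if (is.null(amp_k_ef)) amp_k_ef <- def$amp_k_ef
  if (is.null(persistent_offset_n_ef))
    persistent_offset_n_ef <- def$persistent_offset_n_ef
  stopifnot(tau_on > 0, tau_off > 0, noise_sd >= 0, scan_period > 0,
            reversal_amp >= 0, concentration_scale > 0)
  if (injection_duration < 6 * 60 || injection_duration > 10 * 60)
    stop("injection_duration must lie within the 6-10 min protocol envelope",
         call. = FALSE)
  if (rinse_duration < 10 * 60 || rinse_duration > 20 * 60)
    stop("rinse_duration must lie within the 10-20 min protocol envelope",
         call. = FALSE)
  ok <- switch(scenario,
    "paracellular" = amp_n_ef < 0 && amp_k_ef == 0 &&
      persistent_offset_n_ef == 0,
    "transcellular" = amp_n_ef < 0 && amp_k_ef < 0 &&
      persistent_offset_n_ef > 0,
    "accumulation-only" = amp_n_ef > 0 && amp_k_ef == 0,
    "spreading" = amp_n_ef > 0 && amp_k_ef > 0)
  if (!ok)
    stop("amplitude sign pattern inconsistent with scenario '", scenario,
         "'", call. = FALSE)
  structure(list(scenario = scenario,
                 concentration_scale = concentration_scale,
                 amp_n_ef = amp_n_ef, amp_k_ef = amp_k_ef,
                 amp_n_cell = amp_n_cell, amp_k_cell = amp_k_cell,
                 persistent_offset_n_ef = persistent_offset_n_ef,
                 reversal_amp = reversal_amp, dose_K = def$dose_K,
                 tau_on = tau_on, tau_off = tau_off,
                 injection_start = injection_start,
                 injection_duration = injection_duration,
                 rinse_duration = rinse_duration,
                 baseline = baseline,
                 scan_period = scan_period, noise_sd = noise_sd,
                 seed = as.integer(seed), model = model),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(paste0("<scenario_spec> %s, dose scale %.3g, seed %d\n",
                     "  amp n_ef %+.3g, k_ef %+.3g, offset %+.3g, ",
                     "reversal %.3g\n",
                     "  injection %g-%g s, rinse %g s, scan every %g s, ",
                     "noise sd %.3g\n"),
              x$scenario, x$concentration_scale, x$seed,
              x$amp_n_ef, x$amp_k_ef, x$persistent_offset_n_ef,
              x$reversal_amp, x$injection_start,
              x$injection_start + x$injection_duration, x$rinse_duration,
              x$scan_period, x$noise_sd))
  invisible(x)
}

# saturating dose law
.dose_gain <- function(spec) {
  spec$concentration_scale / (spec$concentration_scale + spec$dose_K)
}

# first-order excursion: rise towards amp during injection, relax
# towards offset during rinse; optional delayed opposing term
.kinetic_trace <- function(t, amp, offset, spec, reversal = 0) {
  t0 <- spec$injection_start
  t1 <- t0 + spec$injection_duration
  x <- numeric(length(t))
  inj <- t >= t0 & t <= t1
  x[inj] <- amp * (1 - exp(-(t[inj] - t0) / spec$tau_on))
  if (reversal > 0) {
    dly <- spec$injection_duration / 2
    late <- t >= t0 + dly & t <= t1
    x[late] <- x[late] +
      reversal * (1 - exp(-(t[late] - t0 - dly) / spec$tau_on))
  }
  post <- t > t1
  if (any(post)) {
    x_end <- amp * (1 - exp(-spec$injection_duration / spec$tau_on))
    if (reversal > 0)
      x_end <- x_end + reversal *
        (1 - exp(-(spec$injection_duration / 2) / spec$tau_on))
    x[post] <- offset + (x_end - offset) * exp(-(t[post] - t1) / spec$tau_off)
  }
  x
}

#' Deterministic time course of cell-model parameters for a scenario
#'
#' Evaluates the scenario's first-order kinetics on the scan clock: for
#' each scan time, the instantaneous `n_ef`, `k_ef`, `n_cell`,
#' `k_cell`.  No noise enters at this stage.
#'
#' @param spec A [scenario_spec()].
#' @param times Scan times in seconds; `NULL` for the spec's protocol
#'   clock (baseline, injection, rinse at `scan_period` spacing).
#' @return A data frame with columns `time_s`, `n_ef`, `k_ef`,
#'   `n_cell`, `k_cell`, plus attributes `spec` and `injections`.
#' @export
parameter_timecourse <- function(spec, times = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(times)) {
    t_end <- spec$injection_start + spec$injection_duration +
      spec$rinse_duration
    times <- seq(spec$injection_start - spec$baseline, t_end,
                 by = spec$scan_period)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly ascending",
                                  call. = FALSE)
  g <- .dose_gain(spec)
  m <- spec$model
  out <- data.frame(
    time_s = times,
    n_ef = m$n_ef + .kinetic_trace(times, g * spec$amp_n_ef,
                                   g * spec$persistent_offset_n_ef, spec,
                                   reversal = g * spec$reversal_amp),
    k_ef = pmax(0, m$k_ef + .kinetic_trace(times, g * spec$amp_k_ef, 0,
                                           spec)),
    n_cell = m$n_cell + .kinetic_trace(times, g * spec$amp_n_cell, 0, spec),
    k_cell = pmax(0, m$k_cell + .kinetic_trace(times, g * spec$amp_k_cell, 0,
                                               spec)))
  attr(out, "spec") <- spec
  attr(out, "injections") <- data.frame(
    start_s = spec$injection_start,
    end_s = spec$injection_start + spec$injection_duration,
    label = spec$scenario,
    concentration = spec$concentration_scale)
  out
}

#' Render a scenario into a noisy series of angular scans
#'
#' Maps the parameter time course through the cell-stack optics (one
#' full transfer-matrix evaluation per scan) and adds i.i.d. Gaussian
#' intensity noise clipped to `[0, 1]`.  Rendering is vectorized over
#' scans, so a complete injection/rinse experiment costs a single
#' batched matrix evaluation.  The generator's scan grid is the
#' instrument's 60-78 degree range at 0.05 degree spacing; peak and TIR
#' localization are sub-grid, so this resolution supports the
#' 0.02-0.3 degree response range (see the vignette).
#'
#' @param spec A [scenario_spec()].
#' @param constants An [instrument_constants()] object.
#' @param timecourse Parameter time course; `NULL` to derive it from
#'   `spec` via [parameter_timecourse()].
#' @param angles Instrument-axis scan grid.
#' @return A list of [angular_spectrum()] objects with timestamps, with
#'   attributes `injections` and `spec`.  Identical seeds give
#'   identical output.
#' @export
render_sensogram <- function(spec, constants = instrument_constants(),
                             timecourse = NULL,
                             angles = spr_angle_grid(by = 0.05)) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(timecourse)) timecourse <- parameter_timecourse(spec)
  m <- spec$model
  phys <- angles - constants$angle_offset
  if (any(phys <= 0) || any(phys >= 90))
    stop("angle grid outside the physical range after offset correction",
         call. = FALSE)
  eps <- list(
    permittivity_from_index(constants$prism$n, constants$prism$k),
    permittivity_from_index(constants$chromium$n, constants$chromium$k),
    permittivity_from_index(constants$gold$n, constants$gold$k),
    permittivity_from_index(timecourse$n_ef, timecourse$k_ef),
    permittivity_from_index(timecourse$n_cell, timecourse$k_cell),
    permittivity_from_index(m$n_bulk, m$k_bulk))
  d <- c(NA, constants$chromium$thickness, constants$gold$thickness,
         m$d_ef, m$d_cell, NA)
  R <- .tmm_reflectance(eps, d, constants$wavelength, phys)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    R <- R + matrix(stats::rnorm(length(R), 0, spec$noise_sd), nrow(R))
    R <- pmin(pmax(R, 0), 1)
  }
  spectra <- lapply(seq_len(ncol(R)), function(j) {
    sp <- angular_spectrum(angles, R[, j],
                           timestamp = timecourse$time_s[j])
    attr(sp, "angle_offset") <- constants$angle_offset
    sp
  })
  attr(spectra, "injections") <- attr(timecourse, "injections")
  attr(spectra, "spec") <- spec
  spectra
}

# concentration ladder: five levels echoing a 2.5 nM - 250 uM dilution
# series, mapped into amplitude-scale space through the saturating
# uptake kinetics of a passive-absorption assay
.concentration_ladder <- function() {
  data.frame(label = c("2.5nM", "250nM", "2.5uM", "25uM", "250uM"),
             scale = c(0.5, 0.75, 1, 1.5, 2))
}

#' Generate a labelled benchmark suite of synthetic experiments
#'
#' Produces `n_per_scenario` seeded runs for each of the four
#' scenarios, cycling through a five-level concentration ladder with
#' excursion amplitudes jittered +/-30 percent around the scenario
#' defaults.  With `dir` set, each run is written as an
#' instrument-style angular-scan file plus an injection table, and a
#' manifest CSV maps file to ground-truth label; without `dir` the
#' rendered spectra are returned in memory (suitable for small suites).
#'
#' @param n_per_scenario Runs per scenario (>= 1).
#' @param base_seed Integer; run seeds are derived deterministically
#'   from it.
#' @param dir Output directory, or `NULL` for in-memory results.
#' @param noise_sd Intensity noise level passed to every run.
#' @param constants An [instrument_constants()] object.
#' @param scenarios Character vector of scenarios to include.
#' @return A list with `manifest` (data frame: `run_id`, `scenario`,
#'   `concentration`, `scale`, `seed`, `file`) and, when `dir` is
#'   `NULL`, `runs` (list of spectra lists).
#' @export
make_benchmark_suite <- function(n_per_scenario, base_seed = 1L,
                                 dir = NULL, noise_sd = 0.002,
                                 constants = instrument_constants(),
                                 scenarios = .scenarios) {
  stopifnot(n_per_scenario >= 1)
  ladder <- .concentration_ladder()
  manifest <- list()
  runs <- list()
  rid <- 0L
  for (sc in scenarios) {
    for (i in seq_len(n_per_scenario)) {
      rid <- rid + 1L
      lev <- ladder[(i - 1L) %% nrow(ladder) + 1L, ]
      seed <- (as.integer(base_seed) + 7919L * rid) %% .Machine$integer.max
      # amplitude jitter, deterministic per run
      set.seed(seed)
      jit <- stats::runif(2, 0.7, 1.3)
      def <- .scenario_defaults(sc)
      spec <- scenario_spec(sc, concentration_scale = lev$scale,
                            amp_n_ef = def$amp_n_ef * jit[1L],
                            amp_k_ef = def$amp_k_ef * jit[2L],
                            noise_sd = noise_sd, seed = seed)
      spectra <- render_sensogram(spec, constants)
      file <- NA_character_
      if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        file <- file.path(dir, sprintf("run-%03d.txt", rid))
        write_angular_scans(spectra, file,
                            wavelength = constants$wavelength,
                            angle_offset = constants$angle_offset)
        inj <- attr(spectra, "injections")
        utils::write.csv(inj, sub("\\.txt$", "-injections.csv", file),
                         row.names = FALSE, quote = FALSE)
      } else {
        runs[[rid]] <- spectra
      }
      manifest[[rid]] <- data.frame(run_id = rid, scenario = sc,
                                    concentration = lev$label,
                                    scale = lev$scale, seed = seed,
                                    file = basename(file))
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    list(manifest = manifest)
  } else {
    list(manifest = manifest, runs = runs)
  }
}

#' Scenario label recovery rate on a synthetic benchmark
#'
#' Streams through a [make_benchmark_suite()]-style set of runs
#' (without retaining the spectra), classifies each with
#' [classify_sensogram()] and tabulates recovery of the generating
#' label.
#'
#' @inheritParams make_benchmark_suite
#' @return A data frame with one row per run: `scenario`,
#'   `concentration`, `seed`, `label`, `correct`.
#' @export
scenario_recovery <- function(n_per_scenario, base_seed = 1L,
                              noise_sd = 0.002,
                              constants = instrument_constants(),
                              scenarios = .scenarios) {
  ladder <- .concentration_ladder()
  rows <- list()
  rid <- 0L
  for (sc in scenarios) {
    for (i in seq_len(n_per_scenario)) {
      rid <- rid + 1L
      lev <- ladder[(i - 1L) %% nrow(ladder) + 1L, ]
      seed <- (as.integer(base_seed) + 7919L * rid) %% .Machine$integer.max
      set.seed(seed)
      jit <- stats::runif(2, 0.7, 1.3)
      def <- .scenario_defaults(sc)
      spec <- scenario_spec(sc, concentration_scale = lev$scale,
                            amp_n_ef = def$amp_n_ef * jit[1L],
                            amp_k_ef = def$amp_k_ef * jit[2L],
                            noise_sd = noise_sd, seed = seed)
      spectra <- render_sensogram(spec, constants)
      sg <- features_over_time(spectra, attr(spectra, "injections"))
      label <- as.character(classify_sensogram(sg))
      rows[[rid]] <- data.frame(scenario = sc, concentration = lev$label,
                                seed = seed, label = label,
                                correct = sub("-like$", "", label) == sc)
    }
  }
  do.call(rbind, rows)
}
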
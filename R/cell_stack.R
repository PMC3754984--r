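# Instrument and cell-monolayer stack builders, parameter sweeps, and
# the thin-layer vs cell-monolayer sensitivity comparison.

#' Fixed optical constants of the simulated SPR instrument
#'
#' The sensor-side components are fixed throughout all simulations:
#' glass prism (n = 1.5294), chromium adhesion layer (n = 3.1085,
#' k = 3.4873, 1.53 nm), gold layer (n = 0.2262, k = 3.7639, 50.59 nm),
#' a water-like bulk medium (n = 1.3299) and a 670 nm source.
#'
#' `angle_offset` maps the physical in-prism incidence angle onto the
#' instrument's reported angle axis: reported = in-prism + offset.  The
#' default (+2.16 deg) is a one-point calibration of the simulated
#' angle axis against the known angular position of the main SPR dip of
#' the reference cell-monolayer stack; the TIR-region location then
#' serves as an independent check of the calibration (see the package
#' vignette).  Set it to 0 to work purely on the in-prism axis.
#'
#' @param prism_n,cr_n,cr_k,cr_d,au_n,au_k,au_d,bulk_n,bulk_k Optical
#'   constants and thicknesses (nm) of the fixed layers.
#' @param wavelength Source wavelength in nm.
#' @param angle_offset Instrument angle-axis calibration in degrees.
#' @return A list of class `"instrument_constants"`.
#' @export
instrument_constants <- function(prism_n = 1.5294,
                                 cr_n = 3.1085, cr_k = 3.4873, cr_d = 1.53,
                                 au_n = 0.2262, au_k = 3.7639, au_d = 50.59,
                                 bulk_n = 1.3299, bulk_k = 0,
                                 wavelength = 670, angle_offset = 2.16) {
  structure(list(
    prism = optical_layer("prism", prism_n, 0, Inf),
    chromium = optical_layer("chromium", cr_n, cr_k, cr_d),
    gold = optical_layer("gold", au_n, au_k, au_d),
    water_bulk = optical_layer("bulk", bulk_n, bulk_k, Inf),
    wavelength = wavelength,
    angle_offset = angle_offset), class = "instrument_constants")
}

#' @export
print.instrument_constants <- function(x, ...) {
  cat(sprintf("<instrument_constants> %g nm, angle offset %+.3g deg\n",
              x$wavelength, x$angle_offset))
  for (l in x[c("prism", "chromium", "gold", "water_bulk")]) print(l)
  invisible(x)
}

#' Three-section optical model of a cell monolayer
#'
#' A confluent cell monolayer on the sensor is split into three
#' sections: a thin section within reach of the evanescent field next
#' to the gold surface (`d_ef`, default 500 nm), a thick section for
#' the rest of the cell body (`d_cell`, default 3000 nm), and the
#' semi-infinite bulk medium above.  Each section carries its own real
#' index and extinction coefficient.
#'
#' @param d_ef,n_ef,k_ef Thickness (nm) and optical constants of the
#'   evanescent-field section.
#' @param d_cell,n_cell,k_cell Thickness (nm) and optical constants of
#'   the cell-body section.
#' @param n_bulk,k_bulk Bulk medium constants.
#' @return A list of class `"cell_monolayer_model"`.
#' @export
cell_monolayer_model <- function(d_ef = 500, n_ef = 1.34, k_ef = 0.002,
                                 d_cell = 3000, n_cell = 1.34,
                                 k_cell = 0.002,
                                 n_bulk = 1.3299, k_bulk = 0) {
  m <- list(d_ef = d_ef, n_ef = n_ef, k_ef = k_ef,
            d_cell = d_cell, n_cell = n_cell, k_cell = k_cell,
            n_bulk = n_bulk, k_bulk = k_bulk)
  bad <- c(d_ef <= 0, d_cell <= 0, n_ef <= 0, n_cell <= 0, n_bulk <= 0,
           k_ef < 0, k_cell < 0, k_bulk < 0)
  if (any(!vapply(m, is.finite, logical(1))) || any(bad))
    stop("invalid cell model: thicknesses and n must be > 0, k >= 0",
         call. = FALSE)
  structure(m, class = "cell_monolayer_model")
}

#' @export
print.cell_monolayer_model <- function(x, ...) {
  cat(sprintf(paste0("<cell_monolayer_model> ef: %g nm (n=%.4g, k=%.4g); ",
                     "cell: %g nm (n=%.4g, k=%.4g); bulk n=%.4g k=%.4g\n"),
              x$d_ef, x$n_ef, x$k_ef, x$d_cell, x$n_cell, x$k_cell,
              x$n_bulk, x$k_bulk))
  invisible(x)
}

#' Build a sensor stack carrying a single thin sample layer
#'
#' prism | Cr | Au | sample | bulk, the classic configuration for
#' biomolecular films much thinner than the evanescent-field
#' penetration depth.
#'
#' @param n,k,thickness Sample-layer optical constants and thickness in
#'   nm.
#' @param constants An [instrument_constants()] object.
#' @return A [layer_stack()] with the instrument's angle offset
#'   attached.
#' @export
build_thin_sample_stack <- function(n, k = 0, thickness = 10,
                                    constants = instrument_constants()) {
  s <- layer_stack(list(constants$prism, constants$chromium, constants$gold,
                        optical_layer("sample", n, k, thickness),
                        constants$water_bulk),
                   wavelength = constants$wavelength)
  attr(s, "angle_offset") <- constants$angle_offset
  s
}

#' Build the three-section cell-monolayer stack
#'
#' prism | Cr | Au | evanescent-field section | cell section | bulk.
#'
#' @param model A [cell_monolayer_model()].
#' @param constants An [instrument_constants()] object.
#' @return A [layer_stack()] with the instrument's angle offset
#'   attached.
#' @export
build_cell_stack <- function(model = cell_monolayer_model(),
                             constants = instrument_constants()) {
  stopifnot(inherits(model, "cell_monolayer_model"))
  s <- layer_stack(list(
    constants$prism, constants$chromium, constants$gold,
    optical_layer("ef_section", model$n_ef, model$k_ef, model$d_ef),
    optical_layer("cell_section", model$n_cell, model$k_cell, model$d_cell),
    optical_layer("bulk", model$n_bulk, model$k_bulk, Inf)),
    wavelength = constants$wavelength)
  attr(s, "angle_offset") <- constants$angle_offset
  s
}

#' Simulate an angular scan on the instrument's angle axis
#'
#' Computes the reflectance of a stack over a grid of instrument-axis
#' angles.  The stack's attached angle offset (see
#' [instrument_constants()]) is subtracted before the physical
#' transfer-matrix evaluation, so the returned spectrum is labelled in
#' instrument angles.
#'
#' @param stack A [layer_stack()], typically from [build_cell_stack()]
#'   or [build_thin_sample_stack()].
#' @param angles Instrument-axis angles in degrees.
#' @param timestamp Optional timestamp in seconds.
#' @return An [angular_spectrum()] with an `"angle_offset"` attribute.
#' @examples
#' sp <- simulate_scan(build_cell_stack())
#' find_spr_minimum(sp)$angle   # main SPR dip near 71.85 deg
#' @export
simulate_scan <- function(stack, angles = spr_angle_grid(),
                          timestamp = NULL) {
  off <- attr(stack, "angle_offset")
  if (is.null(off)) off <- 0
  sp <- stack_reflectance(stack, angles - off, timestamp = timestamp)
  sp$angles <- angles
  attr(sp, "angle_offset") <- off
  sp
}

.cell_params <- c("d_ef", "n_ef", "k_ef", "d_cell", "n_cell", "k_cell",
                  "n_bulk", "k_bulk", "total_thickness")
.thin_params <- c("n", "k", "thickness")

#' Sweep one model parameter and tabulate spectrum features
#'
#' Rebuilds the stack for each value of the swept parameter, simulates
#' the angular scan and extracts the multi-parameter feature set.  For
#' the cell builder the special parameter `"total_thickness"` varies
#' `d_cell` so that `d_ef + d_cell` equals the requested value.
#'
#' @param parameter Name of the parameter to sweep.  Cell builder: one
#'   of `d_ef`, `n_ef`, `k_ef`, `d_cell`, `n_cell`, `k_cell`, `n_bulk`,
#'   `k_bulk`, `total_thickness`.  Thin builder: `n`, `k` or
#'   `thickness`.
#' @param values Numeric vector of parameter values, reported in input
#'   order.
#' @param builder `"cell"` for the three-section monolayer model,
#'   `"thin"` for the single thin sample layer.
#' @param model Base [cell_monolayer_model()] (cell builder).
#' @param thin Base thin-layer description, a list with `n`, `k`,
#'   `thickness` (thin builder).
#' @param constants An [instrument_constants()] object.
#' @param angles Instrument-axis angle grid.
#' @return A data frame with one row per value: the swept parameter,
#'   `peak_angle_deg`, `peak_intensity`, `tir_angle_deg`,
#'   `tir_intensity`, `n_nodes` and `flags`.
#' @export
sweep_features <- function(parameter, values, builder = c("cell", "thin"),
                           model = cell_monolayer_model(),
                           thin = list(n = 1.45, k = 0, thickness = 10),
                           constants = instrument_constants(),
                           angles = spr_angle_grid()) {
  builder <- match.arg(builder)
  valid <- if (builder == "cell") .cell_params else .thin_params
  if (!is.character(parameter) || length(parameter) != 1L ||
      !(parameter %in% valid))
    stop("unknown sweep parameter '", parameter, "' for builder '",
         builder, "'", call. = FALSE)
  stopifnot(is.numeric(values), length(values) >= 1L)
  rows <- lapply(values, function(v) {
    if (builder == "cell") {
      m <- unclass(model)
      if (parameter == "total_thickness") {
        if (v <= m$d_ef) stop("total_thickness must exceed d_ef",
                              call. = FALSE)
        m$d_cell <- v - m$d_ef
      } else m[[parameter]] <- v
      stack <- build_cell_stack(do.call(cell_monolayer_model, m), constants)
      nb <- m$n_bulk
    } else {
      t <- thin
      t[[parameter]] <- v
      stack <- build_thin_sample_stack(t$n, t$k, t$thickness, constants)
      nb <- constants$water_bulk$n
    }
    sp <- simulate_scan(stack, angles)
    f <- spectrum_features(sp, n_prism = constants$prism$n, n_bulk = nb)
    cbind(value = v, as.data.frame(f))
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- parameter
  rownames(out) <- NULL
  out
}

#' Refractive-index sensitivity: thin layer vs cell monolayer
#'
#' Quantifies how much larger an index change a 10 nm sample layer
#' needs, compared with the 500 nm evanescent-field section of the cell
#' model, to displace the main SPR peak by the same angle.  The default
#' target shift is the one produced by raising `n_ef` from 1.340 to
#' 1.345 in the cell model.  The matching thin-layer index change is
#' found by bisection (resolved to 1e-6 index units).
#'
#' @param constants An [instrument_constants()] object.
#' @param target_shift Peak shift in degrees to match; `NULL` for the
#'   default `n_ef` sweep shift.
#' @param thin_n0,thin_thickness Starting index and thickness of the
#'   thin configuration.
#' @param delta_n_ef Index change applied to the ef-section when
#'   `target_shift` is `NULL` (default 0.005).
#' @param max_delta_n Upper bound of the bisection bracket (default
#'   0.2).
#' @param angles Angle grid used for the peak localization; a fine grid
#'   keeps the bisection well conditioned.
#' @return The ratio `delta_n_thin / delta_n_ef` (dimensionless), with
#'   attributes `target_shift`, `delta_n_thin` and `delta_n_ef`.
#' @export
sensitivity_ratio <- function(constants = instrument_constants(),
                              target_shift = NULL,
                              thin_n0 = 1.45, thin_thickness = 10,
                              delta_n_ef = 0.005, max_delta_n = 0.2,
                              angles = spr_angle_grid(by = 0.005)) {
  peak_of <- function(stack) {
    find_spr_minimum(simulate_scan(stack, angles))$angle
  }
  cell_peak <- function(n_ef) {
    peak_of(build_cell_stack(cell_monolayer_model(n_ef = n_ef), constants))
  }
  if (is.null(target_shift)) {
    target_shift <- cell_peak(1.340 + delta_n_ef) - cell_peak(1.340)
  } else {
    stopifnot(is.numeric(target_shift), target_shift > 0)
    # solve the ef-section change giving the requested shift
    base <- cell_peak(1.340)
    g <- function(dn) cell_peak(1.340 + dn) - base - target_shift
    if (g(max_delta_n) < 0)
      stop("target shift not attainable within delta_n <= ", max_delta_n,
           call. = FALSE)
    lo <- 0; hi <- max_delta_n
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (g(mid) < 0) lo <- mid else hi <- mid
    }
    delta_n_ef <- (lo + hi) / 2
  }
  thin_peak <- function(n) {
    peak_of(build_thin_sample_stack(n, 0, thin_thickness, constants))
  }
  p0 <- thin_peak(thin_n0)
  f <- function(dn) thin_peak(thin_n0 + dn) - p0 - target_shift
  if (f(max_delta_n) < 0)
    stop("target shift not attainable within delta_n <= ", max_delta_n,
         " in the thin configuration", call. = FALSE)
  lo <- 0; hi <- max_delta_n
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  dn_thin <- (lo + hi) / 2
  structure(dn_thin / delta_n_ef, target_shift = target_shift,
            delta_n_thin = dn_thin, delta_n_ef = delta_n_ef)
}

# sweep grids of the reference simulation suite; ranges as published,
# six evenly spaced values unless the published grid is discrete
.model_sweep_plan <- function() {
  list(
    fig3A = list(builder = "thin", parameter = "n",
                 values = seq(1.45, 1.50, length.out = 6)),
    fig3B = list(builder = "thin", parameter = "k",
                 values = seq(0, 0.05, length.out = 6)),
    fig3C = list(builder = "thin", parameter = "thickness",
                 values = c(400, 500, 600, 700),
                 thin = list(n = 1.38, k = 0, thickness = 400),
                 angles = spr_angle_grid(from = 55)),
    fig4B = list(builder = "cell", parameter = "n_ef",
                 values = seq(1.340, 1.345, length.out = 6)),
    fig4C = list(builder = "cell", parameter = "k_ef",
                 values = seq(0, 0.005, length.out = 6)),
    fig4D = list(builder = "cell", parameter = "n_cell",
                 values = seq(1.340, 1.345, length.out = 6)),
    fig4E = list(builder = "cell", parameter = "k_cell",
                 values = seq(0, 0.005, length.out = 6)),
    figS1 = list(builder = "cell", parameter = "total_thickness",
                 values = seq(2000, 6000, length.out = 6)),
    figS2 = list(builder = "cell", parameter = "n_bulk",
                 values = seq(1.330, 1.355, length.out = 6)))
}

#' Run the full reference sweep suite and write spectra + feature tables
#'
#' Reproduces every parameter sweep of the simulation study — thin-layer
#' index, extinction and waveguide-thickness sweeps, the four
#' cell-model sweeps, the total-thickness invariance and the bulk-index
#' invariance — writing, per sweep, one angular-scan file per parameter
#' value (`spectrum-###.txt`) and a `features.csv` table into
#' `output_dir/<sweep-id>/`.  Output is deterministic: running twice
#' produces byte-identical files.
#'
#' The waveguide-thickness sweep is scanned from 55 degrees so that the
#' emerging node near the TIR edge is inside the recorded range.
#'
#' @param output_dir Directory to create the sweep tree under.
#' @param constants An [instrument_constants()] object.
#' @return Invisibly, a named list of the feature tables.
#' @export
run_model_sweeps <- function(output_dir,
                             constants = instrument_constants()) {
  plan <- .model_sweep_plan()
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (id in names(plan)) {
    p <- plan[[id]]
    angles <- if (is.null(p$angles)) spr_angle_grid() else p$angles
    thin <- if (is.null(p$thin)) list(n = 1.45, k = 0, thickness = 10) else
      p$thin
    tab <- sweep_features(p$parameter, p$values, builder = p$builder,
                          thin = thin, constants = constants,
                          angles = angles)
    dir.create(file.path(output_dir, id), showWarnings = FALSE)
    for (i in seq_along(p$values)) {
      stack <- if (p$builder == "cell") {
        m <- unclass(cell_monolayer_model())
        if (p$parameter == "total_thickness") m$d_cell <- p$values[i] - m$d_ef
        else m[[p$parameter]] <- p$values[i]
        build_cell_stack(do.call(cell_monolayer_model, m), constants)
      } else {
        t <- thin; t[[p$parameter]] <- p$values[i]
        build_thin_sample_stack(t$n, t$k, t$thickness, constants)
      }
      sp <- simulate_scan(stack, angles, timestamp = 0)
      write_angular_scans(list(sp),
                          file.path(output_dir, id,
                                    sprintf("spectrum-%03d.txt", i)),
                          wavelength = constants$wavelength)
    }
    utils::write.csv(tab, file.path(output_dir, id, "features.csv"),
                     row.names = FALSE, quote = FALSE)
    out[[id]] <- tab
  }
  invisible(out)
}
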
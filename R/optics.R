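# Optics engine: multilayer p-polarized reflectance in the Kretschmann
# geometry via the 2x2 characteristic (Abeles) matrix formalism.

#' Create a homogeneous optical layer
#'
#' A layer is a homogeneous slab described by its real refractive index
#' `n`, extinction coefficient `k` and thickness in nanometres.  The
#' complex refractive index is `n + i k`; the corresponding complex
#' permittivity is its square (see [permittivity_from_index()]).  Entry
#' and exit media of a stack are semi-infinite, encoded as
#' `thickness = Inf`.
#'
#' @param name Short label for the layer (no whitespace), used in error
#'   messages and serialized stack files.
#' @param n Real refractive index, must be positive.
#' @param k Extinction coefficient, must be non-negative.
#' @param thickness Thickness in nm (> 0), or `Inf` for a semi-infinite
#'   medium.
#' @return An object of class `"optical_layer"`.
#' @examples
#' optical_layer("gold", 0.2262, 3.7639, 50.59)
#' optical_layer("water", 1.3299, 0, Inf)
#' @export
optical_layer <- function(name, n, k = 0, thickness = Inf) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (grepl("[[:space:]]", name))
    stop("layer name must not contain whitespace: ", name, call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("invalid layer '", name, "': n must be a positive number", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
    stop("invalid layer '", name, "': k must be non-negative", call. = FALSE)
  if (!is.numeric(thickness) || length(thickness) != 1L || is.na(thickness) ||
      thickness <= 0)
    stop("invalid layer '", name, "': thickness must be > 0 nm or Inf",
         call. = FALSE)
  structure(list(name = name, n = n, k = k, thickness = thickness),
            class = "optical_layer")
}

#' @export
print.optical_layer <- function(x, ...) {
  th <- if (is.infinite(x$thickness)) "semi-infinite" else
    sprintf("%.4g nm", x$thickness)
  cat(sprintf("<optical_layer> %s: n = %.6g, k = %.6g, %s\n",
              x$name, x$n, x$k, th))
  invisible(x)
}

is_semi_infinite <- function(layer) is.infinite(layer$thickness)

#' Assemble an ordered multilayer stack
#'
#' Layers are ordered from the illumination side (prism) to the exit
#' medium.  Exactly the first and last layer must be semi-infinite; any
#' number of finite films may lie between them.  The wavelength is a
#' property of the stack because all optical constants are taken at a
#' single simulation wavelength (no dispersion model).
#'
#' @param layers List of [optical_layer()] objects (at least two).
#' @param wavelength Vacuum wavelength in nm (default 670).
#' @return An object of class `"layer_stack"`.
#' @examples
#' s <- layer_stack(list(
#'   optical_layer("prism", 1.5294, 0, Inf),
#'   optical_layer("gold", 0.2262, 3.7639, 50.59),
#'   optical_layer("water", 1.3299, 0, Inf)))
#' s
#' @export
layer_stack <- function(layers, wavelength = 670) {
  if (!is.list(layers) || length(layers) < 2L)
    stop("a stack needs at least entry and exit media", call. = FALSE)
  ok <- vapply(layers, inherits, logical(1), what = "optical_layer")
  if (!all(ok)) stop("all elements of 'layers' must be optical_layer objects",
                     call. = FALSE)
  semi <- vapply(layers, is_semi_infinite, logical(1))
  n <- length(layers)
  if (!semi[1L] || !semi[n] || any(semi[-c(1L, n)]))
    stop("exactly the first and last layer must be semi-infinite",
         call. = FALSE)
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      !is.finite(wavelength) || wavelength <= 0)
    stop("wavelength must be a positive number (nm)", call. = FALSE)
  structure(list(layers = layers, wavelength = wavelength),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers, wavelength %.6g nm\n",
              length(x$layers), x$wavelength))
  for (l in x$layers) print(l)
  off <- attr(x, "angle_offset")
  if (!is.null(off) && off != 0)
    cat(sprintf("  instrument angle offset: %+.4g deg\n", off))
  invisible(x)
}

#' Convert refractive index to complex permittivity
#'
#' For a complex refractive index `n + i k` the relative permittivity is
#' its square: the real part is `n^2 - k^2` and the imaginary part is
#' `2 n k`.
#'
#' @param n Real refractive index (> 0).
#' @param k Extinction coefficient (>= 0).
#' @return A complex number (vectorized over `n` and `k`).
#' @seealso [index_from_permittivity()] for the inverse.
#' @export
permittivity_from_index <- function(n, k = 0) {
  if (any(!is.finite(n)) || any(n <= 0))
    stop("invalid layer: n must be positive", call. = FALSE)
  if (any(!is.finite(k)) || any(k < 0))
    stop("invalid layer: k must be non-negative", call. = FALSE)
  complex(real = n^2 - k^2, imaginary = 2 * n * k)
}

#' Convert complex permittivity to refractive index
#'
#' Takes the principal square root with non-negative imaginary part, so
#' the returned extinction coefficient `k` is always `>= 0` (passive
#' medium convention).
#'
#' @param eps Complex permittivity (vectorized).
#' @return A list with numeric components `n` and `k`.
#' @export
index_from_permittivity <- function(eps) {
  eps <- as.complex(eps)
  z <- sqrt(eps)
  flip <- Im(z) < 0
  z[flip] <- -z[flip]
  list(n = Re(z), k = Im(z))
}

#' Closed-form surface plasmon resonance angle estimate
#'
#' Solves the matching condition between the in-plane wavevector of the
#' incident light and the surface plasmon dispersion at a single
#' metal/dielectric interface,
#' \deqn{\sqrt{\varepsilon_0}\,\sin\theta =
#'   \mathrm{Re}\sqrt{\frac{\varepsilon_m \varepsilon_d}
#'                         {\varepsilon_m + \varepsilon_d}},}
#' giving the angle at which resonance is expected.  This ignores the
#' finite metal thickness and any additional films, so it is a sanity
#' estimate only; locate actual reflectance minima with
#' [find_spr_minimum()] on a simulated spectrum.
#'
#' @param eps_prism Real permittivity of the coupling prism.
#' @param eps_metal Complex permittivity of the metal
#'   (`Re(eps_metal) < -eps_medium` required for a bound plasmon).
#' @param eps_medium Real permittivity of the dielectric adjacent to the
#'   metal.
#' @return The resonance angle in degrees (in-prism).
#' @export
resonance_angle_approx <- function(eps_prism, eps_metal, eps_medium) {
  stopifnot(is.numeric(eps_prism), eps_prism > 0,
            is.numeric(eps_medium), eps_medium > 0)
  eps_metal <- as.complex(eps_metal)
  if (Re(eps_metal) >= -eps_medium)
    stop("no bound surface plasmon: Re(eps_metal) must be < -eps_medium",
         call. = FALSE)
  s <- Re(sqrt(eps_metal * eps_medium / (eps_metal + eps_medium))) /
    sqrt(eps_prism)
  if (s >= 1)
    stop("no resonance below grazing incidence for these permittivities",
         call. = FALSE)
  asin(s) * 180 / pi
}

#' Critical angle of total internal reflection
#'
#' @param n_prism Refractive index of the dense (prism) side.
#' @param n_bulk Refractive index of the rare (bulk) side; must be
#'   smaller than `n_prism`.
#' @return Angle in degrees, `asin(n_bulk / n_prism)`.
#' @export
critical_angle <- function(n_prism, n_bulk) {
  stopifnot(n_prism > 0, n_bulk > 0)
  if (n_bulk >= n_prism)
    stop("no total internal reflection: n_bulk must be < n_prism",
         call. = FALSE)
  asin(n_bulk / n_prism) * 180 / pi
}

#' Construct a sampled angular reflectance spectrum
#'
#' @param angles Strictly ascending angles in degrees (length >= 3).
#' @param reflectance Intensity reflectance values in `[0, 1]`, same
#'   length as `angles`.
#' @param timestamp Optional acquisition time in seconds.
#' @return An object of class `"angular_spectrum"`: a list with fields
#'   `angles`, `reflectance` and `timestamp`.
#' @export
angular_spectrum <- function(angles, reflectance, timestamp = NULL) {
  if (!is.numeric(angles) || !is.numeric(reflectance))
    stop("angles and reflectance must be numeric", call. = FALSE)
  if (length(angles) != length(reflectance) || length(angles) < 3L)
    stop("angles and reflectance must have equal length >= 3", call. = FALSE)
  if (any(diff(angles) <= 0))
    stop("angles must be strictly ascending", call. = FALSE)
  # tolerate sub-ulp numerical overshoot from the matrix product
  reflectance[reflectance > 1 & reflectance <= 1 + 1e-9] <- 1
  reflectance[reflectance < 0 & reflectance >= -1e-9] <- 0
  if (any(reflectance < 0 | reflectance > 1))
    stop("reflectance must lie in [0, 1]", call. = FALSE)
  if (!is.null(timestamp)) stopifnot(is.numeric(timestamp),
                                     length(timestamp) == 1L)
  structure(list(angles = angles, reflectance = reflectance,
                 timestamp = timestamp),
            class = "angular_spectrum")
}

#' @export
print.angular_spectrum <- function(x, ...) {
  cat(sprintf(
    "<angular_spectrum> %d points, %.4g-%.4g deg, R in [%.4g, %.4g]%s\n",
    length(x$angles), min(x$angles), max(x$angles),
    min(x$reflectance), max(x$reflectance),
    if (is.null(x$timestamp)) "" else sprintf(", t = %.6g s", x$timestamp)))
  invisible(x)
}

#' @export
as.data.frame.angular_spectrum <- function(x, ...) {
  data.frame(angle_deg = x$angles, reflectance = x$reflectance)
}

#' Default instrument angle grid
#'
#' The angular-scan grid of the simulated instrument: 60 to 78 degrees.
#' The default step is 0.01 degrees.
#'
#' @param from,to,by Grid limits and step in degrees.
#' @return Numeric vector of angles.
#' @export
spr_angle_grid <- function(from = 60, to = 78, by = 0.01) {
  seq(from, to, by = by)
}

# Core characteristic-matrix computation.
#
# eps: list, one element per layer; each element a complex scalar or a
#      complex vector of length Tn (time-varying optics).  Entry medium
#      must be scalar and lossless.
# d:   thickness vector in nm, NA for the two semi-infinite media.
# Returns an A x Tn matrix of intensity reflectance.
.tmm_reflectance <- function(eps, d, wavelength, angles, layer_names = NULL) {
  k0 <- 2 * pi / wavelength
  A <- length(angles)
  Tn <- max(vapply(eps, length, integer(1)))
  e0 <- eps[[1L]][1L]
  kx2 <- Re(e0) * sin(angles * pi / 180)^2   # (n0 sin theta)^2

  # longitudinal wavevector with Im >= 0 so evanescent fields decay
  kz_of <- function(ej) {
    if (length(ej) == 1L) {
      arg <- matrix(ej - as.complex(kx2), A, Tn)
    } else {
      arg <- matrix(ej, A, Tn, byrow = TRUE) - as.complex(kx2)
    }
    z <- k0 * sqrt(arg)
    flip <- Im(z) < 0
    z[flip] <- -z[flip]
    z
  }

  nlay <- length(eps)
  one <- matrix(1 + 0i, A, Tn)
  m11 <- one; m22 <- one
  m12 <- matrix(0i, A, Tn); m21 <- m12
  for (j in seq(2L, length.out = nlay - 2L)) {
    kzj <- kz_of(eps[[j]])
    qj <- kzj / (k0 * if (length(eps[[j]]) == 1L) eps[[j]] else
      matrix(eps[[j]], A, Tn, byrow = TRUE))       # p-pol admittance
    beta <- kzj * d[j]
    cb <- cos(beta); sb <- sin(beta)
    a12 <- -1i * sb / qj
    a21 <- -1i * qj * sb
    t11 <- m11 * cb + m12 * a21
    t12 <- m11 * a12 + m12 * cb
    t21 <- m21 * cb + m22 * a21
    t22 <- m21 * a12 + m22 * cb
    if (anyNA(t11) || any(!is.finite(Re(t11))))
      stop("non-finite characteristic matrix at layer ",
           if (is.null(layer_names)) j else layer_names[j],
           " (thickness too large?)", call. = FALSE)
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
  }
  q1 <- kz_of(eps[[1L]]) / (k0 * e0)
  qN <- kz_of(eps[[nlay]]) /
    (k0 * if (length(eps[[nlay]]) == 1L) eps[[nlay]] else
      matrix(eps[[nlay]], A, Tn, byrow = TRUE))
  num1 <- m11 + m12 * qN
  num2 <- m21 + m22 * qN
  r <- (num1 * q1 - num2) / (num1 * q1 + num2)
  R <- Mod(r)^2
  R[R > 1 & R <= 1 + 1e-9] <- 1
  R
}

#' Compute the p-polarized reflectance spectrum of a multilayer stack
#'
#' Evaluates the intensity reflectance of a [layer_stack()] at the given
#' incidence angles with the 2x2 characteristic-matrix method.  Angles
#' are the incidence angles at the base of the prism, measured inside
#' the prism (the physical in-prism convention; for spectra on the
#' instrument's calibrated angle axis see [simulate_scan()]).
#' Transverse momentum is conserved across layers
#' (`n0 sin(theta0) = nj sin(thetaj)` with complex `nj`), and the
#' longitudinal wavevector root is chosen with non-negative imaginary
#' part so evanescent fields decay away from each interface.
#'
#' @param stack A [layer_stack()].
#' @param angles Incidence angles in degrees, strictly inside (0, 90).
#' @param timestamp Optional timestamp passed through to the returned
#'   spectrum.
#' @return An [angular_spectrum()].
#' @examples
#' s <- layer_stack(list(
#'   optical_layer("prism", 1.5294, 0, Inf),
#'   optical_layer("gold", 0.2262, 3.7639, 50.59),
#'   optical_layer("water", 1.3299, 0, Inf)))
#' sp <- stack_reflectance(s, spr_angle_grid())
#' sp
#' @export
stack_reflectance <- function(stack, angles = spr_angle_grid(),
                              timestamp = NULL) {
  stopifnot(inherits(stack, "layer_stack"))
  if (any(angles <= 0) || any(angles >= 90))
    stop("angles must lie strictly between 0 and 90 degrees", call. = FALSE)
  eps <- lapply(stack$layers, function(l) permittivity_from_index(l$n, l$k))
  d <- vapply(stack$layers, function(l)
    if (is_semi_infinite(l)) NA_real_ else l$thickness, numeric(1))
  nm <- vapply(stack$layers, `[[`, character(1), "name")
  R <- .tmm_reflectance(eps, d, stack$wavelength, angles, layer_names = nm)
  angular_spectrum(angles, drop(R), timestamp = timestamp)
}
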
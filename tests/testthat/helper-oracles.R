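# Closed-form optical oracles, independent of the characteristic-matrix
# implementation, plus random-configuration generators.

eps_of <- function(n, k = 0) complex(real = n^2 - k^2, imaginary = 2 * n * k)

# complex longitudinal cosine in medium with permittivity eps for
# in-plane momentum set by (n0 sin theta); branch with Im >= 0
.cth <- function(eps, n0_sin) {
  z <- sqrt(as.complex(eps - n0_sin^2)) / sqrt(eps)
  z
}

# p-polarized amplitude reflection coefficient at a single a|b interface
fresnel_rp <- function(eps_a, eps_b, theta_deg, n0_sin = NULL) {
  th <- theta_deg * pi / 180
  if (is.null(n0_sin)) n0_sin <- sqrt(Re(eps_a)) * sin(th)
  kza <- sqrt(as.complex(eps_a - n0_sin^2))
  kzb <- sqrt(as.complex(eps_b - n0_sin^2))
  kza[Im(kza) < 0] <- -kza[Im(kza) < 0]
  kzb[Im(kzb) < 0] <- -kzb[Im(kzb) < 0]
  (eps_b * kza - eps_a * kzb) / (eps_b * kza + eps_a * kzb)
}

# closed-form Fresnel intensity reflectance, single interface
fresnel_R <- function(n1, k1, n2, k2, theta_deg) {
  Mod(fresnel_rp(eps_of(n1, k1), eps_of(n2, k2), theta_deg))^2
}

# closed-form Airy (two-beam summation) reflectance for a single film
# between semi-infinite media, p-polarization
airy_R <- function(n1, n2, k2, n3, k3, d_nm, lambda_nm, theta_deg) {
  e1 <- eps_of(n1); e2 <- eps_of(n2, k2); e3 <- eps_of(n3, k3)
  th <- theta_deg * pi / 180
  n0_sin <- n1 * sin(th)
  kz2 <- (2 * pi / lambda_nm) * sqrt(as.complex(e2 - n0_sin^2))
  kz2[Im(kz2) < 0] <- -kz2[Im(kz2) < 0]
  r12 <- fresnel_rp(e1, e2, theta_deg)
  r23 <- fresnel_rp(e2, e3, theta_deg, n0_sin = n0_sin)
  ph <- exp(2i * kz2 * d_nm)
  Mod((r12 + r23 * ph) / (1 + r12 * r23 * ph))^2
}

# reflectance of a stack at arbitrary angles via the package, padded so
# the angular_spectrum length-3 invariant is met
stack_R_at <- function(stack, angles) {
  pad <- sort(unique(c(angles, angles + 0.07, angles + 0.13)))
  sp <- stack_reflectance(stack, pad)
  sp$reflectance[match(angles, pad)]
}

random_interface <- function() {
  list(n1 = runif(1, 1.3, 1.8), n2 = runif(1, 1.0, 1.8),
       k2 = sample(c(0, runif(1, 0, 4)), 1),
       theta = runif(1, 1, 89.5))
}

random_film <- function() {
  list(n1 = runif(1, 1.4, 1.8),
       n2 = runif(1, 0.2, 2.2), k2 = sample(c(0, runif(1, 0, 4)), 1),
       n3 = runif(1, 1.0, 1.6), k3 = sample(c(0, runif(1, 0, 0.1)), 1),
       d = runif(1, 1, 800), theta = runif(1, 1, 89.5))
}

two_media <- function(n1, n2, k2 = 0, wavelength = 670) {
  layer_stack(list(optical_layer("a", n1, 0, Inf),
                   optical_layer("b", n2, k2, Inf)),
              wavelength = wavelength)
}
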
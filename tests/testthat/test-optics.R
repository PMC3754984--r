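test_that("permittivity/index conversions match hand arithmetic and round-trip", {
  expect_equal(permittivity_from_index(1, 0), 1 + 0i)
  # printed gold constants
  eps_au <- permittivity_from_index(0.2262, 3.7639)
  expect_equal(Re(eps_au), -14.11577677, tolerance = 1e-9)
  expect_equal(Im(eps_au), 1.70278836, tolerance = 1e-9)
  # water-like medium
  nk <- index_from_permittivity(1.7686 + 0i)
  expect_equal(nk$n, 1.32988721326, tolerance = 1e-10)
  expect_equal(nk$k, 0)
  # inverse of the gold example
  nk <- index_from_permittivity(complex(real = -14.12, imaginary = 1.703))
  expect_equal(nk$n, 0.226194422, tolerance = 1e-8)
  expect_equal(nk$k, 3.764460641, tolerance = 1e-8)

  set.seed(11)
  for (i in 1:50) {
    n <- runif(1, 0.05, 4); k <- runif(1, 0, 5)
    back <- index_from_permittivity(permittivity_from_index(n, k))
    expect_equal(back$n, n, tolerance = 1e-12)
    expect_equal(back$k, k, tolerance = 1e-12)
  }
  expect_error(permittivity_from_index(-1, 0), "n must be positive")
  expect_error(permittivity_from_index(0, 0), "n must be positive")
})

test_that("layer and stack constructors enforce their invariants", {
  expect_error(optical_layer("x", 1.5, -0.1), "non-negative")
  expect_error(optical_layer("x", 1.5, 0, 0), "thickness")
  expect_error(optical_layer("bad name", 1.5), "whitespace")
  prism <- optical_layer("prism", 1.5294, 0, Inf)
  gold <- optical_layer("gold", 0.2262, 3.7639, 50.59)
  water <- optical_layer("water", 1.3299, 0, Inf)
  expect_s3_class(layer_stack(list(prism, gold, water)), "layer_stack")
  expect_error(layer_stack(list(prism, gold)), "semi-infinite")
  expect_error(layer_stack(list(gold, prism, water)), "semi-infinite")
  expect_error(layer_stack(list(prism, water), wavelength = -5),
               "wavelength")
})

test_that("closed-form resonance estimate behaves across its domain", {
  eps_au <- permittivity_from_index(0.2262, 3.7639)
  th <- resonance_angle_approx(1.5294^2, eps_au, 1.3299^2)
  expect_equal(th, 68.2327023, tolerance = 1e-6)
  # infinitely conducting metal: resonance collapses onto the critical
  # angle
  th_inf <- resonance_angle_approx(1.5294^2, -1e9 + 0i, 1.3299^2)
  expect_equal(th_inf, critical_angle(1.5294, 1.3299), tolerance = 1e-3)
  # approaching the pole pushes the resonance towards grazing incidence
  expect_gt(resonance_angle_approx(1.5294^2, -7.5 + 0i, 1.3299^2), 80)
  # at the pole itself the plasmon momentum exceeds what the prism can
  # provide at any real angle
  expect_error(resonance_angle_approx(1.5294^2, -(1.3299^2) * 1.15 + 0i,
                                      1.3299^2), "grazing")
  expect_error(resonance_angle_approx(1.5294^2, -1 + 0i, 1.3299^2),
               "no bound surface plasmon")
})

test_that("two-media reflectance reproduces Fresnel limits", {
  s <- two_media(1.5294, 1.3299)
  # near-normal incidence: ((n1-n2)/(n1+n2))^2
  expect_equal(stack_R_at(s, 0.001), 0.004868177, tolerance = 1e-6)
  # beyond the critical angle a lossless interface reflects totally
  above <- critical_angle(1.5294, 1.3299) + c(0.1, 2, 15)
  expect_equal(stack_R_at(s, above), rep(1, 3), tolerance = 1e-12)
})

test_that("matrix reflectance equals closed-form Fresnel and Airy oracles", {
  set.seed(101)
  for (i in 1:400) {
    cfg <- random_interface()
    s <- two_media(cfg$n1, cfg$n2, cfg$k2)
    expect_equal(stack_R_at(s, cfg$theta),
                 fresnel_R(cfg$n1, 0, cfg$n2, cfg$k2, cfg$theta),
                 tolerance = 1e-10)
  }
  for (i in 1:400) {
    cfg <- random_film()
    s <- layer_stack(list(optical_layer("in", cfg$n1, 0, Inf),
                          optical_layer("film", cfg$n2, cfg$k2, cfg$d),
                          optical_layer("out", cfg$n3, cfg$k3, Inf)))
    expect_equal(stack_R_at(s, cfg$theta),
                 airy_R(cfg$n1, cfg$n2, cfg$k2, cfg$n3, cfg$k3, cfg$d,
                        670, cfg$theta),
                 tolerance = 1e-8)
  }
})

test_that("reflectance stays within [0, 1] for random passive stacks", {
  set.seed(202)
  angles <- seq(1, 89.5, by = 0.5)
  for (i in 1:60) {
    nfilm <- sample(0:4, 1)
    layers <- c(list(optical_layer("in", runif(1, 1.3, 1.8), 0, Inf)),
                lapply(seq_len(nfilm), function(j)
                  optical_layer(paste0("f", j), runif(1, 0.2, 2.5),
                                sample(c(0, runif(1, 0, 4)), 1),
                                runif(1, 1, 1000))),
                list(optical_layer("out", runif(1, 1, 1.7),
                                   sample(c(0, runif(1, 0, 0.2)), 1), Inf)))
    R <- stack_reflectance(layer_stack(layers), angles)$reflectance
    expect_true(all(R >= 0 & R <= 1))
  }
})

test_that("vanishing and split layers leave the spectrum unchanged", {
  angles <- seq(55, 80, by = 0.05)
  base <- layer_stack(list(optical_layer("prism", 1.5294, 0, Inf),
                           optical_layer("gold", 0.2262, 3.7639, 50.59),
                           optical_layer("film", 1.42, 0.01, 350),
                           optical_layer("water", 1.3299, 0, Inf)))
  R0 <- stack_reflectance(base, angles)$reflectance
  # layer of vanishing thickness is optically transparent
  thin <- layer_stack(append(base$layers,
                             list(optical_layer("ghost", 2.1, 0.5, 1e-9)),
                             after = 2))
  expect_equal(stack_reflectance(thin, angles)$reflectance, R0,
               tolerance = 1e-10)
  # splitting a layer into two identical halves changes nothing
  split <- layer_stack(list(base$layers[[1]], base$layers[[2]],
                            optical_layer("film_a", 1.42, 0.01, 150),
                            optical_layer("film_b", 1.42, 0.01, 200),
                            base$layers[[4]]))
  expect_equal(stack_reflectance(split, angles)$reflectance, R0,
               tolerance = 1e-10)
})

test_that("reflectance rejects out-of-domain angles and absurd thickness", {
  s <- two_media(1.5294, 1.3299)
  expect_error(stack_reflectance(s, c(-1, 30, 45)), "between 0 and 90")
  expect_error(stack_reflectance(s, c(30, 45, 95)), "between 0 and 90")
  huge <- layer_stack(list(optical_layer("in", 1.5, 0, Inf),
                           optical_layer("blob", 1.4, 2, 1e12),
                           optical_layer("out", 1.33, 0, Inf)))
  expect_error(stack_reflectance(huge, c(30, 40, 50)),
               "non-finite characteristic matrix at layer blob")
})

test_that("angular_spectrum validates its contract", {
  expect_error(angular_spectrum(c(1, 2), c(0.5, 0.5)), "length >= 3")
  expect_error(angular_spectrum(c(1, 2, 2), c(0.5, 0.5, 0.5)),
               "strictly ascending")
  expect_error(angular_spectrum(1:3, c(0.5, 1.4, 0.5)), "\\[0, 1\\]")
  sp <- angular_spectrum(1:3, c(0.5, 1 + 1e-12, 0.5))
  expect_lte(max(sp$reflectance), 1)
})
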
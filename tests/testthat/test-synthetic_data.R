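# Synthetic cohort generator: truth shapes, observer model, determinism.

test_that("spherical-harmonic basis is orthonormal and the noise field has unit variance", {
  set.seed(4)
  # quadrature check of orthonormality on a cos(theta)-uniform grid
  nt <- 60; np <- 120
  ct <- seq(-1 + 1 / nt, 1 - 1 / nt, length.out = nt)
  ph <- seq(0, 2 * pi * (1 - 1 / np), length.out = np)
  gr <- expand.grid(ct = ct, ph = ph)
  st <- sqrt(1 - gr$ct^2)
  u <- cbind(st * cos(gr$ph), st * sin(gr$ph), gr$ct)
  B <- sh_basis(u, 3)
  w <- (2 / nt) * (2 * pi / np)
  G <- crossprod(B) * w
  expect_equal(G, diag(ncol(B)), tolerance = 5e-3)

  # pointwise variance of the generated field is the injected 1
  cl2 <- oarvar:::noise_band_var(6, 3)
  expect_equal(sum(cl2 * (2 * (1:6) + 1) / (4 * pi)), 1, tolerance = 1e-12)
  flds <- replicate(400, {
    coef <- oarvar:::draw_noise_coef(6, 3)
    as.numeric(sh_basis(rbind(c(1, 0, 0), c(0, 0.6, 0.8)), 6)[, -1] %*% coef)
  })
  expect_equal(apply(flds, 1, sd), c(1, 1), tolerance = 0.12)
})

test_that("shape_radius matches ellipsoid geometry and truth_volume its quadrature", {
  sh <- truth_shape("x", "midline", c(0, 0, 0), c(10, 15, 20), 2)
  expect_equal(shape_radius(sh, c(1, 0, 0)), 10)
  expect_equal(shape_radius(sh, c(0, 1, 0)), 15)
  expect_equal(shape_radius(sh, c(0, 0, 1)), 20)
  expect_equal(truth_volume(sh), 4 / 3 * pi * 10 * 15 * 20 / 1000,
               tolerance = 1e-3)
})

test_that("realize_truth jitters deterministically with the right spread", {
  tmpl <- truth_shape("x", "midline", c(0, 0, 0), c(10, 12, 14), 2)
  expect_identical(realize_truth(tmpl, 0), tmpl)
  a <- realize_truth(tmpl, 0.1, seed = 5)
  b <- realize_truth(tmpl, 0.1, seed = 5)
  expect_identical(a, b)
  set.seed(31)
  fac <- replicate(200, realize_truth(tmpl, 0.1)$semiaxes[1] / 10)
  expect_lt(abs(sd(log(fac)) - 0.1), 0.02)
})

test_that("simulate_observer: identity, bias cube law, and noise recovery", {
  tr <- truth_shape("ball", "midline", c(0, 0, 0), c(10, 10, 10), 2)
  quiet <- observer_model("o", 1, c(0, 0, 0), c(body = 0))
  d <- simulate_observer(tr, quiet, 2)
  expect_equal(delineation_volume(d), 4.18879, tolerance = 0.02)

  biased <- observer_model("o", 1.1, c(0, 0, 0), c(body = 0))
  db <- simulate_observer(tr, biased, 2)
  expect_equal(delineation_volume(db) / truth_volume(tr), 1.1^3,
               tolerance = 0.02 * 1.331)

  # radial noise sd recovered across replicate observers
  set.seed(66)
  noisy <- observer_model("o", 1, c(0, 0, 0), c(body = 2))
  rad <- replicate(20, {
    dn <- simulate_observer(tr, noisy, 2)
    sl <- dn$slices[[which.min(abs(vapply(dn$slices, `[[`, numeric(1), "z")))]]
    p <- sl$polygons[[1]]
    sqrt(p[, 1]^2 + p[, 2]^2 + sl$z^2)  # radius at fixed equatorial angles
  })
  per_vertex_sd <- apply(rad, 1, sd)
  expect_equal(mean(per_vertex_sd), 2, tolerance = 0.3 / 2)

  # systematic shift moves the centroid
  shifted <- observer_model("o", 1, c(3, -2, 0), c(body = 0))
  ds <- simulate_observer(tr, shifted, 2)
  ctr <- colMeans(do.call(rbind, lapply(ds$slices, function(s) s$polygons[[1]])))
  expect_equal(unname(ctr), c(3, -2), tolerance = 0.2)
})

test_that("generate_cohort reproduces the clinical design and is deterministic", {
  cfg <- cohort_config(n_patients = 2, observers = default_observers()[1:2],
                       organs = default_organs()[c(4, 7)], seed = 12,
                       exclusions = list())
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_contour_set(c1$set, f1)
  write_contour_set(c2$set, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_length(c1$set$delineations, 2 * 2 * 2 * 2)

  # exclusions remove whole structures from the set
  cfg2 <- cohort_config(n_patients = 2, observers = default_observers()[1:2],
                        organs = default_organs()[c(4, 7)], seed = 12,
                        exclusions = list(list(patient_id = "P2",
                                               organ = "glottic_larynx")))
  c3 <- generate_cohort(cfg2)
  expect_length(c3$set$delineations, 16 - 4)
  idx <- delineation_index(c3$set)
  expect_false(any(idx$patient_id == "P2" & idx$organ == "glottic_larynx"))

  # ground truth carries the injected decomposition
  expect_true(c1$truth$analytic_icc > 0 && c1$truth$analytic_icc < 1)
  expect_equal(c1$truth$sigma2_patient_log, (3 * 0.1)^2)
  expect_equal(nrow(c1$truth$structure_volumes), 8)
})

test_that("observer volume biases drive a detectable Friedman effect", {
  # strong radial biases, small noise: near-perfect ordering in every block
  set.seed(21)
  biases <- c(0.9, 0.95, 1.0, 1.05, 1.1)
  obs <- lapply(seq_along(biases), function(i)
    observer_model(paste0("o", i), biases[i], c(0, 0, 0), c(body = 0.3)))
  rejections <- replicate(10, {
    cfg <- cohort_config(n_patients = 6, scan_times = "plan", observers = obs,
                         organs = default_organs()[7], seed = sample.int(1e6, 1),
                         exclusions = list())
    vt <- build_volume_table(generate_cohort(cfg)$set)
    friedman_test(vt, "glottic_larynx")$p_value < 0.01
  })
  expect_gte(mean(rejections), 0.9)
})
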
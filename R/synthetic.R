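# Synthetic multi-observer contour cohorts with known ground truth.
#
# Truth anatomy is a star-shaped superellipsoid radial surface r(theta,
# phi); each observer re-draws it with a multiplicative radial bias, a
# small systematic shift and a smooth zero-mean random surface field built
# from low-order spherical harmonics (bands 1..lmax, no l = 0 band, so the
# noise is spatially correlated and essentially volume-preserving). The
# observer surface is sliced into 64-gon polygons on the CT z-planes.

# ---- real orthonormal spherical harmonics -------------------------------

# associated Legendre P_l^m(x) for all l<=lmax, m<=l (Condon-Shortley)
legendre_table <- function(x, lmax) {
  n <- length(x)
  P <- vector("list", lmax + 1)
  for (l in 0:lmax) P[[l + 1]] <- matrix(0, n, l + 1)
  P[[1]][, 1] <- 1
  if (lmax == 0) return(P)
  sx <- sqrt(pmax(1 - x^2, 0))
  for (m in 0:lmax) {
    pmm <- if (m == 0) rep(1, n) else
      (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * sx^m
    P[[m + 1]][, m + 1] <- pmm
    if (m < lmax) {
      pm1 <- x * (2 * m + 1) * pmm
      P[[m + 2]][, m + 1] <- pm1
      if (m + 2 <= lmax) {
        pl2 <- pmm; pl1 <- pm1
        for (l in (m + 2):lmax) {
          pl <- ((2 * l - 1) * x * pl1 - (l + m - 1) * pl2) / (l - m)
          P[[l + 1]][, m + 1] <- pl
          pl2 <- pl1; pl1 <- pl
        }
      }
    }
  }
  P
}

#' Real spherical-harmonic basis at unit directions
#'
#' Orthonormal real basis, columns ordered (l, m) = (0,0), (1,-1), (1,0),
#' (1,1), (2,-2), ... so that `sum over basis of Y^2` is
#' `(lmax+1)^2 / (4 pi)` at every direction.
#'
#' @param u n x 3 matrix of unit direction vectors.
#' @param lmax maximum band (>= 0).
#' @return n x (lmax+1)^2 basis matrix.
#' @export
sh_basis <- function(u, lmax) {
  u <- matrix(u, ncol = 3)
  x <- pmin(pmax(u[, 3], -1), 1)
  phi <- atan2(u[, 2], u[, 1])
  P <- legendre_table(x, lmax)
  K <- (lmax + 1)^2
  B <- matrix(0, nrow(u), K)
  col <- 1L
  for (l in 0:lmax) {
    for (m in -l:l) {
      am <- abs(m)
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      B[, col] <- if (m == 0) nlm * P[[l + 1]][, 1] else if (m > 0)
        sqrt(2) * nlm * P[[l + 1]][, m + 1] * cos(m * phi)
      else
        sqrt(2) * nlm * P[[l + 1]][, am + 1] * sin(am * phi)
      col <- col + 1L
    }
  }
  B
}

# ---- truth shapes --------------------------------------------------------

#' Define a star-shaped truth anatomy
#'
#' Superellipsoid radial surface about `center`:
#' `r(u) = (|ux/a|^p + |uy/b|^p + |uz/c|^p)^(-1/p)` (p = 2 is an
#' ellipsoid, larger p more box-like), optionally perturbed by fixed
#' spherical-harmonic coefficients (mm).
#'
#' @param organ organ label.
#' @param laterality `"left"`, `"right"` or `"midline"`.
#' @param center (x, y, z) mm in the patient frame.
#' @param semiaxes (a, b, c) mm, all > 0.
#' @param exponent superellipsoid exponent p >= 1.
#' @param sh_coef optional perturbation coefficients matching [sh_basis()]
#'   column order for some lmax.
#' @return a `truth_shape` object.
#' @export
truth_shape <- function(organ, laterality, center, semiaxes, exponent = 2,
                        sh_coef = NULL) {
  stopifnot(length(center) == 3, length(semiaxes) == 3, all(semiaxes > 0),
            exponent >= 1)
  laterality <- match.arg(laterality, LATERALITIES)
  structure(list(organ = organ, laterality = laterality,
                 center = as.numeric(center), semiaxes = as.numeric(semiaxes),
                 exponent = exponent, sh_coef = sh_coef),
            class = "truth_shape")
}

#' Radial function of a truth shape
#'
#' @param shape a [truth_shape()].
#' @param u n x 3 unit directions.
#' @return radii in mm (all > 0).
#' @export
shape_radius <- function(shape, u) {
  u <- matrix(u, ncol = 3)
  p <- shape$exponent
  s <- (abs(u[, 1] / shape$semiaxes[1])^p +
        abs(u[, 2] / shape$semiaxes[2])^p +
        abs(u[, 3] / shape$semiaxes[3])^p)^(-1 / p)
  if (!is.null(shape$sh_coef)) {
    lmax <- as.integer(sqrt(length(shape$sh_coef))) - 1L
    s <- s + as.numeric(sh_basis(u, lmax) %*% shape$sh_coef)
    if (any(s <= 0)) stop("truth shape perturbation makes radius non-positive")
  }
  s
}

#' Analytic-quadrature volume of a truth shape
#'
#' `V = (1/3) integral of r(u)^3 over the sphere`, by a midpoint product
#' rule in (cos theta, phi).
#'
#' @param shape a [truth_shape()].
#' @param n_theta,n_phi quadrature resolution.
#' @return volume in cm^3.
#' @export
truth_volume <- function(shape, n_theta = 128, n_phi = 128) {
  ct <- seq(-1 + 1 / n_theta, 1 - 1 / n_theta, length.out = n_theta)
  ph <- seq(0, 2 * pi * (1 - 1 / n_phi), length.out = n_phi)
  g <- expand.grid(ct = ct, ph = ph)
  st <- sqrt(1 - g$ct^2)
  u <- cbind(st * cos(g$ph), st * sin(g$ph), g$ct)
  r <- shape_radius(shape, u)
  sum(r^3) / 3 * (2 / n_theta) * (2 * pi / n_phi) / 1000
}

#' Realize a patient-specific truth from a template
#'
#' Scales the template's semi-axes by one log-normal factor
#' (`exp(rnorm(1, 0, patient_jitter_sd))`), so the log semi-axes inherit
#' the jitter SD and the log volume three times it.
#'
#' @param template a [truth_shape()].
#' @param patient_jitter_sd SD of the log scale factor.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return a jittered `truth_shape`.
#' @export
realize_truth <- function(template, patient_jitter_sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (patient_jitter_sd == 0) return(template)
  for (i in 1:20) {
    f <- exp(stats::rnorm(1, 0, patient_jitter_sd))
    if (all(template$semiaxes * f > 1e-3)) {
      template$semiaxes <- template$semiaxes * f
      return(template)
    }
    warning("jitter produced a degenerate shape; resampling")
  }
  stop("could not realize a positive truth shape after 20 retries")
}

# ---- observer model ------------------------------------------------------

#' Define an observer's systematic and random delineation behaviour
#'
#' @param observer_id identifier.
#' @param volume_bias multiplicative radial scale (> 0); the enclosed
#'   volume scales with its cube.
#' @param systematic_shift (x, y, z) mm added to every contour.
#' @param noise_sd_by_region named mm SDs of the smooth surface noise;
#'   recognised names are the sub-region labels (`cranial`, `caudal`,
#'   `medial`, `lateral`, `anterior`, `posterior`) plus `body` as the
#'   fallback for unnamed regions. A single unnamed value is uniform noise.
#' @param noise_lmax highest spherical-harmonic band of the noise field.
#' @param noise_scale band-concentration parameter; larger values put more
#'   energy into higher (shorter-wavelength) bands.
#' @return an `observer_model` object.
#' @export
observer_model <- function(observer_id, volume_bias = 1,
                           systematic_shift = c(0, 0, 0),
                           noise_sd_by_region = c(body = 1),
                           noise_lmax = 6L, noise_scale = 2) {
  stopifnot(volume_bias > 0, length(systematic_shift) == 3,
            all(noise_sd_by_region >= 0), noise_lmax >= 1)
  if (is.null(names(noise_sd_by_region)) && length(noise_sd_by_region) == 1)
    names(noise_sd_by_region) <- "body"
  structure(list(observer_id = observer_id, volume_bias = volume_bias,
                 systematic_shift = as.numeric(systematic_shift),
                 noise_sd_by_region = noise_sd_by_region,
                 noise_lmax = as.integer(noise_lmax),
                 noise_scale = noise_scale),
            class = "observer_model")
}

# band variances c_l^2 (l = 1..lmax) normalized so the pointwise variance
# of the random field is exactly 1 at every direction
noise_band_var <- function(lmax, scale) {
  l <- seq_len(lmax)
  w <- exp(-l * (l + 1) / (scale * (scale + 1)))
  w / sum(w * (2 * l + 1) / (4 * pi))
}

# draw spherical-harmonic coefficients of a unit-variance smooth field
draw_noise_coef <- function(lmax, scale) {
  cl2 <- noise_band_var(lmax, scale)
  unlist(lapply(seq_len(lmax), function(l)
    stats::rnorm(2 * l + 1, 0, sqrt(cl2[l]))))
}

# region label of unit directions on a (biased) truth surface, mirroring
# the analysis sub-region rules: z caps by slice counts, quadrants
# elsewhere
truth_region <- function(shape, u, bias, slice_spacing,
                         cranial_slices = 3, caudal_slices = 3) {
  r <- bias * shape_radius(shape, u)
  z <- r * u[, 3]
  zr <- range(z)
  lab <- rep(NA_character_, nrow(u))
  lab[z > zr[2] - cranial_slices * slice_spacing] <- "cranial"
  lab[z < zr[1] + caudal_slices * slice_spacing & is.na(lab)] <- "caudal"
  rest <- is.na(lab)
  med_sign <- switch(shape$laterality, left = -1, right = +1, midline = 0)
  xside <- abs(u[, 1]) >= abs(u[, 2])
  q <- ifelse(xside,
              if (med_sign == 0) "lateral" else
                ifelse(sign(u[, 1]) == med_sign, "medial", "lateral"),
              ifelse(u[, 2] < 0, "anterior", "posterior"))
  lab[rest] <- q[rest]
  lab
}

region_noise_sd <- function(labels, sds) {
  out <- unname(sds[labels])
  fallback <- if ("body" %in% names(sds)) sds[["body"]] else unname(sds[1])
  out[is.na(out)] <- fallback
  out
}

#' Simulate one observer's delineation of a truth shape
#'
#' The observer surface radius is `volume_bias * r(u)` plus a smooth
#' zero-mean spherical-harmonic noise field with region-dependent SD; the
#' surface is shifted by the observer's systematic shift and sliced into
#' 64-gon polygons on the global z-planes (integer multiples of
#' `slice_spacing`). Slices the noisy surface no longer reaches are
#' dropped; radii driven below 0.5 mm are clipped with a warning.
#'
#' @param truth a [truth_shape()].
#' @param model an [observer_model()].
#' @param slice_spacing CT slice spacing in mm.
#' @param patient_id,scan_time identifiers for the resulting delineation.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @param n_vertices polygon vertices per slice.
#' @return a [delineation()].
#' @export
simulate_observer <- function(truth, model, slice_spacing,
                              patient_id = "P1", scan_time = "plan",
                              seed = NULL, n_vertices = 64L) {
  stopifnot(inherits(truth, "truth_shape"), inherits(model, "observer_model"))
  if (!is.null(seed)) set.seed(seed)
  coef <- draw_noise_coef(model$noise_lmax, model$noise_scale)
  ctr <- truth$center + model$systematic_shift
  sd_max <- max(model$noise_sd_by_region)

  # candidate z planes: global multiples of the slice spacing
  zext <- model$volume_bias * max(truth$semiaxes) + 3 * sd_max + 1
  k0 <- ceiling((ctr[3] - zext) / slice_spacing)
  k1 <- floor((ctr[3] + zext) / slice_spacing)
  if (k1 < k0) stop("truth shape thinner than one slice")
  zs <- (k0:k1) * slice_spacing
  psi <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices

  np <- length(zs)
  clip_env <- new.env()
  clip_env$clipped <- FALSE
  # observer surface radius in direction u (rows of a unit matrix)
  surf_radius <- function(u) {
    labs <- truth_region(truth, u, model$volume_bias, slice_spacing)
    sds <- region_noise_sd(labs, model$noise_sd_by_region)
    noise <- if (sd_max > 0)
      as.numeric(sh_basis(u, model$noise_lmax)[, -1, drop = FALSE] %*% coef)
    else 0
    R <- model$volume_bias * shape_radius(truth, u) + sds * noise
    if (any(R <= 0)) clip_env$clipped <- TRUE
    pmax(R, 0.5)
  }

  # a plane is cut iff the surface reaches above/below it on the slice axis
  dz_pl <- zs - ctr[3]
  pole_r <- surf_radius(cbind(0, 0, sign(dz_pl + 1e-12)))
  ok_plane <- abs(dz_pl) < pole_r - 1e-6

  dzv <- rep(dz_pl[ok_plane], each = n_vertices)
  cps <- rep(cos(psi), sum(ok_plane))
  sps <- rep(sin(psi), sum(ok_plane))
  # bisection on the in-plane radius: h(rho) = |(rho, dz)| - R(u(rho)) is
  # negative at rho = 0 (the axis point is inside) and positive for large
  # rho, so a crossing always exists for retained planes
  lo <- rep(0, length(dzv))
  hi <- rep(model$volume_bias * max(truth$semiaxes) + 3 * sd_max + 1,
            length(dzv))
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    nrm <- sqrt(mid^2 + dzv^2)
    u <- cbind(mid * cps, mid * sps, dzv) / nrm
    outside <- nrm > surf_radius(u)
    hi[outside] <- mid[outside]
    lo[!outside] <- mid[!outside]
  }
  rho <- (lo + hi) / 2
  if (clip_env$clipped)
    warning("noise drove the surface radius below zero; clipped at 0.5 mm")
  if (!any(ok_plane)) stop("observer surface intersects no slice plane")

  keep <- which(ok_plane)
  slices <- lapply(seq_along(keep), function(j) {
    idx <- ((j - 1) * n_vertices + 1):(j * n_vertices)
    contour_slice(zs[keep[j]], list(cbind(ctr[1] + rho[idx] * cps[idx],
                                          ctr[2] + rho[idx] * sps[idx])))
  })
  delineation(patient_id = patient_id, scan_time = scan_time,
              observer_id = model$observer_id, organ = truth$organ,
              laterality = truth$laterality, slices = slices,
              slice_spacing = slice_spacing)
}

# ---- cohort --------------------------------------------------------------

#' Default five-observer roster
#'
#' Radial biases 0.97-1.03 (volume ratios roughly 0.91-1.09), half-mm
#' systematic shifts, and regional noise SDs larger cranially and caudally
#' than over the body — the pattern reported for head-and-neck organs at
#' risk.
#' @export
default_observers <- function() {
  biases <- c(0.97, 0.99, 1.00, 1.01, 1.03)
  shifts <- list(c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0),
                 c(-0.5, 0, 0), c(0, -0.5, 0))
  lapply(1:5, function(i)
    observer_model(paste0("obs", i), volume_bias = biases[i],
                   systematic_shift = shifts[[i]],
                   noise_sd_by_region = c(cranial = 2.0, caudal = 1.6,
                                          body = 1.0)))
}

#' Default seven-structure organ template set
#'
#' Superellipsoid stand-ins for the head-and-neck organs at risk (spinal
#' cord, left/right parotid and submandibular glands, thyroid cartilage,
#' glottic larynx), sized to the magnitude of the clinical mean volumes.
#' @export
default_organs <- function() {
  list(
    truth_shape("spinal_cord", "midline", c(0, 60, -20), c(4.5, 4.5, 80), 4),
    truth_shape("parotid_left", "left", c(55, 10, 30), c(17, 20, 20), 2),
    truth_shape("parotid_right", "right", c(-55, 10, 30), c(17, 20, 20), 2),
    truth_shape("submandibular_left", "left", c(25, 0, -15), c(12, 14, 15), 2),
    truth_shape("submandibular_right", "right", c(-25, 0, -15), c(12, 14, 15), 2),
    truth_shape("thyroid_cartilage", "midline", c(0, -20, -35), c(14, 14, 11), 3),
    truth_shape("glottic_larynx", "midline", c(0, -20, -60), c(13, 14, 13.5), 2))
}

#' Configure a synthetic cohort
#'
#' Defaults emulate the clinical design: 5 observers, 6 patients, planning
#' and repeat scans, 7 structures at 2 mm slicing, with the right parotid
#' gland of patient 4 excluded (410 structures in total).
#'
#' @param n_patients number of patients (>= 2).
#' @param scan_times scan labels, subset of c("plan", "rep").
#' @param observers list of [observer_model()] (>= 2).
#' @param organs list of [truth_shape()] templates.
#' @param jitter_sd SD of the per-patient log size factor.
#' @param scan_jitter_sd SD of the per-scan log size factor (anatomy change
#'   between planning and repeat CT).
#' @param slice_spacing CT slice spacing in mm.
#' @param exclusions list of records with `patient_id` and/or `organ`
#'   (missing fields are wildcards); matching structures are not generated.
#' @param seed RNG seed recorded in the output metadata.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(n_patients = 6, scan_times = c("plan", "rep"),
                          observers = default_observers(),
                          organs = default_organs(),
                          jitter_sd = 0.10, scan_jitter_sd = 0.02,
                          slice_spacing = 2,
                          exclusions = list(list(patient_id = "P4",
                                                 organ = "parotid_right")),
                          seed = 1L) {
  stopifnot(n_patients >= 2, length(observers) >= 2,
            all(scan_times %in% SCAN_TIMES), length(organs) >= 1,
            slice_spacing > 0)
  structure(list(n_patients = as.integer(n_patients), scan_times = scan_times,
                 observers = observers, organs = organs,
                 jitter_sd = jitter_sd, scan_jitter_sd = scan_jitter_sd,
                 slice_spacing = slice_spacing, exclusions = exclusions,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a full synthetic cohort with ground truth
#'
#' Full factorial patients x scan times x observers x organs minus the
#' configured exclusions, bit-reproducible from `(config, seed)`. The
#' ground truth records every injected parameter, the per-structure truth
#' volumes, and the analytic ICC implied by the injected log-volume
#' variance decomposition: patient and patient-time size jitter contribute
#' `(3 jitter_sd)^2` and `(3 scan_jitter_sd)^2`, the observer radial
#' biases `var(3 log bias)`, and the zero-mean noise field essentially
#' nothing.
#'
#' @param config a [cohort_config()].
#' @return list with `set` (a [delineation_set()]) and `truth` (a
#'   `ground_truth` list).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  dels <- list()
  tv <- list()
  pids <- paste0("P", seq_len(config$n_patients))
  for (p in pids) {
    for (tmpl in config$organs) {
      patient_truth <- realize_truth(tmpl, config$jitter_sd)
      for (st in config$scan_times) {
        truth <- realize_truth(patient_truth, config$scan_jitter_sd)
        skip <- is_excluded(list(patient_id = p, organ = tmpl$organ,
                                 scan_time = st), config$exclusions)
        tv[[length(tv) + 1]] <- data.frame(
          patient_id = p, scan_time = st, organ = tmpl$organ,
          true_volume = truth_volume(truth), excluded = skip)
        for (om in config$observers) {
          d <- simulate_observer(truth, om, config$slice_spacing,
                                 patient_id = p, scan_time = st)
          if (!skip) dels[[length(dels) + 1]] <- d
        }
      }
    }
  }
  biases <- vapply(config$observers, `[[`, numeric(1), "volume_bias")
  s2p <- (3 * config$jitter_sd)^2
  s2pt <- (3 * config$scan_jitter_sd)^2
  s2o <- var(3 * log(biases))
  truth <- structure(list(
    seed = config$seed,
    structure_volumes = do.call(rbind, tv),
    observer_bias = setNames(biases, vapply(config$observers, `[[`,
                                            character(1), "observer_id")),
    noise_sd_by_region = config$observers[[1]]$noise_sd_by_region,
    sigma2_patient_log = s2p, sigma2_patient_time_log = s2pt,
    sigma2_observer_log = s2o,
    analytic_icc = (s2p + s2pt) / (s2p + s2pt + s2o)),
    class = "ground_truth")
  set <- delineation_set(dels, metadata = list(
    generator = "oarvar_synthetic", seed = config$seed,
    n_patients = config$n_patients,
    excluded = config$exclusions))
  list(set = set, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> seed %d, %d structures, analytic ICC %.3f\n",
              x$seed, nrow(x$structure_volumes), x$analytic_icc))
  invisible(x)
}
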
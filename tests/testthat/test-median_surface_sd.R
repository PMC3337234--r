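# Median contour surface, local/global/regional 3D SD, sub-region rules.

concentric_masks <- function(radii = 8:12, half = 15, spacing = 1) {
  lapply(radii, ball_mask, half = half, spacing = spacing)
}

test_that("compute_median_surface reproduces the majority shape", {
  masks <- concentric_masks()
  surf <- compute_median_surface(masks)
  expect_true(mesh_is_closed(surf))
  expect_equal(surf$n_observers, 5)
  # enclosed volume within 5% of the 10 mm median ball
  expect_equal(mesh_volume(surf), 4 / 3 * pi, tolerance = 0.05)

  # unanimity: identical observers reproduce the common mask's volume
  same <- concentric_masks(c(9, 9, 9))
  s2 <- compute_median_surface(same)
  expect_equal(mesh_volume(s2), mask_volume(same[[1]]), tolerance = 0.12)

  # two disjoint observers have no strict-majority voxel
  g <- oar_grid(c(0, 0, 0), c(1, 1, 1), c(30, 30, 30))
  a <- box_mask(g, c(1, 1, 1), c(8, 8, 8))
  b <- box_mask(g, c(15, 15, 15), c(25, 25, 25))
  expect_error(compute_median_surface(list(a, b)), "degenerate median")
  expect_error(compute_median_surface(list(a)), "length\\(masks\\) >= 2")
})

test_that("local_sd recovers the concentric-ball dispersion", {
  masks <- concentric_masks()
  surf <- compute_median_surface(masks)
  fld <- local_sd(surf, masks)
  # per-vertex distances ~ {-2,-1,0,1,2} mm -> sd = sqrt(2.5) = 1.5811
  expect_equal(fld$global_sd, sd(-2:2), tolerance = 0.15)
  expect_lt(diff(range(fld$sd)), 0.9)  # roughly uniform over the sphere
  expect_equal(fld$n_observers, 5)

  # identical observers: exactly zero variation
  same <- concentric_masks(c(10, 10, 10, 10))
  s0 <- compute_median_surface(same)
  f0 <- local_sd(s0, same)
  expect_equal(f0$global_sd, 0)
  expect_true(all(f0$sd == 0))
})

test_that("a shifted observer concentrates variation at the shift poles", {
  g <- ball_mask(10)$grid
  ax <- seq(-15, 15, by = 1)
  shifted <- oar_mask(g, outer(outer((ax - 2)^2, ax^2, `+`), ax^2, `+`) <= 100)
  masks <- c(concentric_masks(c(10, 10, 10, 10)), list(shifted))
  surf <- compute_median_surface(masks)
  fld <- local_sd(surf, masks)
  v <- surf$vertices
  on_x_pole <- abs(abs(v[, 1]) - 10) < 1.5 & abs(v[, 2]) < 3 & abs(v[, 3]) < 3
  on_y_pole <- abs(abs(v[, 2]) - 10) < 1.5 & abs(v[, 1]) < 3 & abs(v[, 3]) < 3
  expect_gt(mean(fld$sd[on_x_pole]), 2 * mean(fld$sd[on_y_pole]))
})

test_that("degenerate observer masks are excluded with a warning", {
  masks <- concentric_masks(c(9, 10, 11))
  surf <- compute_median_surface(masks)
  empty <- oar_mask(masks[[1]]$grid, array(FALSE, masks[[1]]$grid$shape))
  expect_warning(fld <- local_sd(surf, c(masks, list(empty))), "degenerate")
  expect_equal(fld$n_observers, 3)
})

test_that("property: rigid motion equivariance and a median 6th observer", {
  masks <- concentric_masks()
  surf <- compute_median_surface(masks)
  fld <- local_sd(surf, masks)

  # translate everything together by whole voxels (content shift on the grid)
  shift_mask <- function(m, k) {
    occ <- array(FALSE, m$grid$shape)
    occ[(1 + k):dim(occ)[1], , ] <- m$occupancy[1:(dim(occ)[1] - k), , ]
    oar_mask(m$grid, occ)
  }
  masks_t <- lapply(masks, shift_mask, k = 2)
  surf_t <- compute_median_surface(masks_t)
  fld_t <- local_sd(surf_t, masks_t)
  expect_equal(fld_t$global_sd, fld$global_sd, tolerance = 0.05)

  # rotation about z by 90 degrees (exact on the grid)
  rot_mask <- function(m) {
    occ <- aperm(m$occupancy, c(2, 1, 3))
    occ <- occ[dim(occ)[1]:1, , ]
    oar_mask(m$grid, occ)
  }
  masks_r <- lapply(masks, rot_mask)
  fld_r <- local_sd(compute_median_surface(masks_r), masks_r)
  expect_equal(fld_r$global_sd, fld$global_sd, tolerance = 0.05)

  # adding a 6th observer equal to the median ball never increases the sd
  masks6 <- c(masks, list(ball_mask(10)))
  fld6 <- local_sd(compute_median_surface(masks6), masks6)
  expect_lte(fld6$global_sd, fld$global_sd + 0.05)

  # grid-refinement convergence: halving the in-plane spacing moves the
  # global sd by < 5%
  masks_f <- concentric_masks(spacing = 0.5, half = 14)
  fld_f <- local_sd(compute_median_surface(masks_f), masks_f)
  expect_lt(abs(fld_f$global_sd - fld$global_sd) / fld$global_sd, 0.05)
})

test_that("assign_regions: slice caps, quadrants and landmark bands", {
  # elongated box: 20 occupied planes at dz = 1
  g <- oar_grid(c(-10, -10, -10), c(1, 1, 1), c(21, 21, 22))
  masks <- lapply(c(6, 7, 8), function(r)
    box_mask(g, c(-r, -r, -9), c(r, r, 10)))
  surf <- compute_median_surface(masks)
  spec5 <- region_spec("parotidish", "caps", 5, 5)
  lab <- assign_regions(surf, spec5, "left")
  v <- surf$vertices
  k <- round(v[, 3] + 9)  # plane index 0..19
  expect_true(all(lab[k >= 15] == "cranial"))
  expect_true(all(lab[k <= 4] == "caudal"))
  mid <- k > 4 & k < 15
  expect_true(all(lab[mid] %in% c("medial", "lateral", "anterior", "posterior")))
  # left-sided organ: medial faces the midline at -x under LPS (check the
  # wall centres; corners are tie-broken towards the x side)
  body <- which(mid)
  wall <- function(d1, s) body[s * v[body, d1] > 6.5 & abs(v[body, 3 - d1]) < 3]
  expect_true(all(lab[wall(1, -1)] == "medial"))
  expect_true(all(lab[wall(1, +1)] == "lateral"))
  expect_true(all(lab[wall(2, -1)] == "anterior"))
  expect_true(all(lab[wall(2, +1)] == "posterior"))
  # right-sided organ mirrors medial/lateral
  lab_r <- assign_regions(surf, spec5, "right")
  expect_true(all(lab_r[wall(1, +1)] == "medial"))

  # landmark rule: cranial above C1, caudal from T2 on
  spec_l <- region_spec("cord", "landmarks", landmarks = c(5, -5))
  lab_l <- assign_regions(surf, spec_l, "midline")
  expect_true(all(lab_l[v[, 3] >= 5] == "cranial"))
  expect_true(all(lab_l[v[, 3] <= -5] == "caudal"))
  expect_true(all(lab_l[v[, 3] > -5 & v[, 3] < 5] == "medial"))
  expect_error(region_spec("cord", "landmarks", landmarks = c(-5, 5)),
               "strictly decreasing")

  # too few planes: caps split at the midplane with a warning
  flat <- lapply(c(6, 7, 8), function(r) box_mask(g, c(-r, -r, -1), c(r, r, 2)))
  sflat <- compute_median_surface(flat)
  expect_warning(lab_f <- assign_regions(sflat, spec5, "left"), "midplane")
  expect_true(all(lab_f %in% c("cranial", "caudal")))
})

test_that("thyroid closed-slice rule finds the unclosed caudal run", {
  # tube (ring cross-section) on top, solid bottom: bottom 4 planes unclosed
  g <- oar_grid(c(-10, -10, 0), c(1, 1, 1), c(21, 21, 14))
  ax <- seq(-10, 10, by = 1)
  r2 <- outer(ax^2, ax^2, `+`)
  ring <- r2 <= 64 & r2 >= 16
  solid <- r2 <= 64
  occ <- array(FALSE, g$shape)
  for (z in 1:4) occ[, , z] <- solid
  for (z in 5:12) occ[, , z] <- ring
  m <- oar_mask(g, occ)
  surf <- compute_median_surface(list(m, m, m))
  spec <- region_spec("thyroid", "closed_caudal", cranial_slices = 1)
  lab <- assign_regions(surf, spec, "midline")
  v <- surf$vertices
  expect_true(all(lab[v[, 3] < 3.4] == "caudal"))
  expect_true(all(lab[v[, 3] > 10.6] == "cranial"))
  expect_true(any(lab %in% c("lateral", "anterior", "posterior")))
})

test_that("regional_sd averages per label and write_ply exports", {
  masks <- concentric_masks(c(9, 10, 11))
  surf <- compute_median_surface(masks)
  fld <- local_sd(surf, masks)
  lab <- rep("body", length(fld$sd))
  lab[surf$vertices[, 3] > 5] <- "cranial"
  fld2 <- fld
  fld2$sd <- ifelse(lab == "cranial", 3, 1)
  reg <- regional_sd(fld2, lab)
  expect_equal(unname(reg["cranial"]), 3)
  expect_equal(unname(reg["body"]), 1)
  expect_error(regional_sd(fld, lab[-1]), "cover all")

  # constant field: every region equals the constant
  fld3 <- fld; fld3$sd <- rep(2, length(fld$sd))
  expect_true(all(abs(regional_sd(fld3, lab) - 2) < 1e-12))

  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(surf, f, sd = fld$sd, region = lab)
  lines <- readLines(f)
  expect_equal(lines[1], "ply")
  expect_equal(sum(lines == "end_header"), 1)
  nv <- nrow(surf$vertices); nt <- nrow(surf$triangles)
  expect_true(any(grepl(paste("element vertex", nv), lines)))
  expect_equal(length(lines), which(lines == "end_header") + nv + nt)
})

test_that("injected cranial noise is recovered in the regional summary", {
  set.seed(99)
  tr <- truth_shape("phantom", "midline", c(0, 0, 0), c(12, 12, 12), 2)
  spec <- region_spec("phantom", "caps", 2, 2)
  hits <- 0; cran <- c(); body <- c()
  n_rep <- 8
  for (rep in 1:n_rep) {
    masks <- lapply(1:5, function(i) {
      om <- observer_model(paste0("o", i), 1, c(0, 0, 0),
                           c(cranial = 3, caudal = 1, body = 1))
      d <- simulate_observer(tr, om, 2)
      rasterize(d, oar_grid(c(-25, -25, -24), c(1, 1, 2), c(51, 51, 25)))
    })
    surf <- compute_median_surface(masks)
    fld <- local_sd(surf, masks)
    lab <- assign_regions(surf, spec, "midline")
    reg <- regional_sd(fld, lab)
    others <- reg[setdiff(names(reg), c("cranial", "caudal"))]
    if (reg["cranial"] > max(others)) hits <- hits + 1
    cran <- c(cran, reg[["cranial"]])
  }
  expect_gte(hits, n_rep - 1)
  expect_equal(mean(cran), 3, tolerance = 0.4 / 3)
})
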
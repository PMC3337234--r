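# Independent oracles and phantom builders shared across the suite.

# ---- geometry phantoms ----------------------------------------------------

square_poly <- function(side = 10, x0 = 0, y0 = 0) {
  matrix(c(x0, y0, x0 + side, y0, x0 + side, y0 + side, x0, y0 + side),
         ncol = 2, byrow = TRUE)
}

prism_delineation <- function(side = 10, n_slices = 5, dz = 2) {
  delineation("P1", "plan", "obs1", "prism", "midline",
              lapply(seq(0, by = dz, length.out = n_slices), function(z)
                contour_slice(z, list(square_poly(side)))),
              slice_spacing = dz)
}

# voxelized centred ball on an isotropic grid
ball_mask <- function(radius, half = 15, spacing = 1) {
  n <- 2 * half / spacing + 1
  g <- oar_grid(c(-half, -half, -half), rep(spacing, 3), rep(n, 3))
  ax <- seq(-half, half, by = spacing)
  occ <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= radius^2
  oar_mask(g, occ)
}

# axis-aligned box mask given corner coordinates, on a shared grid
box_mask <- function(grid, lo, hi) {
  ax <- lapply(1:3, function(d)
    grid$origin[d] + (seq_len(grid$shape[d]) - 1) * grid$spacing[d])
  inx <- ax[[1]] >= lo[1] & ax[[1]] <= hi[1]
  iny <- ax[[2]] >= lo[2] & ax[[2]] <= hi[2]
  inz <- ax[[3]] >= lo[3] & ax[[3]] <= hi[3]
  occ <- outer(outer(inx, iny, `&`), inz, `&`)
  oar_mask(grid, occ)
}

# every edge of a triangulation must be shared by exactly two triangles
mesh_is_closed <- function(mesh) {
  F <- mesh$triangles
  ed <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(key) == 2)
}

# ---- point-in-polygon oracle (independent of the C++ rasterizer) ---------

# even-odd crossing parity with the same half-open lower-edge convention,
# coded directly from the ray-casting definition
pip_oracle <- function(x, y, polys) {
  crossings <- 0L
  for (p in polys) {
    n <- nrow(p)
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      yi <- p[i, 2]; yj <- p[j, 2]
      if ((y < yi) != (y < yj)) {
        t <- (y - yi) / (yj - yi)
        if (x < p[i, 1] + t * (p[j, 1] - p[i, 1])) crossings <- crossings + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

rasterize_oracle <- function(polys, grid, k) {
  occ <- matrix(FALSE, grid$shape[1], grid$shape[2])
  for (i in seq_len(grid$shape[1])) for (j in seq_len(grid$shape[2])) {
    occ[i, j] <- pip_oracle(grid$origin[1] + (i - 1) * grid$spacing[1],
                            grid$origin[2] + (j - 1) * grid$spacing[2], polys)
  }
  occ
}

random_polygon <- function(n_max = 12) {
  n <- sample(3:n_max, 1)
  cbind(runif(n, 2, 28), runif(n, 2, 28))
}

# ---- statistics oracles ---------------------------------------------------

# classic (no-tie) Friedman statistic straight from the rank formula
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  Rj <- colSums(ranks)
  12 / (n * k * (k + 1)) * sum((Rj - n * (k + 1) / 2)^2)
}

# expected-mean-squares method-of-moments solution for the balanced
# patients x observers x 2-times single-replicate design
ems_oracle <- function(df) {
  a <- length(unique(df$patient_id))
  b <- length(unique(df$observer_id))
  cc <- length(unique(df$scan_time))
  y <- xtabs(volume ~ patient_id + observer_id + scan_time, df)
  stopifnot(nrow(df) == a * b * cc)
  gm <- mean(y)
  mp <- apply(y, 1, mean); mo <- apply(y, 2, mean); mt <- apply(y, 3, mean)
  mpo <- apply(y, c(1, 2), mean)
  mpt <- apply(y, c(1, 3), mean)
  mot <- apply(y, c(2, 3), mean)
  SSP <- b * cc * sum((mp - gm)^2)
  SSO <- a * cc * sum((mo - gm)^2)
  SST <- a * b * sum((mt - gm)^2)
  SSPO <- cc * sum((mpo - outer(mp, rep(1, b)) - outer(rep(1, a), mo) + gm)^2)
  SSPT <- b * sum((mpt - outer(mp, rep(1, cc)) - outer(rep(1, a), mt) + gm)^2)
  SSOT <- a * sum((mot - outer(mo, rep(1, cc)) - outer(rep(1, b), mt) + gm)^2)
  SSE <- sum((y - gm)^2) - SSP - SSO - SST - SSPO - SSPT - SSOT
  MSE <- SSE / ((a - 1) * (b - 1) * (cc - 1))
  s2po <- (SSPO / ((a - 1) * (b - 1)) - MSE) / cc
  s2pt <- (SSPT / ((a - 1) * (cc - 1)) - MSE) / b
  s2ot <- (SSOT / ((b - 1) * (cc - 1)) - MSE) / a
  s2p <- (SSP / (a - 1) - MSE - cc * s2po - b * s2pt) / (b * cc)
  s2o <- (SSO / (b - 1) - MSE - cc * s2po - a * s2ot) / (a * cc)
  c(patient = s2p, observer = s2o, patient_observer = s2po,
    patient_time = s2pt, observer_time = s2ot, residual = MSE)
}

# simulate volume records straight from the three-way ANOVA model
sim_anova_records <- function(n_pat = 6, n_obs = 5, sd_p = 3, sd_o = 1,
                              sd_po = 0, sd_pt = 0, sd_ot = 0, sd_res = 1,
                              time_effect = 0, mean_vol = 20) {
  df <- expand.grid(patient_id = paste0("P", seq_len(n_pat)),
                    observer_id = paste0("o", seq_len(n_obs)),
                    scan_time = c("plan", "rep"), stringsAsFactors = FALSE)
  df$organ <- "sim"
  fp <- factor(df$patient_id); fo <- factor(df$observer_id)
  fpo <- interaction(fp, fo); fpt <- interaction(fp, df$scan_time)
  fot <- interaction(fo, df$scan_time)
  df$volume <- mean_vol + time_effect * (df$scan_time == "rep") +
    rnorm(nlevels(fp), 0, sd_p)[as.integer(fp)] +
    rnorm(nlevels(fo), 0, sd_o)[as.integer(fo)] +
    rnorm(nlevels(fpo), 0, sd_po)[as.integer(fpo)] +
    rnorm(nlevels(fpt), 0, sd_pt)[as.integer(fpt)] +
    rnorm(nlevels(fot), 0, sd_ot)[as.integer(fot)] +
    rnorm(nrow(df), 0, sd_res)
  df
}

# ---- minimal DICOM RT Structure Set writer (explicit VR little endian) ----

dcm_w_u <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                      endian = "little")

dcm_w_el <- function(group, elem, vr, value) {
  if (is.character(value)) value <- charToRaw(value)
  if (length(value) %% 2 == 1)
    value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  tag <- c(dcm_w_u(group, 2), dcm_w_u(elem, 2))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), dcm_w_u(length(value), 4), value)
  } else {
    c(tag, charToRaw(vr), dcm_w_u(length(value), 2), value)
  }
}

dcm_w_item <- function(content) {
  c(dcm_w_u(0xFFFE, 2), dcm_w_u(0xE000, 2), dcm_w_u(length(content), 4),
    content)
}

# rois: list of list(number, name, contours = list of n x 3 matrices)
write_fixture_rtstruct <- function(path, patient_id = "PAT1",
                                   observer = "obsA", rois = list()) {
  ts <- dcm_w_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(dcm_w_el(0x0002, 0x0000, "UL", dcm_w_u(length(ts), 4)), ts)

  ssr <- do.call(c, c(list(raw(0)), lapply(rois, function(r) {
    dcm_w_item(c(dcm_w_el(0x3006, 0x0022, "IS", as.character(r$number)),
                 if (!is.null(r$name))
                   dcm_w_el(0x3006, 0x0026, "LO", r$name)))
  })))
  rcs <- do.call(c, c(list(raw(0)), lapply(rois, function(r) {
    contours <- do.call(c, c(list(raw(0)), lapply(r$contours, function(m) {
      data <- paste(sprintf("%.4f", t(m)), collapse = "\\")
      gtype <- if (is.null(r$geometry)) "CLOSED_PLANAR" else r$geometry
      dcm_w_item(c(dcm_w_el(0x3006, 0x0042, "CS", gtype),
                   dcm_w_el(0x3006, 0x0046, "IS", as.character(nrow(m))),
                   dcm_w_el(0x3006, 0x0050, "DS", data)))
    })))
    dcm_w_item(c(dcm_w_el(0x3006, 0x0040, "SQ", contours),
                 dcm_w_el(0x3006, 0x0084, "IS", as.character(r$number))))
  })))

  body <- c(dcm_w_el(0x0008, 0x1070, "PN", observer),
            dcm_w_el(0x0010, 0x0020, "LO", patient_id),
            dcm_w_el(0x3006, 0x0020, "SQ", ssr),
            dcm_w_el(0x3006, 0x0039, "SQ", rcs))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# square contour as an n x 3 (x, y, z) matrix for the RTSTRUCT writer
square_xyz <- function(side, z, x0 = 0, y0 = 0) {
  cbind(square_poly(side, x0, y0), z)
}
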
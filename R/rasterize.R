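# Geometric substrate: grids, binary masks, scalar fields, grid-free slab
# volumes, even-odd rasterization and signed distance fields.

#' Define a voxel grid
#'
#' `origin` is the (x, y, z) position in mm of the centre of voxel
#' (1, 1, 1); `spacing` the voxel pitch in mm; `shape` the voxel counts.
#' All grid-based containers (masks, scalar fields) share this spec.
#'
#' @param origin numeric length 3 (mm).
#' @param spacing numeric length 3, all > 0 (mm).
#' @param shape integer length 3, all >= 1.
#' @return an `oar_grid` object.
#' @export
oar_grid <- function(origin, spacing, shape) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(shape) == 3)
  if (!all(is.finite(origin))) stop("grid origin must be finite")
  if (!all(is.finite(spacing) & spacing > 0)) stop("grid spacing must be > 0")
  if (!all(shape >= 1)) stop("grid shape components must be >= 1")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "oar_grid")
}

#' @export
print.oar_grid <- function(x, ...) {
  cat(sprintf("<oar_grid> %dx%dx%d @ %gx%gx%g mm, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) && all(a$shape == b$shape)
}

grid_z_planes <- function(grid) grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]

#' Construct a binary occupancy mask on a grid
#'
#' @param grid an [oar_grid()].
#' @param occupancy logical array with dim equal to `grid$shape` (or a
#'   vector of that length).
#' @return an `oar_mask` object.
#' @export
oar_mask <- function(grid, occupancy) {
  stopifnot(inherits(grid, "oar_grid"))
  occupancy <- array(as.logical(occupancy), dim = grid$shape)
  if (anyNA(occupancy)) stop("mask occupancy must be defined for every voxel")
  structure(list(grid = grid, occupancy = occupancy), class = "oar_mask")
}

#' Construct a scalar field on a grid
#'
#' @param grid an [oar_grid()].
#' @param values finite numeric array with dim equal to `grid$shape`.
#' @return an `oar_field` object.
#' @export
oar_field <- function(grid, values) {
  stopifnot(inherits(grid, "oar_grid"))
  values <- array(as.numeric(values), dim = grid$shape)
  if (!all(is.finite(values))) stop("scalar field values must be finite")
  structure(list(grid = grid, values = values), class = "oar_field")
}

#' Voxel volume of a grid in mm^3
#' @param grid an [oar_grid()].
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Mask volume by voxel count, in cm^3
#' @param mask an [oar_mask()].
#' @export
mask_volume <- function(mask) sum(mask$occupancy) * voxel_volume(mask$grid) / 1000

#' Shoelace area of a planar polygon
#'
#' Absolute value of the signed shoelace sum; orientation-independent.
#'
#' @param p polygon matrix, see [validate_polygon()].
#' @return area in mm^2.
#' @export
polygon_area <- function(p) {
  p <- validate_polygon(p)
  n <- nrow(p)
  nxt <- c(seq_len(n)[-1], 1L)
  abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])) / 2
}

# net even-odd area of a slice's polygons: each polygon is signed by the
# parity of the number of other polygons containing its first vertex.
# Exact for non-crossing (possibly nested) parts; crossing parts are only
# handled exactly by the rasterized route.
slice_net_area <- function(polygons) {
  k <- length(polygons)
  areas <- vapply(polygons, polygon_area, numeric(1))
  if (k == 1) return(areas)
  depth <- vapply(seq_len(k), function(i) {
    pt <- polygons[[i]][1, ]
    sum(vapply(seq_len(k)[-i], function(j)
      point_in_polygon(pt[1], pt[2], polygons[[j]]), logical(1)))
  }, integer(1))
  abs(sum(areas * (-1)^depth))
}

# even-odd point-in-polygon with the half-open lower-edge rule
point_in_polygon <- function(x, y, p) {
  n <- nrow(p)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    yi <- p[i, 2]; yj <- p[j, 2]
    if ((yi > y) != (yj > y)) {
      xc <- p[i, 1] + (y - yi) / (yj - yi) * (p[j, 1] - p[i, 1])
      if (x < xc) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Grid-free volume of a delineation
#'
#' Sum over slices of the net even-odd polygon area times the slice
#' spacing (slab rule), converted to cm^3. This is the volume endpoint
#' used for all volume statistics; it carries no voxelization artifacts.
#'
#' @param d a [delineation()].
#' @return volume in cm^3.
#' @export
delineation_volume <- function(d) {
  stopifnot(inherits(d, "delineation"))
  if (length(d$slices) == 0) {
    warning("delineation has no slices; volume 0")
    return(0)
  }
  areas <- vapply(d$slices, function(s) slice_net_area(s$polygons), numeric(1))
  sum(areas) * d$slice_spacing / 1000
}

#' Bounding box of a delineation
#' @param d a [delineation()].
#' @return 2x3 matrix (min row, max row) in mm; z expanded by half a slice.
#' @export
delineation_bbox <- function(d) {
  xs <- unlist(lapply(d$slices, function(s) lapply(s$polygons, function(p) p[, 1])))
  ys <- unlist(lapply(d$slices, function(s) lapply(s$polygons, function(p) p[, 2])))
  zs <- vapply(d$slices, `[[`, numeric(1), "z")
  rbind(c(min(xs), min(ys), min(zs)), c(max(xs), max(ys), max(zs)))
}

#' Default analysis grid for a group of delineations
#'
#' In-plane spacing defaults to 1 mm; axial spacing is taken from the
#' delineations' slice spacing with planes aligned to the contour z
#' levels. A margin (default 8 mm in-plane) keeps surfaces away from the
#' grid border.
#'
#' @param dels list of [delineation()] objects on one scan frame.
#' @param spacing in-plane spacing c(dx, dy) in mm or full c(dx, dy, dz);
#'   an `NA` dz is replaced by the slice spacing.
#' @param margin extra in-plane margin in mm; axially two extra planes are
#'   always added.
#' @return an [oar_grid()].
#' @export
default_grid <- function(dels, spacing = c(1, 1, NA), margin = 8) {
  if (inherits(dels, "delineation")) dels <- list(dels)
  stopifnot(length(dels) >= 1)
  dz <- dels[[1]]$slice_spacing
  if (length(spacing) == 2) spacing <- c(spacing, NA)
  if (is.na(spacing[3])) spacing[3] <- dz
  bb <- Reduce(function(a, b) rbind(pmin(a[1, ], b[1, ]), pmax(a[2, ], b[2, ])),
               lapply(dels, delineation_bbox))
  zs <- sort(unique(unlist(lapply(dels, function(d)
    vapply(d$slices, `[[`, numeric(1), "z")))))
  oz <- min(zs) - 2 * spacing[3]
  nz <- ceiling((max(zs) - oz) / spacing[3]) + 3L
  ox <- bb[1, 1] - margin
  oy <- bb[1, 2] - margin
  nx <- ceiling((bb[2, 1] + margin - ox) / spacing[1]) + 1L
  ny <- ceiling((bb[2, 2] + margin - oy) / spacing[2]) + 1L
  oar_grid(c(ox, oy, oz), spacing, c(nx, ny, nz))
}

#' Rasterize a delineation to a binary mask
#'
#' A voxel is occupied iff its centre lies inside the even-odd interior of
#' the polygons on the slice whose z matches the voxel-centre z plane
#' (nearest plane within half the grid's axial spacing). Edge cases are
#' resolved by a fixed half-open crossing rule so the result is
#' deterministic; self-intersecting polygons are accepted under the
#' even-odd interpretation.
#'
#' @param d a [delineation()].
#' @param grid an [oar_grid()] covering the delineation's bounding box.
#' @return an [oar_mask()].
#' @export
rasterize <- function(d, grid) {
  stopifnot(inherits(d, "delineation"), inherits(grid, "oar_grid"))
  occ <- array(FALSE, dim = grid$shape)
  if (length(d$slices) == 0) return(oar_mask(grid, occ))
  bb <- delineation_bbox(d)
  gmin <- grid$origin
  gmax <- grid$origin + (grid$shape - 1) * grid$spacing
  over <- c("x", "y", "z")[bb[1, ] < gmin - grid$spacing / 2 |
                           bb[2, ] > gmax + grid$spacing / 2]
  if (length(over) > 0)
    stop("delineation bounding box exceeds grid extent on axes: ",
         paste(over, collapse = ", "))
  zp <- grid_z_planes(grid)
  for (s in d$slices) {
    k <- which.min(abs(zp - s$z))
    if (abs(zp[k] - s$z) > grid$spacing[3] / 2 + 1e-9)
      stop("slice z=", s$z, " has no grid plane within dz/2")
    sl <- cpp_rasterize_slice(s$polygons, grid$origin[1], grid$origin[2],
                              grid$spacing[1], grid$spacing[2],
                              grid$shape[1], grid$shape[2])
    occ[, , k] <- occ[, , k] | matrix(sl, grid$shape[1], grid$shape[2])
  }
  oar_mask(grid, occ)
}

# box-mean smoothing of a 0/1 array with zero padding; radii in voxels
box_smooth <- function(a, r = c(1, 1, 0)) {
  d <- dim(a)
  big <- array(0, d + 2 * r)
  big[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3])] <- a
  out <- array(0, d)
  n <- prod(2 * r + 1)
  for (i in -r[1]:r[1]) for (j in -r[2]:r[2]) for (k in -r[3]:r[3])
    out <- out + big[r[1] + i + seq_len(d[1]), r[2] + j + seq_len(d[2]),
                     r[3] + k + seq_len(d[3])]
  out / n
}

# smoothing radii: one voxel in-plane; axially only when dz is no coarser
# than the in-plane pitch (anisotropic CT grids keep exact slice caps)
auto_smooth_radii <- function(grid) {
  rz <- if (grid$spacing[3] <= max(grid$spacing[1:2]) + 1e-9) 1L else 0L
  c(1L, 1L, rz)
}

# Boundary mesh of a mask: marching tetrahedra at 0.5 on the box-smoothed
# occupancy. Falls back to the raw binary field if smoothing erases the
# interior (very thin structures).
mask_boundary_mesh <- function(mask, smooth = NULL) {
  stopifnot(inherits(mask, "oar_mask"))
  occ <- mask$occupancy
  n_occ <- sum(occ)
  if (n_occ == 0 || n_occ == length(occ))
    stop("degenerate mask (empty or full); no boundary surface")
  if (is.null(smooth)) smooth <- auto_smooth_radii(mask$grid)
  f <- if (all(smooth == 0)) occ * 1 else box_smooth(occ * 1, smooth)
  if (max(f) <= 0.5) f <- occ * 1  # smoothing erased a thin structure
  iso_mesh(oar_field(mask$grid, f), iso = 0.5)
}

#' Extract the iso-surface of a scalar field
#'
#' Marching tetrahedra (six tetrahedra per grid cell, consistent diagonal)
#' with linear sub-voxel interpolation; the field is treated as zero one
#' layer outside the grid so surfaces always close. Interior is strictly
#' `value > iso`; field values exactly equal to `iso` are nudged below it.
#'
#' @param field an [oar_field()].
#' @param iso iso level.
#' @return an `oar_mesh`: list with `vertices` (n x 3 mm), `triangles`
#'   (m x 3, 1-based, outward-oriented) and the `grid`.
#' @export
iso_mesh <- function(field, iso = 0.5) {
  stopifnot(inherits(field, "oar_field"))
  v <- field$values
  v[v == iso] <- iso - 1e-9
  g <- field$grid
  res <- cpp_marching_tetra(as.numeric(v), g$shape[1], g$shape[2], g$shape[3],
                            g$origin[1], g$origin[2], g$origin[3],
                            g$spacing[1], g$spacing[2], g$spacing[3], iso)
  structure(list(vertices = res$vertices, triangles = res$triangles, grid = g),
            class = "oar_mesh")
}

#' @export
print.oar_mesh <- function(x, ...) {
  cat(sprintf("<%s> %d vertices, %d triangles\n", class(x)[1],
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Volume enclosed by a triangulated surface
#'
#' Divergence-theorem sum over outward-oriented triangles.
#'
#' @param mesh an `oar_mesh`.
#' @return enclosed volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det) / 6 / 1000
}

# trilinear interpolation of a grid array at points (n x 3, mm);
# values outside the grid are clamped to the border voxel
trilinear <- function(grid, values, pts) {
  t <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")
  out <- numeric(nrow(pts))
  i0 <- pmin(pmax(floor(t[, 1]), 0), grid$shape[1] - 1)
  j0 <- pmin(pmax(floor(t[, 2]), 0), grid$shape[2] - 1)
  k0 <- pmin(pmax(floor(t[, 3]), 0), grid$shape[3] - 1)
  fx <- pmin(pmax(t[, 1] - i0, 0), 1)
  fy <- pmin(pmax(t[, 2] - j0, 0), 1)
  fz <- pmin(pmax(t[, 3] - k0, 0), 1)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- pmin(i0 + di, grid$shape[1] - 1)
    jj <- pmin(j0 + dj, grid$shape[2] - 1)
    kk <- pmin(k0 + dk, grid$shape[3] - 1)
    w <- (if (di == 1) fx else 1 - fx) *
         (if (dj == 1) fy else 1 - fy) *
         (if (dk == 1) fz else 1 - fz)
    out <- out + w * values[cbind(ii + 1, jj + 1, kk + 1)]
  }
  out
}

# signed distance from arbitrary points to a mask's boundary surface;
# negative inside (occupied), positive outside
mask_signed_distance_at <- function(mask, pts, mesh = NULL, smooth = NULL) {
  if (is.null(mesh)) mesh <- mask_boundary_mesh(mask, smooth)
  cell <- 2 * max(mask$grid$spacing)
  d <- cpp_mesh_distance(pts, mesh$vertices, mesh$triangles, cell)
  occ <- trilinear(mask$grid, mask$occupancy * 1, pts)
  ifelse(occ > 0.5, -d, d)
}

#' Signed Euclidean distance field of a binary mask
#'
#' Exact distance in mm from every voxel centre to the mask's boundary
#' surface (the 0.5 iso-surface of the lightly smoothed occupancy),
#' negative inside and positive outside, with anisotropic spacing
#' respected. Occupied voxels always get values <= 0 and unoccupied
#' voxels >= 0.
#'
#' @param mask a non-empty, non-full [oar_mask()].
#' @param smooth integer voxel radii of the box smoothing used to place
#'   the boundary surface; default: 1 in-plane, 1 axially only for
#'   near-isotropic grids.
#' @return an [oar_field()] of signed distances (mm).
#' @export
signed_distance <- function(mask, smooth = NULL) {
  stopifnot(inherits(mask, "oar_mask"))
  n_occ <- sum(mask$occupancy)
  if (n_occ == 0 || n_occ == length(mask$occupancy))
    stop("degenerate mask (empty or full) has no signed distance field")
  g <- mask$grid
  mesh <- mask_boundary_mesh(mask, smooth)
  pts <- as.matrix(expand.grid(
    g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1],
    g$origin[2] + (seq_len(g$shape[2]) - 1) * g$spacing[2],
    g$origin[3] + (seq_len(g$shape[3]) - 1) * g$spacing[3]))
  d <- cpp_mesh_distance(pts, mesh$vertices, mesh$triangles, 2 * max(g$spacing))
  sgn <- ifelse(as.vector(mask$occupancy), -1, 1)
  oar_field(g, array(sgn * d, dim = g$shape))
}
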
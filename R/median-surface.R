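# Median contour surface over observers, per-vertex SD of signed observer
# distances, anatomical sub-region assignment and regional summaries.

#' Median contour surface of several observer masks
#'
#' The mean-occupancy field (fraction of observers covering each voxel) is
#' iso-surfaced at 0.5 with sub-voxel interpolation, which reproduces the
#' majority vote (>= 3 of 5 observers) with a smooth triangulated surface.
#' Occupancy exactly 0.5 (possible for even observer counts) falls outside:
#' the interior is the strict majority.
#'
#' @param masks list of >= 2 [oar_mask()] objects on one grid.
#' @return a `median_surface` (an `oar_mesh` carrying in addition the
#'   majority occupancy array and `n_observers`).
#' @export
compute_median_surface <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 2)
  g <- masks[[1]]$grid
  for (m in masks) {
    stopifnot(inherits(m, "oar_mask"))
    if (!grids_identical(m$grid, g))
      stop("median surface requires masks on the identical grid")
  }
  mean_occ <- Reduce(`+`, lapply(masks, function(m) m$occupancy * 1)) / length(masks)
  majority <- mean_occ > 0.5
  if (!any(majority))
    stop("degenerate median surface: no voxel is covered by a strict majority")
  mesh <- iso_mesh(oar_field(g, mean_occ), iso = 0.5)
  mesh$majority <- majority
  mesh$mean_occupancy <- mean_occ
  mesh$n_observers <- length(masks)
  class(mesh) <- c("median_surface", class(mesh))
  mesh
}

# outward unit normals per vertex: area-weighted mean of incident
# triangle normals (triangles are outward-oriented by construction)
vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  a <- V[F[, 1], , drop = FALSE]
  u <- V[F[, 2], , drop = FALSE] - a
  w <- V[F[, 3], , drop = FALSE] - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])  # 2 * area * unit normal
  n <- matrix(0, nrow(V), 3)
  for (c_ in 1:3) {
    idx <- F[, c_]
    for (d in 1:3) {
      agg <- tapply(fn[, d], idx, sum)
      n[as.integer(names(agg)), d] <- n[as.integer(names(agg)), d] + agg
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Outward normals from the gradient of the (smoothed) occupancy field the
# surface was extracted from: much smoother than per-triangle normals on a
# marching-tetrahedra mesh. Falls back to mesh normals without a field.
surface_normals <- function(mesh) {
  if (is.null(mesh$mean_occupancy)) return(vertex_normals(mesh))
  g <- mesh$grid
  f <- box_smooth(mesh$mean_occupancy, auto_smooth_radii(g))
  V <- mesh$vertices
  n <- matrix(0, nrow(V), 3)
  for (d in 1:3) {
    h <- g$spacing[d]
    e <- rep(0, 3); e[d] <- h
    n[, d] <- (trilinear(g, f, sweep(V, 2, e, "+")) -
                 trilinear(g, f, sweep(V, 2, e, "-"))) / (2 * h)
  }
  n <- -n  # occupancy decreases outward
  len <- sqrt(rowSums(n^2))
  flat <- len < 1e-8
  if (any(flat)) {
    mn <- vertex_normals(mesh)
    n[flat, ] <- mn[flat, ]
    len[flat] <- 1
  }
  n / len
}

# Signed distance from median-surface vertices to an observer's boundary,
# measured along the median surface's outward normal (the classical
# construction for median-contour variability): ray-march the observer's
# smoothed occupancy to bracket the 0.5 crossing, then bisect. Falls back
# to the nearest-point distance where the ray finds no crossing within
# `tmax`.
normal_ray_distance <- function(mask, verts, normals, smooth = NULL,
                                tmax = 15) {
  g <- mask$grid
  if (is.null(smooth)) smooth <- auto_smooth_radii(g)
  f <- if (all(smooth == 0)) mask$occupancy * 1 else
    box_smooth(mask$occupancy * 1, smooth)
  if (max(f) <= 0.5) f <- mask$occupancy * 1
  sample_f <- function(p) trilinear(g, f, p)
  inside <- sample_f(verts) > 0.5
  dir <- normals * ifelse(inside, 1, -1)  # march towards the boundary
  h <- min(g$spacing) / 2
  ts <- seq(h, tmax, by = h)
  prev_t <- rep(0, nrow(verts))
  prev_s <- sample_f(verts) - 0.5
  cross_lo <- rep(NA_real_, nrow(verts))
  cross_hi <- rep(NA_real_, nrow(verts))
  s_lo <- rep(NA_real_, nrow(verts))
  for (t in ts) {
    open <- which(is.na(cross_lo))
    if (length(open) == 0) break
    s <- sample_f(verts[open, , drop = FALSE] + t * dir[open, , drop = FALSE]) - 0.5
    hit <- sign(s) != sign(prev_s[open]) & s != prev_s[open]
    if (any(hit)) {
      hi <- open[hit]
      cross_lo[hi] <- prev_t[hi]
      cross_hi[hi] <- t
      s_lo[hi] <- prev_s[hi]
    }
    prev_t[open] <- t
    prev_s[open] <- s
  }
  out <- rep(NA_real_, nrow(verts))
  solved <- which(!is.na(cross_lo))
  if (length(solved) > 0) {
    lo <- cross_lo[solved]; hi <- cross_hi[solved]; sl <- s_lo[solved]
    for (it in 1:25) {
      mid <- (lo + hi) / 2
      sm <- sample_f(verts[solved, , drop = FALSE] +
                       mid * dir[solved, , drop = FALSE]) - 0.5
      same <- sign(sm) == sign(sl)
      lo[same] <- mid[same]
      sl[same] <- sm[same]
      hi[!same] <- mid[!same]
    }
    out[solved] <- (lo + hi) / 2
  }
  d <- ifelse(inside, -out, out)
  if (anyNA(d)) {
    miss <- which(is.na(d))
    d[miss] <- mask_signed_distance_at(mask, verts[miss, , drop = FALSE],
                                       smooth = smooth)
  }
  d
}

# per-vertex weights: one third of the area of the incident triangles
vertex_areas <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  a <- V[F[, 1], , drop = FALSE]
  u <- V[F[, 2], , drop = FALSE] - a
  w <- V[F[, 3], , drop = FALSE] - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  ta <- sqrt(rowSums(cr^2)) / 2
  wts <- numeric(nrow(V))
  for (c_ in 1:3) {
    agg <- tapply(ta, F[, c_], sum)
    wts[as.integer(names(agg))] <- wts[as.integer(names(agg))] + agg
  }
  wts / 3
}

#' Local and global 3D SD of observer distances to the median surface
#'
#' For every median-surface vertex, the signed distance (mm, positive
#' outside the observer's structure) to each observer's boundary surface
#' is evaluated; the per-vertex SD is the sample SD (n - 1 denominator) of
#' the n observer distances about their mean. The global 3D SD is the
#' unweighted mean of the per-vertex SDs (area-weighted variant by
#' `weighted = TRUE`). Degenerate observer masks are excluded with a
#' warning.
#'
#' Two distance constructions are offered. `"normal"` (default, the
#' classical median-contour construction) measures along the median
#' surface's outward normal, so an observer surface offset radially by d
#' scores d regardless of surface roughness. `"nearest"` evaluates the
#' observer's signed Euclidean distance field exactly at the vertex; it is
#' a lower bound on the normal-ray distance and systematically smaller on
#' rough surfaces.
#'
#' @param surface a [compute_median_surface()] result.
#' @param masks the observer masks (same grid as the surface).
#' @param signed use signed distances (default); `FALSE` uses absolute
#'   distances.
#' @param weighted area-weight the global mean over vertices.
#' @param method `"normal"` or `"nearest"` (see above).
#' @param smooth smoothing radii passed to the observer boundary surfaces.
#' @return a `local_sd_field`: per-vertex `sd` (mm), `global_sd`,
#'   `n_observers`, the per-vertex `weights` used.
#' @export
local_sd <- function(surface, masks, signed = TRUE, weighted = FALSE,
                     method = c("normal", "nearest"), smooth = NULL) {
  stopifnot(inherits(surface, "oar_mesh"))
  method <- match.arg(method)
  pts <- surface$vertices
  normals <- if (method == "normal") surface_normals(surface) else NULL
  dmat <- matrix(NA_real_, nrow(pts), 0)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!grids_identical(m$grid, surface$grid))
      stop("observer mask ", i, " is not on the surface's grid")
    n_occ <- sum(m$occupancy)
    if (n_occ == 0 || n_occ == length(m$occupancy)) {
      warning("observer mask ", i, " is degenerate (empty or full); excluded")
      next
    }
    d <- if (method == "normal")
      normal_ray_distance(m, pts, normals, smooth = smooth)
    else mask_signed_distance_at(m, pts, smooth = smooth)
    if (!signed) d <- abs(d)
    dmat <- cbind(dmat, d)
  }
  if (ncol(dmat) < 2)
    stop("local SD needs at least 2 non-degenerate observer masks")
  mu <- rowMeans(dmat)
  sdv <- sqrt(rowSums((dmat - mu)^2) / (ncol(dmat) - 1))
  w <- if (weighted) vertex_areas(surface) else rep(1, nrow(pts))
  structure(list(sd = sdv, global_sd = sum(w * sdv) / sum(w),
                 n_observers = ncol(dmat), weights = w, weighted = weighted),
            class = "local_sd_field")
}

#' @export
print.local_sd_field <- function(x, ...) {
  cat(sprintf("<local_sd_field> %d vertices, %d observers, global 3D SD %.2f mm\n",
              length(x$sd), x$n_observers, x$global_sd))
  invisible(x)
}

#' Sub-region rule set for an organ surface
#'
#' Three rule families cover the studied organs:
#' * `"caps"`: the upper `cranial_slices` and lower `caudal_slices`
#'   z-planes become the cranial and caudal sub-regions (5 slices for
#'   parotid-type organs, 3 for submandibular-type, 1 for the glottic
#'   larynx);
#' * `"landmarks"`: longitudinal bands split at user-supplied vertebral
#'   z-positions `landmarks = c(z_c1, z_t1)` (strictly decreasing):
#'   cranial above C1-bottom, medial C2 to T1, caudal from T2 on;
#' * `"closed_caudal"`: the caudal sub-region is the maximal contiguous
#'   run of "unclosed" bottom planes — planes whose majority mask has no
#'   background fully enclosed by foreground (no ring); used for the
#'   thyroid cartilage.
#'
#' Remaining (non-cap) vertices are split into four axial quadrants about
#' the per-slice centroid when `quadrants = TRUE`, with the medial
#' quadrant facing the patient midline according to laterality (for
#' midline organs both x-quadrants are labelled lateral).
#'
#' @param organ organ label the rule set applies to.
#' @param rule one of `"caps"`, `"landmarks"`, `"closed_caudal"`.
#' @param cranial_slices,caudal_slices cap thickness in slices (>= 1).
#' @param landmarks numeric c(z_c1, z_t1) in mm, required for
#'   `"landmarks"`.
#' @param quadrants split non-cap vertices into axial quadrants.
#' @param caps_exclusive caps take precedence over quadrants (the
#'   alternative keeps the quadrant label of every vertex in the
#'   `"quadrant"` attribute of [assign_regions()]).
#' @return a `region_spec` object.
#' @export
region_spec <- function(organ, rule = c("caps", "landmarks", "closed_caudal"),
                        cranial_slices = 3L, caudal_slices = 3L,
                        landmarks = NULL, quadrants = TRUE,
                        caps_exclusive = TRUE) {
  rule <- match.arg(rule)
  if (rule == "landmarks") {
    if (is.null(landmarks) || length(landmarks) != 2 || !all(is.finite(landmarks)))
      stop("landmarks rule needs landmarks = c(z_c1, z_t1) in mm")
    if (landmarks[1] <= landmarks[2])
      stop("landmarks must be strictly decreasing in z: (C1_bottom, T1_bottom)")
  }
  if (cranial_slices < 1 || caudal_slices < 1)
    stop("cap slice counts must be >= 1")
  structure(list(organ = organ, rule = rule,
                 cranial_slices = as.integer(cranial_slices),
                 caudal_slices = as.integer(caudal_slices),
                 landmarks = landmarks, quadrants = isTRUE(quadrants),
                 caps_exclusive = isTRUE(caps_exclusive)),
            class = "region_spec")
}

# TRUE if the logical plane has a background component not connected to the
# plane border (a ring / closed structure in the transverse view)
has_enclosed_background <- function(m) {
  bg <- !m
  if (!any(bg)) return(FALSE)
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[1, ] <- bg[1, ]; reach[nrow(m), ] <- bg[nrow(m), ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, ncol(m)] <- reach[, ncol(m)] | bg[, ncol(m)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(m), ]
    grown[-nrow(m), ] <- grown[-nrow(m), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(m)]
    grown[, -ncol(m)] <- grown[, -ncol(m)] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  any(bg & !reach)
}

#' Assign anatomical sub-region labels to median-surface vertices
#'
#' Every vertex receives exactly one label from cranial, caudal, medial,
#' lateral, anterior, posterior according to the organ's [region_spec()].
#' Slice membership snaps the vertex z to the grid's z-planes (cap-face
#' vertices halfway between planes belong to the occupied plane). The
#' quadrant label of every vertex is additionally returned in the
#' `"quadrant"` attribute.
#'
#' @param surface a [compute_median_surface()] result.
#' @param spec a [region_spec()] matching the surface's organ.
#' @param laterality `"left"`, `"right"` or `"midline"`.
#' @return character vector of labels, one per vertex.
#' @export
assign_regions <- function(surface, spec, laterality = "midline") {
  stopifnot(inherits(surface, "oar_mesh"), inherits(spec, "region_spec"))
  laterality <- match.arg(laterality, LATERALITIES)
  V <- surface$vertices
  g <- surface$grid
  nv <- nrow(V)
  # snap to the nearest plane, clamped to the planes the surface encloses so
  # that cap-face vertices (half a spacing beyond the outermost occupied
  # plane) belong to that outermost slice
  t3 <- (V[, 3] - g$origin[3]) / g$spacing[3]
  k <- floor(t3 + 0.5 - 1e-9)
  k <- pmin(pmax(k, ceiling(min(t3) - 1e-6)), floor(max(t3) + 1e-6))
  planes <- sort(unique(k))
  np <- length(planes)
  labels <- rep(NA_character_, nv)

  if (spec$rule == "landmarks") {
    labels[V[, 3] >= spec$landmarks[1]] <- "cranial"
    labels[V[, 3] <= spec$landmarks[2]] <- "caudal"
    labels[is.na(labels)] <- "medial"
  } else {
    if (spec$rule == "caps") {
      ncr <- spec$cranial_slices; nca <- spec$caudal_slices
      if (np < ncr + nca) {
        warning("surface has fewer z-planes (", np, ") than the cap slices; ",
                "splitting caps at the midplane")
        mid <- stats::median(range(planes))
        labels[k > mid] <- "cranial"
        labels[k <= mid] <- "caudal"
      } else {
        labels[k %in% planes[(np - ncr + 1):np]] <- "cranial"
        labels[k %in% planes[1:nca]] <- "caudal"
      }
    } else {  # closed_caudal
      if (is.null(surface$majority))
        stop("closed-slice rule needs the surface's majority occupancy")
      closed <- vapply(planes, function(p)
        has_enclosed_background(surface$majority[, , p + 1]), logical(1))
      run <- 0L
      for (i in seq_len(np)) {
        if (closed[i]) break
        run <- i
      }
      if (run > 0) labels[k %in% planes[1:run]] <- "caudal"
      rest <- planes[planes > if (run > 0) planes[run] else -Inf]
      nrest <- length(rest)
      ncr <- min(spec$cranial_slices, nrest)
      if (ncr > 0) labels[k %in% rest[(nrest - ncr + 1):nrest]] <- "cranial"
    }
  }

  # axial quadrants about the per-slice centroid
  quad <- rep(NA_character_, nv)
  for (p in planes) {
    on_p <- which(k == p)
    cx <- mean(V[on_p, 1]); cy <- mean(V[on_p, 2])
    dx <- V[on_p, 1] - cx; dy <- V[on_p, 2] - cy
    xside <- abs(dx) >= abs(dy)
    lab <- character(length(on_p))
    # LPS: +x patient-left, +y posterior
    med_sign <- switch(laterality, left = -1, right = +1, midline = 0)
    lab[xside] <- if (med_sign == 0) "lateral" else
      ifelse(sign(dx[xside]) == med_sign, "medial", "lateral")
    lab[!xside] <- ifelse(dy[!xside] < 0, "anterior", "posterior")
    quad[on_p] <- lab
  }
  caps <- labels
  if (spec$quadrants) {
    if (spec$caps_exclusive) {
      labels[is.na(labels)] <- quad[is.na(labels)]
    } else {
      labels <- quad  # caps still reported via the "cap" attribute
    }
  } else {
    labels[is.na(labels)] <- "body"
  }
  attr(labels, "quadrant") <- quad
  attr(labels, "cap") <- caps
  labels
}

#' Regional 3D SD
#'
#' Unweighted mean of the per-vertex SD within each sub-region label;
#' regions without vertices are omitted.
#'
#' @param field a [local_sd()] result.
#' @param labels per-vertex labels from [assign_regions()].
#' @return named numeric vector of regional SDs (mm).
#' @export
regional_sd <- function(field, labels) {
  stopifnot(inherits(field, "local_sd_field"))
  if (length(labels) != length(field$sd))
    stop("labels must cover all surface vertices")
  out <- tapply(field$sd, as.character(labels), mean)
  setNames(as.numeric(out), names(out))
}

#' Export a surface as ASCII PLY
#'
#' Vertices, triangles and optional per-vertex SD (`quality`) and region
#' (coded `region` property plus a comment mapping codes to labels).
#'
#' @param mesh an `oar_mesh`.
#' @param path output file.
#' @param sd optional per-vertex SD values.
#' @param region optional per-vertex region labels.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, sd = NULL, region = NULL) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  hdr <- c("ply", "format ascii 1.0", "comment oarvar surface export")
  props <- c("property float x", "property float y", "property float z")
  cols <- list(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  if (!is.null(sd)) {
    props <- c(props, "property float quality")
    cols <- c(cols, list(sd))
  }
  if (!is.null(region)) {
    lev <- sort(unique(as.character(region)))
    hdr <- c(hdr, paste0("comment region ", seq_along(lev) - 1, " = ", lev))
    props <- c(props, "property int region")
    cols <- c(cols, list(match(as.character(region), lev) - 1L))
  }
  hdr <- c(hdr, paste("element vertex", nv), props,
           paste("element face", nt),
           "property list uchar int vertex_indices", "end_header")
  vtx <- do.call(paste, lapply(cols, function(x)
    if (is.integer(x)) sprintf("%d", x) else sprintf("%.6f", x)))
  fc <- sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L)
  writeLines(c(hdr, vtx, fc), path)
  invisible(path)
}
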
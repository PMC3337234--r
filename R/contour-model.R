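#' @useDynLib oarvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd setNames pchisq aggregate
#' @importFrom utils write.csv combn
"_PACKAGE"

SCAN_TIMES <- c("plan", "rep")
LATERALITIES <- c("left", "right", "midline")

#' Validate a planar contour polygon
#'
#' Polygons are ordered (x, y) vertex matrices in mm, implicitly closed.
#' A polygon must have at least three vertices, finite coordinates, and no
#' two identical consecutive vertices. An explicitly repeated first vertex
#' at the end is dropped with a warning (both dialects occur in the wild).
#'
#' @param p numeric matrix with two columns (x, y in mm).
#' @param where character context used in error messages.
#' @return the validated (possibly trimmed) polygon matrix.
#' @export
validate_polygon <- function(p, where = "polygon") {
  if (!is.matrix(p) || ncol(p) != 2 || !is.numeric(p))
    stop(where, ": polygon must be a numeric matrix with 2 columns")
  if (!all(is.finite(p)))
    stop(where, ": polygon has non-finite coordinates")
  n <- nrow(p)
  if (n >= 4 && all(p[1, ] == p[n, ])) {
    warning(where, ": explicitly closed polygon; dropping repeated first vertex")
    p <- p[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3) stop(where, ": polygon has fewer than 3 vertices")
  nxt <- c(seq_len(n)[-1], 1L)
  dup <- which(p[, 1] == p[nxt, 1] & p[, 2] == p[nxt, 2])
  dup <- setdiff(dup, n)  # closing edge identity already handled above
  if (length(dup) > 0)
    stop(where, ": identical consecutive vertices at position ", dup[1])
  unname(p)
}

#' Construct one contour slice
#'
#' All polygons of a slice live at a single axial position `z` (mm).
#' Multiple and nested polygons are interpreted under the even-odd rule.
#'
#' @param z axial position in mm.
#' @param polygons list of polygon matrices (see [validate_polygon()]).
#' @return a `contour_slice` list.
#' @export
contour_slice <- function(z, polygons) {
  if (length(z) != 1 || !is.finite(z)) stop("slice z must be a single finite number")
  if (!is.list(polygons) || length(polygons) == 0)
    stop("slice at z=", z, " must carry at least one polygon")
  polygons <- lapply(seq_along(polygons), function(i)
    validate_polygon(polygons[[i]], where = sprintf("slice z=%g polygon %d", z, i)))
  structure(list(z = as.numeric(z), polygons = polygons), class = "contour_slice")
}

#' Construct one observer's delineation of one organ on one scan
#'
#' A delineation is a stack of planar contour slices at fixed z levels in
#' the DICOM LPS patient frame (+x patient-left, +y posterior, +z cranial),
#' one cell of the patient x scan x observer x organ design. Slices are
#' normalized to ascending z; z values must be strictly increasing and
#' consecutive occupied slices must sit an integer multiple of
#' `slice_spacing` apart.
#'
#' @param patient_id,observer_id,organ character identifiers.
#' @param scan_time `"plan"` (planning CT) or `"rep"` (repeat CT).
#' @param laterality `"left"`, `"right"` or `"midline"`.
#' @param slices list of [contour_slice()] objects (any order).
#' @param slice_spacing axial slice spacing in mm (> 0).
#' @return a `delineation` object.
#' @export
delineation <- function(patient_id, scan_time, observer_id, organ,
                        laterality, slices, slice_spacing) {
  for (f in c("patient_id", "observer_id", "organ")) {
    v <- get(f)
    if (!is.character(v) || length(v) != 1 || !nzchar(v))
      stop(f, " must be a non-empty string")
  }
  scan_time <- match.arg(scan_time, SCAN_TIMES)
  laterality <- match.arg(laterality, LATERALITIES)
  if (length(slice_spacing) != 1 || !is.finite(slice_spacing) || slice_spacing <= 0)
    stop("slice_spacing must be a single positive number")
  slices <- lapply(slices, function(s) {
    if (!inherits(s, "contour_slice")) s <- contour_slice(s$z, s$polygons)
    s
  })
  zs <- vapply(slices, `[[`, numeric(1), "z")
  where <- sprintf("delineation %s/%s/%s/%s", patient_id, scan_time, observer_id, organ)
  if (anyDuplicated(zs))
    stop(where, ": duplicate slice z value ", zs[duplicated(zs)][1])
  o <- order(zs)
  slices <- slices[o]
  zs <- zs[o]
  if (length(zs) > 1) {
    steps <- diff(zs) / slice_spacing
    if (any(abs(steps - round(steps)) > 1e-6))
      stop(where, ": slice z gaps are not integer multiples of slice_spacing")
  }
  structure(list(patient_id = patient_id, scan_time = scan_time,
                 observer_id = observer_id, organ = organ,
                 laterality = laterality, slices = slices,
                 slice_spacing = as.numeric(slice_spacing)),
            class = "delineation")
}

#' Construct a set of delineations
#'
#' The (patient, scan_time, observer, organ) key must be unique across the
#' set; all delineations of one (patient, scan) are assumed to share one
#' patient coordinate frame. `metadata` is a free-form provenance record;
#' the element `metadata$excluded` (a list of records with fields drawn
#' from `patient_id`, `organ`, `scan_time`, `observer_id`; missing fields
#' are wildcards) flags structures to omit from volume analysis.
#'
#' @param delineations list of [delineation()] objects.
#' @param metadata named list of provenance values.
#' @return a `delineation_set` object.
#' @export
delineation_set <- function(delineations = list(), metadata = list()) {
  stopifnot(is.list(delineations), is.list(metadata))
  for (d in delineations)
    if (!inherits(d, "delineation")) stop("delineations must be delineation objects")
  keys <- vapply(delineations, function(d)
    paste(d$patient_id, d$scan_time, d$observer_id, d$organ, sep = "\r"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (patient, scan_time, observer, organ) key: ",
         gsub("\r", "/", keys[duplicated(keys)][1]))
  structure(list(metadata = metadata, delineations = delineations),
            class = "delineation_set")
}

#' @export
print.delineation_set <- function(x, ...) {
  cat(sprintf("<delineation_set> %d delineations\n", length(x$delineations)))
  if (length(x$delineations)) {
    df <- delineation_index(x)
    cat(sprintf("  patients: %d | scans: %s | observers: %d | organs: %d\n",
                length(unique(df$patient_id)),
                paste(sort(unique(df$scan_time)), collapse = ","),
                length(unique(df$observer_id)), length(unique(df$organ))))
  }
  invisible(x)
}

#' @export
print.delineation <- function(x, ...) {
  cat(sprintf("<delineation> %s %s %s %s (%s): %d slices, dz=%g mm\n",
              x$patient_id, x$scan_time, x$observer_id, x$organ,
              x$laterality, length(x$slices), x$slice_spacing))
  invisible(x)
}

#' Tabulate the design cells of a delineation set
#'
#' @param set a [delineation_set()].
#' @return data.frame with one row per delineation: patient_id, scan_time,
#'   observer_id, organ, laterality, n_slices.
#' @export
delineation_index <- function(set) {
  stopifnot(inherits(set, "delineation_set"))
  do.call(rbind, c(list(data.frame(patient_id = character(), scan_time = character(),
                                   observer_id = character(), organ = character(),
                                   laterality = character(), n_slices = integer())),
                   lapply(set$delineations, function(d)
                     data.frame(patient_id = d$patient_id, scan_time = d$scan_time,
                                observer_id = d$observer_id, organ = d$organ,
                                laterality = d$laterality,
                                n_slices = length(d$slices)))))
}

# TRUE for delineations matched by any exclusion record in the metadata
is_excluded <- function(d, excluded) {
  if (is.null(excluded) || length(excluded) == 0) return(FALSE)
  for (e in excluded) {
    hit <- TRUE
    for (f in c("patient_id", "organ", "scan_time", "observer_id"))
      if (!is.null(e[[f]]) && !identical(e[[f]], d[[f]])) { hit <- FALSE; break }
    if (hit) return(TRUE)
  }
  FALSE
}
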
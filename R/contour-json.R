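# Canonical JSON interchange format for contour sets.
#
# Layout:
#   {"delineations": [{"laterality", "observer_id", "organ", "patient_id",
#                      "scan_time", "slice_spacing_mm",
#                      "slices": [{"polygons": [[[x,y],...],...], "z_mm"}]}],
#    "metadata": {...}}
# Keys are emitted in sorted order and every float is printed with exactly
# six decimals, so re-exporting an unchanged set is byte-identical.

fmt_num <- function(x) {
  if (!all(is.finite(x))) stop("non-finite coordinate refused in canonical JSON")
  s <- sprintf("%.6f", x)
  s[s == "-0.000000"] <- "0.000000"
  s
}

json_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub('"', '\\\\"', s)
  s <- gsub("\n", "\\\\n", s)
  s <- gsub("\r", "\\\\r", s)
  s <- gsub("\t", "\\\\t", s)
  s
}

# canonical serializer for free-form metadata (sorted keys, 6-decimal floats,
# integers printed as integers)
to_canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      o <- order(nm)
      parts <- vapply(o, function(i)
        paste0('"', json_escape(nm[i]), '":', to_canonical_json(x[[i]])), character(1))
      return(paste0("{", paste(parts, collapse = ","), "}"))
    }
    parts <- vapply(x, to_canonical_json, character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (length(x) != 1) {
    parts <- vapply(seq_along(x), function(i) to_canonical_json(x[i]), character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (is.character(x)) return(paste0('"', json_escape(x), '"'))
  if (is.logical(x)) return(if (isTRUE(x)) "true" else "false")
  if (is.numeric(x)) {
    if (is.integer(x) || (is.finite(x) && x == round(x) && abs(x) < 1e15))
      return(sprintf("%d", as.integer(x)))
    return(fmt_num(x))
  }
  stop("unsupported metadata value of class ", class(x)[1])
}

#' Write a delineation set to canonical JSON
#'
#' Emits sorted keys and fixed 6-decimal float precision so that an
#' unchanged set re-exports byte-identically. Non-finite coordinates are
#' refused.
#'
#' @param set a [delineation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contour_set <- function(set, path) {
  stopifnot(inherits(set, "delineation_set"))
  dels <- vapply(set$delineations, function(d) {
    slices <- vapply(d$slices, function(s) {
      polys <- vapply(s$polygons, function(p) {
        validate_polygon(p)
        rows <- paste0("[", fmt_num(p[, 1]), ",", fmt_num(p[, 2]), "]")
        paste0("[", paste(rows, collapse = ","), "]")
      }, character(1))
      paste0('{"polygons":[', paste(polys, collapse = ","),
             '],"z_mm":', fmt_num(s$z), "}")
    }, character(1))
    paste0('{"laterality":"', json_escape(d$laterality),
           '","observer_id":"', json_escape(d$observer_id),
           '","organ":"', json_escape(d$organ),
           '","patient_id":"', json_escape(d$patient_id),
           '","scan_time":"', json_escape(d$scan_time),
           '","slice_spacing_mm":', fmt_num(d$slice_spacing),
           ',"slices":[', paste(slices, collapse = ","), "]}")
  }, character(1))
  txt <- paste0('{"delineations":[', paste(dels, collapse = ","),
                '],"metadata":', to_canonical_json(set$metadata), "}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(txt)), con)
  invisible(path)
}

#' Load a delineation set from the JSON contour format
#'
#' Reads and fully validates a contour file written by
#' [write_contour_set()] (or any conforming producer). Slice ordering is
#' normalized to ascending z; schema or invariant violations raise errors
#' naming the offending record.
#'
#' @param path input file path.
#' @return a validated [delineation_set()].
#' @export
load_contour_set <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("contour file parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(raw) || is.null(raw$delineations))
    stop("contour file schema error: missing top-level 'delineations'")
  dels <- lapply(seq_along(raw$delineations), function(i) {
    r <- raw$delineations[[i]]
    need <- c("patient_id", "scan_time", "observer_id", "organ",
              "laterality", "slice_spacing_mm", "slices")
    miss <- setdiff(need, names(r))
    if (length(miss) > 0)
      stop(sprintf("delineation %d: missing field(s) %s", i,
                   paste(miss, collapse = ", ")))
    slices <- lapply(r$slices, function(s) {
      if (is.null(s$z_mm) || is.null(s$polygons))
        stop(sprintf("delineation %d: slice missing z_mm or polygons", i))
      polys <- lapply(s$polygons, function(p) {
        m <- do.call(rbind, lapply(p, function(pt) as.numeric(unlist(pt))))
        if (is.null(m) || ncol(m) != 2)
          stop(sprintf("delineation %d: malformed polygon at z=%s", i, s$z_mm))
        m
      })
      contour_slice(as.numeric(s$z_mm), polys)
    })
    delineation(r$patient_id, r$scan_time, r$observer_id, r$organ,
                r$laterality, slices, as.numeric(r$slice_spacing_mm))
  })
  md <- raw$metadata
  if (is.null(md)) md <- list()
  delineation_set(dels, md)
}
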
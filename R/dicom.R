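# Minimal read-only DICOM parser, sufficient for RT Structure Sets.
# Supports explicit and implicit VR little endian transfer syntaxes and
# nested sequences with defined or undefined lengths. This is deliberately
# a tiny adapter, not a general DICOM implementation.

dcm_u16 <- function(raw, pos) {
  readBin(raw[pos:(pos + 1L)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
dcm_u32 <- function(raw, pos) {
  v <- readBin(raw[pos:(pos + 3L)], "integer", size = 4, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
DCM_STR_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
                 "SH", "ST", "TM", "UI", "UC", "UR", "UT")
# tags parsed as sequences under implicit VR
DCM_SQ_TAGS <- c("30060010", "30060012", "30060014", "30060016", "30060020",
                 "30060039", "30060040", "30060080", "30060086", "300a0010")

# DICOM strings are padded with trailing spaces or NUL bytes
dcm_rawstr <- function(v) {
  if (is.raw(v)) v <- rawToChar(v[v != as.raw(0)])
  sub(" +$", "", v)
}

# parse one element at pos; returns list(tag, value, pos) with pos advanced
dcm_element <- function(raw, pos, explicit) {
  group <- dcm_u16(raw, pos)
  elem <- dcm_u16(raw, pos + 2L)
  tag <- sprintf("%04x%04x", group, elem)
  pos <- pos + 4L
  vr <- NULL
  if (group == 0xFFFE) {  # item / delimiter tags carry no VR
    len <- dcm_u32(raw, pos)
    pos <- pos + 4L
  } else if (explicit) {
    vr <- rawToChar(raw[pos:(pos + 1L)])
    if (vr %in% DCM_LONG_VRS) {
      len <- dcm_u32(raw, pos + 4L)
      pos <- pos + 8L
    } else {
      len <- dcm_u16(raw, pos + 2L)
      pos <- pos + 4L
    }
  } else {
    len <- dcm_u32(raw, pos)
    pos <- pos + 4L
    vr <- if (tag %in% DCM_SQ_TAGS || len == 4294967295) "SQ" else "UN"
  }

  if (!is.null(vr) && vr == "SQ" || (group != 0xFFFE && len == 4294967295)) {
    items <- list()
    if (len == 4294967295) {
      repeat {
        itag <- sprintf("%04x%04x", dcm_u16(raw, pos), dcm_u16(raw, pos + 2L))
        if (itag == "fffee0dd") { pos <- pos + 8L; break }
        it <- dcm_item(raw, pos, explicit)
        items[[length(items) + 1L]] <- it$value
        pos <- it$pos
      }
    } else {
      end <- pos + len
      while (pos < end) {
        it <- dcm_item(raw, pos, explicit)
        items[[length(items) + 1L]] <- it$value
        pos <- it$pos
      }
    }
    return(list(tag = tag, value = items, pos = pos))
  }

  value <- raw[seq_len(len) + pos - 1L]
  if (!is.null(vr) && vr %in% DCM_STR_VRS) value <- dcm_rawstr(value)
  if (!is.null(vr) && vr == "US") value <- dcm_u16(raw, pos)
  if (!is.null(vr) && vr == "UL") value <- dcm_u32(raw, pos)
  list(tag = tag, value = value, pos = pos + len)
}

# parse one sequence item starting at its (FFFE,E000) tag
dcm_item <- function(raw, pos, explicit) {
  itag <- sprintf("%04x%04x", dcm_u16(raw, pos), dcm_u16(raw, pos + 2L))
  if (itag != "fffee000") stop("RTSTRUCT parse error: expected item tag, got ", itag)
  len <- dcm_u32(raw, pos + 4L)
  pos <- pos + 8L
  ds <- list()
  if (len == 4294967295) {
    repeat {
      t <- sprintf("%04x%04x", dcm_u16(raw, pos), dcm_u16(raw, pos + 2L))
      if (t == "fffee00d") { pos <- pos + 8L; break }
      el <- dcm_element(raw, pos, explicit)
      ds[[el$tag]] <- el$value
      pos <- el$pos
    }
  } else {
    end <- pos + len
    while (pos < end) {
      el <- dcm_element(raw, pos, explicit)
      ds[[el$tag]] <- el$value
      pos <- el$pos
    }
  }
  list(value = ds, pos = pos)
}

dcm_parse <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  ts <- "1.2.840.10008.1.2.1"
  # file meta group (0002,xxxx) is always explicit little endian
  while (pos + 7L <= length(raw) && dcm_u16(raw, pos) == 2L) {
    el <- dcm_element(raw, pos, explicit = TRUE)
    if (el$tag == "00020010") ts <- el$value
    pos <- el$pos
  }
  explicit <- switch(ts,
                     "1.2.840.10008.1.2" = FALSE,
                     "1.2.840.10008.1.2.1" = TRUE,
                     stop("unsupported DICOM transfer syntax: ", ts))
  ds <- list()
  while (pos + 7L <= length(raw)) {
    el <- dcm_element(raw, pos, explicit)
    ds[[el$tag]] <- el$value
    pos <- el$pos
  }
  ds
}

dcm_string <- function(v) {
  if (is.raw(v)) dcm_rawstr(v) else dcm_rawstr(as.character(v))
}

infer_laterality <- function(name) {
  n <- tolower(name)
  if (grepl("(^|[^a-z])l(eft)?([^a-z]|$)|_l$|left", n)) return("left")
  if (grepl("(^|[^a-z])r(ight)?([^a-z]|$)|_r$|right", n)) return("right")
  "midline"
}

#' Load a DICOM RT Structure Set as a delineation set
#'
#' Read-only adapter for the clinical interchange format. Each ROI becomes
#' one [delineation()]; contour triplets (x, y, z) are taken as LPS mm and
#' grouped into axial slices. Only planar axial contours are supported;
#' a contour whose points do not share one z raises an
#' unsupported-geometry error. ROIs without a name are skipped with a
#' warning.
#'
#' @param path RT Structure Set file.
#' @param ct_slice_spacing axial spacing of the underlying CT in mm.
#' @param scan_time scan-time label to assign (`"plan"` or `"rep"`).
#' @param patient_tag,observer_tag DICOM tags (8 hex digits, lowercase)
#'   from which patient and observer identifiers are read; defaults are
#'   PatientID (0010,0020) and OperatorsName (0008,1070).
#' @param laterality optional named character vector mapping ROI names to
#'   lateralities; unmapped names are inferred from the ROI name.
#' @return a [delineation_set()].
#' @export
load_rtstruct <- function(path, ct_slice_spacing, scan_time = "plan",
                          patient_tag = "00100020",
                          observer_tag = "00081070",
                          laterality = NULL) {
  ds <- dcm_parse(path)
  patient <- if (!is.null(ds[[patient_tag]])) dcm_string(ds[[patient_tag]]) else "unknown"
  observer <- if (!is.null(ds[[observer_tag]])) dcm_string(ds[[observer_tag]]) else "unknown"

  roi_names <- list()
  for (item in ds[["30060020"]]) {  # StructureSetROISequence
    num <- dcm_string(item[["30060022"]])
    nm <- item[["30060026"]]
    roi_names[[num]] <- if (is.null(nm)) NA_character_ else dcm_string(nm)
  }

  dels <- list()
  for (item in ds[["30060039"]]) {  # ROIContourSequence
    num <- dcm_string(item[["30060084"]])
    nm <- roi_names[[num]]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) {
      warning("RTSTRUCT ROI ", num, " has no name; skipped")
      next
    }
    by_z <- list()
    for (cs in item[["30060040"]]) {  # ContourSequence
      gtype <- if (!is.null(cs[["30060042"]])) dcm_string(cs[["30060042"]]) else "CLOSED_PLANAR"
      if (!gtype %in% c("CLOSED_PLANAR", "CLOSEDPLANAR_XOR"))
        stop("RTSTRUCT ROI ", nm, ": unsupported contour geometry ", gtype)
      pts <- as.numeric(strsplit(dcm_string(cs[["30060050"]]), "\\\\")[[1]])
      m <- matrix(pts, ncol = 3, byrow = TRUE)
      if (diff(range(m[, 3])) > 1e-3)
        stop("RTSTRUCT ROI ", nm, ": non-axial contour plane (unsupported geometry)")
      zkey <- sprintf("%.3f", m[1, 3])
      by_z[[zkey]] <- c(by_z[[zkey]], list(m[, 1:2, drop = FALSE]))
    }
    if (length(by_z) == 0) next
    slices <- lapply(names(by_z), function(zk)
      contour_slice(as.numeric(zk), by_z[[zk]]))
    lat <- if (!is.null(laterality) && nm %in% names(laterality))
      laterality[[nm]] else infer_laterality(nm)
    dels[[length(dels) + 1L]] <- delineation(
      patient_id = patient, scan_time = scan_time, observer_id = observer,
      organ = nm, laterality = lat, slices = slices,
      slice_spacing = ct_slice_spacing)
  }
  if (length(dels) == 0) warning("RTSTRUCT contains no usable ROIs: ", path)
  delineation_set(dels, metadata = list(source = "rtstruct", file = basename(path)))
}
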
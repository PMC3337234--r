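# Contour data model, canonical JSON round trips, RTSTRUCT adapter.

make_simple_set <- function() {
  d <- delineation("P1", "plan", "obs1", "organ_a", "midline",
                   list(contour_slice(0, list(square_poly(10)))),
                   slice_spacing = 2)
  delineation_set(list(d), metadata = list(study = "unit", version = 1L))
}

test_that("polygon and slice invariants are enforced", {
  expect_error(validate_polygon(matrix(c(0, 0, 1, 1), 2, 2)), "fewer than 3")
  expect_error(validate_polygon(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "identical consecutive")
  expect_error(validate_polygon(rbind(c(0, 0), c(NaN, 1), c(1, 1))),
               "non-finite")
  # explicitly closed polygons are accepted with a warning, trailing vertex dropped
  p <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 0))
  expect_warning(q <- validate_polygon(p), "repeated first vertex")
  expect_equal(nrow(q), 3)
  expect_error(contour_slice(NaN, list(square_poly(1))), "finite")
})

test_that("delineation normalizes and validates its slice stack", {
  sl <- list(contour_slice(4, list(square_poly(5))),
             contour_slice(0, list(square_poly(5))),
             contour_slice(2, list(square_poly(5))))
  d <- delineation("P1", "plan", "o", "x", "left", sl, 2)
  expect_equal(vapply(d$slices, `[[`, numeric(1), "z"), c(0, 2, 4))
  # duplicate z
  expect_error(delineation("P1", "plan", "o", "x", "left",
                           list(contour_slice(0, list(square_poly(5))),
                                contour_slice(0, list(square_poly(6)))), 2),
               "duplicate slice z")
  # non-multiple spacing
  expect_error(delineation("P1", "plan", "o", "x", "left",
                           list(contour_slice(0, list(square_poly(5))),
                                contour_slice(3, list(square_poly(5)))), 2),
               "integer multiples")
  expect_error(delineation("P1", "nope", "o", "x", "left", sl, 2))
  expect_error(delineation("P1", "plan", "o", "x", "left", sl, -1),
               "positive")
})

test_that("delineation_set enforces unique design keys", {
  d1 <- delineation("P1", "plan", "o1", "x", "left",
                    list(contour_slice(0, list(square_poly(5)))), 2)
  d2 <- delineation("P1", "plan", "o1", "x", "right",
                    list(contour_slice(0, list(square_poly(6)))), 2)
  expect_error(delineation_set(list(d1, d2)), "duplicate")
})

test_that("canonical JSON write/load round trip is the identity", {
  set <- make_simple_set()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_contour_set(set, f1)
  loaded <- load_contour_set(f1)
  expect_equal(length(loaded$delineations), 1)
  d <- loaded$delineations[[1]]
  expect_equal(d$patient_id, "P1")
  expect_equal(length(d$slices), 1)
  expect_equal(nrow(d$slices[[1]]$polygons[[1]]), 4)
  expect_equal(d$slices[[1]]$polygons[[1]], square_poly(10))
  # idempotent re-export: byte identical
  write_contour_set(loaded, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("empty sets and invalid files are handled", {
  f <- withr::local_tempfile(fileext = ".json")
  write_contour_set(delineation_set(), f)
  empty <- load_contour_set(f)
  expect_length(empty$delineations, 0)

  writeLines("this is not json {", f)
  expect_error(load_contour_set(f), "parse error")
  writeLines('{"metadata": {}}', f)
  expect_error(load_contour_set(f), "delineations")
  expect_error(load_contour_set(file.path(tempdir(), "nope.json")),
               "not found")
})

test_that("files violating invariants are rejected with context", {
  set <- make_simple_set()
  f <- withr::local_tempfile(fileext = ".json")
  write_contour_set(set, f)
  txt <- readLines(f, warn = FALSE)
  # duplicate the single slice to create two slices at the same z
  j <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  j$delineations[[1]]$slices <- c(j$delineations[[1]]$slices,
                                  j$delineations[[1]]$slices)
  writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, digits = NA), f)
  expect_error(load_contour_set(f), "duplicate slice z")

  # a NaN coordinate must be refused on write
  bad <- make_simple_set()
  bad$delineations[[1]]$slices[[1]]$polygons[[1]][1, 1] <- NaN
  expect_error(write_contour_set(bad, f), "non-finite")
})

test_that("property: random valid sets survive the round trip", {
  set.seed(71)
  for (rep in 1:5) {
    dels <- lapply(1:3, function(i) {
      zs <- seq(0, by = 2, length.out = sample(2:5, 1))
      slices <- lapply(zs, function(z) {
        polys <- lapply(seq_len(sample(1:2, 1)), function(k) {
          n <- sample(3:8, 1)
          cbind(round(runif(n, -30, 30), 3), round(runif(n, -30, 30), 3))
        })
        contour_slice(z, polys)
      })
      delineation(paste0("P", i), sample(c("plan", "rep"), 1),
                  paste0("o", i), "organ", "midline", slices, 2)
    })
    set <- delineation_set(dels, metadata = list(rep = rep))
    f <- withr::local_tempfile(fileext = ".json")
    write_contour_set(set, f)
    back <- load_contour_set(f)
    expect_equal(length(back$delineations), 3)
    for (i in 1:3) {
      a <- set$delineations[[i]]; b <- back$delineations[[i]]
      expect_equal(b$slices, a$slices, tolerance = 1e-6)
      expect_identical(b$patient_id, a$patient_id)
      expect_identical(b$slice_spacing, a$slice_spacing)
    }
  }
})

test_that("RTSTRUCT adapter reads a synthetic structure set", {
  f <- withr::local_tempfile(fileext = ".dcm")
  # 20 mm square over 5 slices at dz = 2 mm -> 4 cm^3
  contours <- lapply(seq(0, 8, 2), function(z) square_xyz(20, z))
  write_fixture_rtstruct(f, patient_id = "PAT7", observer = "obsZ",
                         rois = list(list(number = 1, name = "parotid_left",
                                          contours = contours)))
  set <- load_rtstruct(f, ct_slice_spacing = 2)
  expect_length(set$delineations, 1)
  d <- set$delineations[[1]]
  expect_equal(d$patient_id, "PAT7")
  expect_equal(d$observer_id, "obsZ")
  expect_equal(d$organ, "parotid_left")
  expect_equal(d$laterality, "left")
  expect_equal(length(d$slices), 5)
  expect_equal(delineation_volume(d), 20 * 20 * 5 * 2 / 1000)
})

test_that("RTSTRUCT adapter flags bad geometry and empty sets", {
  f <- withr::local_tempfile(fileext = ".dcm")
  write_fixture_rtstruct(f, rois = list())
  expect_warning(set <- load_rtstruct(f, 2), "no usable ROIs")
  expect_length(set$delineations, 0)

  # nameless ROI skipped with a warning (and the set then ends up empty)
  write_fixture_rtstruct(f, rois = list(
    list(number = 1, name = NULL, contours = list(square_xyz(10, 0)))))
  expect_warning(expect_warning(set <- load_rtstruct(f, 2), "no name"),
                 "no usable ROIs")
  expect_length(set$delineations, 0)

  # non-axial contour: z varies within one contour
  tilted <- square_xyz(10, 0); tilted[2, 3] <- 3
  write_fixture_rtstruct(f, rois = list(
    list(number = 1, name = "cord", contours = list(tilted))))
  expect_error(load_rtstruct(f, 2), "non-axial")

  # not a DICOM file at all
  writeLines("hello", f)
  expect_error(load_rtstruct(f, 2), "not a DICOM file")
})
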
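# End-to-end orchestration: simulate -> analyze -> report, with CSV/JSON/
# PLY artifacts and a small command-line front end.

#' Default per-organ sub-region rule sets
#'
#' Parotid-type organs: 5-slice caps; submandibular-type: 3-slice caps;
#' glottic larynx: single-slice caps; spinal cord: vertebral landmark
#' bands (z positions relative to the synthetic cord); thyroid cartilage:
#' caps (the closed-slice rule needs a ring-shaped cross-section that the
#' star-shaped synthetic thyroid cannot produce). Unknown organs fall back
#' to 3-slice caps with quadrants.
#'
#' @return named list of [region_spec()] objects with a `.default` entry.
#' @export
default_region_specs <- function() {
  list(
    spinal_cord = region_spec("spinal_cord", "landmarks",
                              landmarks = c(40, -60)),
    parotid_left = region_spec("parotid_left", "caps", 5, 5),
    parotid_right = region_spec("parotid_right", "caps", 5, 5),
    submandibular_left = region_spec("submandibular_left", "caps", 3, 3),
    submandibular_right = region_spec("submandibular_right", "caps", 3, 3),
    thyroid_cartilage = region_spec("thyroid_cartilage", "caps", 2, 2),
    glottic_larynx = region_spec("glottic_larynx", "caps", 1, 1),
    .default = region_spec("unknown", "caps", 3, 3))
}

#' Configure an end-to-end analysis run
#'
#' Exactly one of `input` (a contour JSON file) and `simulation` (a
#' [cohort_config()]) must be given.
#'
#' @param input path to a contour set JSON file, or `NULL`.
#' @param simulation a [cohort_config()], or `NULL`.
#' @param grid_spacing in-plane analysis grid spacing c(dx, dy) mm; the
#'   axial spacing follows the data.
#' @param region_specs named list of [region_spec()] per organ (plus
#'   `.default`).
#' @param cv_method,se_method descriptive variants, see
#'   [summarize_organ()].
#' @param signed_sd,weighted_sd 3D SD variants, see [local_sd()].
#' @param discrepancy_threshold ICC-vs-CI difference beyond which an organ
#'   is flagged volume- or position-dominated.
#' @param write_meshes export one PLY per analyzed structure group.
#' @param out_dir output directory (created), or `NULL` for no artifacts.
#' @param seed seed for the simulation route.
#' @return an `analysis_config` object.
#' @export
analysis_config <- function(input = NULL, simulation = NULL,
                            grid_spacing = c(1, 1),
                            region_specs = default_region_specs(),
                            cv_method = "per_scan", se_method = "overall",
                            signed_sd = TRUE, weighted_sd = FALSE,
                            discrepancy_threshold = 0.15,
                            write_meshes = FALSE,
                            out_dir = NULL, seed = 1L) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of 'input' and 'simulation' must be given")
  cv_method <- match.arg(cv_method, c("per_scan", "pooled"))
  se_method <- match.arg(se_method, c("overall", "patient_means"))
  structure(list(input = input, simulation = simulation,
                 grid_spacing = grid_spacing, region_specs = region_specs,
                 cv_method = cv_method, se_method = se_method,
                 signed_sd = isTRUE(signed_sd),
                 weighted_sd = isTRUE(weighted_sd),
                 discrepancy_threshold = discrepancy_threshold,
                 write_meshes = isTRUE(write_meshes),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

pick_region_spec <- function(specs, organ) {
  if (!is.null(specs[[organ]])) return(specs[[organ]])
  sp <- specs[[".default"]]
  if (is.null(sp)) sp <- region_spec(organ, "caps", 3, 3)
  sp$organ <- organ
  sp
}

#' Run the full interobserver variability analysis
#'
#' Executes, per organ: volume table and descriptives, Friedman test on
#' the planning data, variance-component ICC, pairwise concordance per
#' (patient, scan), and the median-surface 3D SD with sub-region labels.
#' Stage errors are reported with organ context and the remaining organs
#' are still processed. With an `out_dir`, CSV/JSON (and optionally PLY)
#' artifacts are written; rerunning the same config and seed reproduces
#' them byte-identically.
#'
#' @param config an [analysis_config()].
#' @return a `report_bundle`: list of data.frames (`volumes`,
#'   `organ_summary`, `friedman`, `icc`, `ci_pairs`, `ci_summary`, `sd3d`,
#'   `endpoints`) plus `metadata`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(config$input)) {
    set <- load_contour_set(config$input)
    source_desc <- config$input
  } else {
    sim <- config$simulation
    sim$seed <- config$seed
    set <- generate_cohort(sim)$set
    source_desc <- sprintf("synthetic cohort (seed %d)", config$seed)
  }

  volumes <- build_volume_table(set)
  if (nrow(volumes) == 0) stop("no analyzable structures in the input")
  organs <- sort(unique(volumes$organ))
  problems <- character()
  note <- function(organ, stage, e) {
    msg <- sprintf("[%s/%s] %s", organ, stage, conditionMessage(e))
    warning(msg, call. = FALSE)
    problems <<- c(problems, msg)
    NULL
  }

  organ_summary <- summarize_volumes(volumes, cv_method = config$cv_method,
                                     se_method = config$se_method)
  friedman <- do.call(rbind, lapply(organs, function(og) {
    f <- tryCatch(friedman_test(volumes, og, scan_time = "plan"),
                  error = function(e) note(og, "friedman", e))
    if (is.null(f)) return(NULL)
    data.frame(organ = og, statistic = f$statistic, dof = f$dof,
               p_value = f$p_value, n_blocks = f$n_blocks)
  }))
  icc <- do.call(rbind, lapply(organs, function(og) {
    tryCatch(icc_table(volumes[volumes$organ == og, , drop = FALSE]),
             error = function(e) note(og, "icc", e))
  }))

  # geometric endpoints per (organ, patient, scan) group
  ci_rows <- list()
  sd_rows <- list()
  groups <- unique(delineation_index(set)[c("patient_id", "scan_time", "organ")])
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    dels <- Filter(function(d)
      d$patient_id == g$patient_id && d$scan_time == g$scan_time &&
        d$organ == g$organ, set$delineations)
    if (length(dels) < 2) next
    res <- tryCatch({
      grid <- default_grid(dels, spacing = c(config$grid_spacing, NA))
      masks <- setNames(lapply(dels, rasterize, grid = grid),
                        vapply(dels, `[[`, character(1), "observer_id"))
      pairs <- ci_pairs(masks, g$patient_id, g$scan_time, g$organ)
      surface <- compute_median_surface(masks)
      fld <- local_sd(surface, masks, signed = config$signed_sd,
                      weighted = config$weighted_sd)
      spec <- pick_region_spec(config$region_specs, g$organ)
      labels <- assign_regions(surface, spec, dels[[1]]$laterality)
      reg <- regional_sd(fld, labels)
      if (config$write_meshes && !is.null(config$out_dir))
        write_ply(surface, file.path(config$out_dir,
                                     sprintf("surface_%s_%s_%s.ply", g$organ,
                                             g$patient_id, g$scan_time)),
                  sd = fld$sd, region = labels)
      sdr <- data.frame(organ = g$organ, patient_id = g$patient_id,
                        scan_time = g$scan_time, region = "global",
                        sd = fld$global_sd, n_observers = fld$n_observers)
      sdr <- rbind(sdr, data.frame(organ = g$organ, patient_id = g$patient_id,
                                   scan_time = g$scan_time, region = names(reg),
                                   sd = as.numeric(reg),
                                   n_observers = fld$n_observers))
      list(pairs = pairs, sd = sdr)
    }, error = function(e) note(g$organ, "geometry", e))
    if (is.null(res)) next
    ci_rows[[length(ci_rows) + 1]] <- res$pairs
    sd_rows[[length(sd_rows) + 1]] <- res$sd
  }
  ci_pairs_df <- do.call(rbind, ci_rows)
  sd3d <- do.call(rbind, sd_rows)
  ci_summary <- if (!is.null(ci_pairs_df)) ci_summary_table(ci_pairs_df) else NULL

  # Table-2-style endpoint table (organs can carry different region columns)
  endpoint_rows <- lapply(organs, function(og) {
    row <- data.frame(organ = og, icc = NA_real_, band = NA_character_,
                      ci_mean = NA_real_, ci_min = NA_real_, ci_max = NA_real_,
                      sd_global = NA_real_)
    if (!is.null(icc) && og %in% icc$organ) {
      row$icc <- icc$icc[icc$organ == og]
      row$band <- icc$band[icc$organ == og]
    }
    if (!is.null(ci_summary) && og %in% ci_summary$organ) {
      s <- ci_summary[ci_summary$organ == og, ]
      row$ci_mean <- s$ci_mean; row$ci_min <- s$ci_min; row$ci_max <- s$ci_max
    }
    if (!is.null(sd3d)) {
      s <- sd3d[sd3d$organ == og, ]
      if (nrow(s) > 0) {
        means <- tapply(s$sd, s$region, mean)
        row$sd_global <- unname(means["global"])
        for (rg in setdiff(names(means), "global"))
          row[[paste0("sd_", rg)]] <- unname(means[rg])
      }
    }
    row
  })
  all_cols <- unique(unlist(lapply(endpoint_rows, names)))
  endpoints <- do.call(rbind, lapply(endpoint_rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA_real_
    r[all_cols]
  }))
  if (!is.null(endpoints)) {
    d <- endpoints$icc - endpoints$ci_mean
    endpoints$dominance <- ifelse(
      is.na(d), NA_character_,
      ifelse(d > config$discrepancy_threshold, "volume-dominated",
             ifelse(-d > config$discrepancy_threshold, "position-dominated",
                    "balanced")))
  }

  bundle <- structure(list(
    volumes = volumes, organ_summary = organ_summary, friedman = friedman,
    icc = icc, ci_pairs = ci_pairs_df, ci_summary = ci_summary, sd3d = sd3d,
    endpoints = endpoints,
    metadata = list(source = source_desc, seed = config$seed,
                    grid_spacing = config$grid_spacing,
                    cv_method = config$cv_method, se_method = config$se_method,
                    signed_sd = config$signed_sd,
                    weighted_sd = config$weighted_sd,
                    package_version = as.character(utils::packageVersion("oarvar")),
                    problems = problems)),
    class = "report_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle's CSV/JSON artifacts
#'
#' @param bundle a `report_bundle` from [run_analysis()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("volumes", "organ_summary", "friedman", "icc", "ci_pairs",
               "ci_summary", "sd3d", "endpoints")) {
    df <- bundle[[nm]]
    if (!is.null(df))
      write.csv(df, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  writeLines(to_canonical_json(bundle$metadata),
             file.path(out_dir, "metadata.json"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("== interobserver variability report ==\n")
  cat("source:", x$metadata$source, "\n")
  cat(sprintf("%d volume records, %d organs\n", nrow(x$volumes),
              length(unique(x$volumes$organ))))
  if (!is.null(x$endpoints)) {
    cat("\nendpoints (Table-2 style):\n")
    print(format(x$endpoints, digits = 3), row.names = FALSE)
  }
  if (!is.null(x$friedman)) {
    cat("\nFriedman test (planning scans):\n")
    print(format(x$friedman, digits = 3), row.names = FALSE)
  }
  if (length(x$metadata$problems))
    cat("\nproblems:\n", paste(" -", x$metadata$problems, collapse = "\n"), "\n")
  invisible(x)
}

# ---- command line --------------------------------------------------------

config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    args <- list()
    for (f in c("n_patients", "scan_times", "jitter_sd", "scan_jitter_sd",
                "slice_spacing", "seed"))
      if (!is.null(s[[f]])) args[[f]] <- s[[f]]
    if (!is.null(s$exclusions)) args$exclusions <- s$exclusions
    sim <- do.call(cohort_config, args)
  }
  args <- list(input = y$input, simulation = sim)
  for (f in c("grid_spacing", "cv_method", "se_method", "signed_sd",
              "weighted_sd", "discrepancy_threshold", "write_meshes",
              "out_dir", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(analysis_config, args)
}

#' Command-line entry point
#'
#' Verbs:
#' * `simulate <config.yaml> <out.json>`: generate a synthetic cohort and
#'   write the contour JSON (plus `<out>.truth.json` ground-truth sidecar);
#' * `analyze <config.yaml>`: run [run_analysis()] and write the artifact
#'   CSVs to the configured `out_dir`;
#' * `report <out_dir>`: print a human-readable summary of a previous run.
#'
#' Invoke as `Rscript -e 'oarvar::oarvar_cli()' <verb> ...`.
#'
#' @param args command-line arguments (defaults to `commandArgs()`).
#' @return exit status, invisibly.
#' @export
oarvar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: oarvar_cli simulate <config.yaml> <out.json> | analyze <config.yaml> | report <out_dir>"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  verb <- args[1]
  if (verb == "simulate") {
    if (length(args) < 3) stop(usage)
    cfg <- config_from_yaml(args[2])
    if (is.null(cfg$simulation)) stop("simulate needs a 'simulation' block")
    cohort <- generate_cohort(cfg$simulation)
    write_contour_set(cohort$set, args[3])
    gt <- cohort$truth
    gt$structure_volumes <- lapply(seq_len(nrow(gt$structure_volumes)),
                                   function(i) as.list(gt$structure_volumes[i, ]))
    writeLines(to_canonical_json(unclass(gt)), paste0(args[3], ".truth.json"))
    message("wrote ", args[3])
  } else if (verb == "analyze") {
    if (length(args) < 2) stop(usage)
    cfg <- config_from_yaml(args[2])
    bundle <- run_analysis(cfg)
    if (is.null(cfg$out_dir)) print(bundle)
    message("analysis complete")
  } else if (verb == "report") {
    if (length(args) < 2) stop(usage)
    for (f in c("endpoints.csv", "friedman.csv", "organ_summary.csv")) {
      p <- file.path(args[2], f)
      if (file.exists(p)) {
        cat("\n--", f, "--\n")
        print(format(utils::read.csv(p), digits = 3), row.names = FALSE)
      }
    }
  } else stop(usage)
  invisible(0L)
}
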
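# Three-way mixed-effects variance components and the intraclass
# correlation coefficient for volume agreement.
#
# Model: volume ~ time (fixed, two levels) + patient + observer +
# patient:observer + patient:time + observer:time (all random). With one
# observation per (patient, observer, time) cell the three-way interaction
# is confounded with the residual, so sigma2_residual absorbs it.
# ICC = (s2_patient + s2_patient_time) / (sum of all six components):
# patient-related variation over total variation, the correlation of two
# arbitrary observers measuring the same patient on the same scan.

#' Fit the variance components of the volume model
#'
#' REML estimation by Fisher scoring on the variance scale with
#' non-negativity enforced by projection, so unbalanced designs such as an
#' organ excluded for one patient are handled. Because the covariance is
#' linear in the variance parameters the scoring iteration converges to
#' near machine precision; on balanced complete designs the estimates
#' coincide exactly with the expected-mean-squares method-of-moments
#' solution whenever that solution is interior (non-negative). If scoring
#' fails on pathological input, the fit falls back to [lme4::lmer()] with
#' a warning.
#'
#' @param records volume table (see [build_volume_table()]).
#' @param organ organ label.
#' @return a `variance_components` list with `sigma2_patient`,
#'   `sigma2_observer`, `sigma2_patient_observer`, `sigma2_patient_time`,
#'   `sigma2_observer_time`, `sigma2_residual` (cm^6) and `time_effect`,
#'   the fixed mean volume difference rep - plan (cm^3).
#' @export
fit_components <- function(records, organ) {
  check_volume_records(records)
  r <- records[records$organ == organ, , drop = FALSE]
  for (f in c("patient_id", "observer_id", "scan_time")) {
    if (length(unique(r[[f]])) < 2)
      stop("variance model for organ ", organ, " needs >= 2 levels of ", f)
  }
  r$patient_id <- factor(r$patient_id)
  r$observer_id <- factor(r$observer_id)
  r$scan_time <- factor(r$scan_time, levels = SCAN_TIMES)

  zero <- structure(list(
    organ = organ, sigma2_patient = 0, sigma2_observer = 0,
    sigma2_patient_observer = 0, sigma2_patient_time = 0,
    sigma2_observer_time = 0, sigma2_residual = 0,
    time_effect = 0, n_records = nrow(r)), class = "variance_components")
  if (var(r$volume) == 0) return(zero)  # degenerate: all volumes identical

  X <- cbind(intercept = 1, time_rep = as.numeric(r$scan_time == "rep"))
  Zs <- list(
    patient = mk_indicator(r$patient_id),
    observer = mk_indicator(r$observer_id),
    patient_observer = mk_indicator(interaction(r$patient_id, r$observer_id,
                                                drop = TRUE)),
    patient_time = mk_indicator(interaction(r$patient_id, r$scan_time,
                                            drop = TRUE)),
    observer_time = mk_indicator(interaction(r$observer_id, r$scan_time,
                                             drop = TRUE)))
  fit <- tryCatch(reml_fit(r$volume, X, Zs), error = function(e) e)

  if (!inherits(fit, "error")) {
    s2 <- fit$s2
    te <- fit$beta[2]
  } else {
    warning("REML scoring failed for organ ", organ, " (",
            conditionMessage(fit), "); falling back to lme4")
    lfit <- suppressMessages(suppressWarnings(lme4::lmer(
      volume ~ scan_time + (1 | patient_id) + (1 | observer_id) +
        (1 | patient_id:observer_id) + (1 | patient_id:scan_time) +
        (1 | observer_id:scan_time),
      data = r, REML = TRUE,
      control = lme4::lmerControl(optimizer = "bobyqa",
                                  optCtrl = list(rhoend = 1e-10),
                                  check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(lfit))
    comp <- setNames(vc$vcov, vc$grp)
    pick <- function(nm) { v <- unname(comp[nm]); if (is.na(v)) 0 else max(v, 0) }
    s2 <- c(patient = pick("patient_id"), observer = pick("observer_id"),
            patient_observer = pick("patient_id:observer_id"),
            patient_time = pick("patient_id:scan_time"),
            observer_time = pick("observer_id:scan_time"),
            residual = pick("Residual"))
    fe <- lme4::fixef(lfit)
    te <- if ("scan_timerep" %in% names(fe)) unname(fe["scan_timerep"]) else 0
  }

  structure(list(
    organ = organ,
    sigma2_patient = unname(s2["patient"]),
    sigma2_observer = unname(s2["observer"]),
    sigma2_patient_observer = unname(s2["patient_observer"]),
    sigma2_patient_time = unname(s2["patient_time"]),
    sigma2_observer_time = unname(s2["observer_time"]),
    sigma2_residual = unname(s2["residual"]),
    time_effect = te, n_records = nrow(r)), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> %s\n", x$organ))
  for (nm in c("sigma2_patient", "sigma2_observer", "sigma2_patient_observer",
               "sigma2_patient_time", "sigma2_observer_time", "sigma2_residual"))
    cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  cat(sprintf("  time effect (rep - plan) %g cm^3\n", x$time_effect))
  invisible(x)
}

component_total <- function(c) {
  c$sigma2_patient + c$sigma2_observer + c$sigma2_patient_observer +
    c$sigma2_patient_time + c$sigma2_observer_time + c$sigma2_residual
}

#' Intraclass correlation coefficient from variance components
#'
#' Ratio of the patient-related components (patient and patient-time
#' interaction) to the sum of all six components. The fixed time effect
#' enters neither numerator nor denominator. If every component is zero
#' the ICC is 0 by convention.
#'
#' @param components a `variance_components` object (see
#'   [fit_components()]).
#' @return ICC in \[0, 1\].
#' @export
compute_icc <- function(components) {
  tot <- component_total(components)
  if (tot <= 0) return(0)
  (components$sigma2_patient + components$sigma2_patient_time) / tot
}

ICC_BANDS <- data.frame(
  upper = c(0.10, 0.40, 0.60, 0.80, 1.00),
  band = c("virtually none", "slight", "fair", "moderate", "substantial"))

#' Classify an ICC into an agreement band
#'
#' Standard verbal agreement categories: 0.00-0.10 virtually none,
#' 0.11-0.40 slight, 0.41-0.60 fair, 0.61-0.80 moderate, 0.81-1.00
#' substantial. Intervals are closed at the printed endpoints; values
#' strictly between printed endpoints (e.g. 0.105) fall in the upper band.
#'
#' @param icc value in \[0, 1\].
#' @return band label.
#' @export
classify_icc <- function(icc) {
  if (length(icc) != 1 || !is.finite(icc) || icc < 0 || icc > 1)
    stop("icc must be a single value in [0, 1]")
  ICC_BANDS$band[which(icc <= ICC_BANDS$upper + 1e-12)[1]]
}

#' Per-organ ICC with components and agreement band
#'
#' @inheritParams fit_components
#' @return an `icc_result` list: organ, icc, components, band.
#' @export
icc_organ <- function(records, organ) {
  comp <- fit_components(records, organ)
  icc <- compute_icc(comp)
  structure(list(organ = organ, icc = icc, components = comp,
                 band = classify_icc(icc)), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s: ICC = %.3f (%s agreement)\n",
              x$organ, x$icc, x$band))
  invisible(x)
}

#' ICC table over all organs
#'
#' @param records volume table.
#' @return data.frame, one row per organ, with the six components, the
#'   time effect, the ICC and its band.
#' @export
icc_table <- function(records) {
  organs <- sort(unique(records$organ))
  rows <- lapply(organs, function(og) {
    res <- icc_organ(records, og)
    c_ <- res$components
    data.frame(organ = og, icc = res$icc, band = res$band,
               sigma2_patient = c_$sigma2_patient,
               sigma2_observer = c_$sigma2_observer,
               sigma2_patient_observer = c_$sigma2_patient_observer,
               sigma2_patient_time = c_$sigma2_patient_time,
               sigma2_observer_time = c_$sigma2_observer_time,
               sigma2_residual = c_$sigma2_residual,
               time_effect = c_$time_effect)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
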
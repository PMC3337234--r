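# Volume descriptives: the long volume table, per-organ summaries
# (mean volume, SE, CV, per-observer OAR ratio) and the tie-corrected
# Friedman test for a systematic observer effect.

#' Build the long volume table of a delineation set
#'
#' One row per delineation, with the grid-free slab volume from
#' [delineation_volume()]. Structures flagged in `metadata$excluded` are
#' omitted with a message (mirroring organs excluded from analysis).
#'
#' @param set a [delineation_set()].
#' @return data.frame with columns patient_id, scan_time, observer_id,
#'   organ, laterality, volume (cm^3).
#' @export
build_volume_table <- function(set) {
  stopifnot(inherits(set, "delineation_set"))
  excluded <- set$metadata$excluded
  rows <- lapply(set$delineations, function(d) {
    if (is_excluded(d, excluded)) {
      message("excluded from volume table: ", d$patient_id, "/", d$scan_time,
              "/", d$observer_id, "/", d$organ)
      return(NULL)
    }
    data.frame(patient_id = d$patient_id, scan_time = d$scan_time,
               observer_id = d$observer_id, organ = d$organ,
               laterality = d$laterality, volume = delineation_volume(d))
  })
  out <- do.call(rbind, c(list(data.frame(
    patient_id = character(), scan_time = character(),
    observer_id = character(), organ = character(),
    laterality = character(), volume = numeric())), rows))
  rownames(out) <- NULL
  out
}

check_volume_records <- function(records) {
  need <- c("patient_id", "scan_time", "observer_id", "organ", "volume")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("volume records lack column(s): ", paste(miss, collapse = ", "))
  if (any(records$volume < 0)) stop("volumes must be >= 0")
  invisible(records)
}

#' Summarize one organ's volumes
#'
#' Computes the Table-1-style descriptives:
#' * `mean_volume`: mean over all records (cm^3);
#' * `se`: standard error of the mean. `"overall"` (default) is the sample
#'   SD over all records divided by sqrt(n); `"patient_means"` first
#'   averages within patients;
#' * `cv`: coefficient of variation. `"per_scan"` (default) averages the
#'   across-observer sample SD / mean over the (patient, scan) cells, i.e.
#'   an observer-relative standard deviation; `"pooled"` is SD/mean over
#'   all records;
#' * `oar_ratio`: per observer, that observer's mean volume divided by the
#'   mean over observers of those per-observer means; averages exactly to
#'   1 on complete designs. Observers without records get `NA` with a
#'   warning.
#'
#' @param records volume table (see [build_volume_table()]).
#' @param organ organ label to summarize.
#' @param cv_method `"per_scan"` or `"pooled"`.
#' @param se_method `"overall"` or `"patient_means"`.
#' @param observers optional character vector of the full observer roster
#'   (to flag observers with zero records).
#' @return an `organ_summary` list.
#' @export
summarize_organ <- function(records, organ,
                            cv_method = c("per_scan", "pooled"),
                            se_method = c("overall", "patient_means"),
                            observers = NULL) {
  check_volume_records(records)
  cv_method <- match.arg(cv_method)
  se_method <- match.arg(se_method)
  r <- records[records$organ == organ, , drop = FALSE]
  if (nrow(r) < 2) stop("need at least 2 volume records for organ ", organ)

  mean_volume <- mean(r$volume)
  se <- if (se_method == "overall") {
    sd(r$volume) / sqrt(nrow(r))
  } else {
    pm <- tapply(r$volume, r$patient_id, mean)
    sd(pm) / sqrt(length(pm))
  }

  if (cv_method == "per_scan") {
    cell <- interaction(r$patient_id, r$scan_time, drop = TRUE)
    cvs <- tapply(r$volume, cell, function(v)
      if (length(v) >= 2 && mean(v) > 0) sd(v) / mean(v) else NA_real_)
    cv <- mean(cvs, na.rm = TRUE)
    if (is.nan(cv)) cv <- 0
  } else {
    cv <- if (mean_volume > 0) sd(r$volume) / mean_volume else 0
  }

  obs_means <- tapply(r$volume, r$observer_id, mean)
  ratio <- setNames(as.numeric(obs_means / mean(obs_means)), names(obs_means))
  if (!is.null(observers)) {
    missing_obs <- setdiff(observers, names(obs_means))
    if (length(missing_obs) > 0) {
      warning("organ ", organ, ": no records for observer(s) ",
              paste(missing_obs, collapse = ", "), "; ratio undefined")
      ratio[missing_obs] <- NA_real_
    }
  }

  structure(list(organ = organ, mean_volume = mean_volume, se = se, cv = cv,
                 oar_ratio = ratio, n_records = nrow(r)),
            class = "organ_summary")
}

#' @export
print.organ_summary <- function(x, ...) {
  cat(sprintf("<organ_summary> %s: mean %.2f cm^3 (SE %.2f), CV %.0f%%\n",
              x$organ, x$mean_volume, x$se, 100 * x$cv))
  cat("  OAR ratio:", paste(sprintf("%s=%.2f", names(x$oar_ratio), x$oar_ratio),
                            collapse = " "), "\n")
  invisible(x)
}

#' Summarize all organs into a Table-1-style data frame
#'
#' @inheritParams summarize_organ
#' @return data.frame with one row per organ: mean volume, SE, CV and one
#'   `ratio_<observer>` column per observer.
#' @export
summarize_volumes <- function(records, cv_method = c("per_scan", "pooled"),
                              se_method = c("overall", "patient_means")) {
  check_volume_records(records)
  organs <- sort(unique(records$organ))
  observers <- sort(unique(records$observer_id))
  rows <- lapply(organs, function(og) {
    s <- summarize_organ(records, og, cv_method = cv_method,
                         se_method = se_method, observers = observers)
    ratios <- setNames(as.numeric(s$oar_ratio[observers]),
                       paste0("ratio_", observers))
    cbind(data.frame(organ = og, mean_volume = s$mean_volume, se = s$se,
                     cv = s$cv, n = s$n_records), as.list(ratios))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Friedman test for a systematic observer effect
#'
#' Rank-based Friedman chi-square over patient blocks for one organ on one
#' scan time, with mid-ranks and the standard tie correction (the
#' statistic reduces to the classic formula when there are no ties). The
#' design must be complete: every observer on every patient.
#'
#' @param records volume table.
#' @param organ organ label.
#' @param scan_time scan time whose data are tested (default `"plan"`).
#' @return a `friedman_result` list: organ, statistic, dof, p_value,
#'   n_blocks.
#' @export
friedman_test <- function(records, organ, scan_time = "plan") {
  check_volume_records(records)
  r <- records[records$organ == organ & records$scan_time == scan_time, ,
               drop = FALSE]
  patients <- sort(unique(r$patient_id))
  observers <- sort(unique(r$observer_id))
  n <- length(patients); k <- length(observers)
  if (n < 2 || k < 2)
    stop("Friedman test needs >= 2 patients and >= 2 observers for organ ", organ)
  m <- matrix(NA_real_, n, k, dimnames = list(patients, observers))
  m[cbind(match(r$patient_id, patients), match(r$observer_id, observers))] <- r$volume
  if (anyNA(m)) {
    holes <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete block design for organ ", organ, ": missing ",
         paste(sprintf("(%s, %s)", patients[holes[, 1]], observers[holes[, 2]]),
               collapse = ", "))
  }
  ranks <- t(apply(m, 1, rank))  # mid-ranks within each patient block
  Rj <- colSums(ranks)
  num <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4)
  den <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  statistic <- if (den <= 0) 0 else num / den
  dof <- k - 1L
  structure(list(organ = organ, statistic = statistic, dof = dof,
                 p_value = pchisq(statistic, dof, lower.tail = FALSE),
                 n_blocks = n),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("<friedman_result> %s: chi2 = %.3f, df = %d, p = %.4g (n = %d blocks)\n",
              x$organ, x$statistic, x$dof, x$p_value, x$n_blocks))
  invisible(x)
}
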
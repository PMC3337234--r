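# Pairwise concordance index (Jaccard overlap of two delineated volumes)
# and its per-organ aggregation.

#' Concordance index of two binary masks
#'
#' Intersection over union by voxel count: 1 means identical structures,
#' 0 no overlap. Both masks must share one grid. If exactly one mask is
#' empty the CI is 0 (an absent structure against a present one is zero
#' agreement, logged as a message); two empty masks are undefined and
#' raise an error.
#'
#' @param a,b [oar_mask()] objects on the identical grid.
#' @return CI in \[0, 1\].
#' @export
pairwise_ci <- function(a, b) {
  stopifnot(inherits(a, "oar_mask"), inherits(b, "oar_mask"))
  if (!grids_identical(a$grid, b$grid))
    stop("concordance index requires masks on the identical grid")
  na <- sum(a$occupancy); nb <- sum(b$occupancy)
  if (na == 0 && nb == 0)
    stop("concordance index undefined: both masks are empty")
  if (na == 0 || nb == 0) {
    message("one mask empty: concordance index 0")
    return(0)
  }
  inter <- sum(a$occupancy & b$occupancy)
  uni <- na + nb - inter
  inter / uni
}

#' Dice coefficient implied by a concordance index
#'
#' Fixed algebraic relationship `dice = 2 ci / (1 + ci)`; exposed as a
#' cross-check utility.
#'
#' @param ci concordance index in \[0, 1\].
#' @export
ci_to_dice <- function(ci) 2 * ci / (1 + ci)

#' Pairwise concordance table for one group of observer masks
#'
#' All unordered observer pairs of one (patient, scan, organ) cell.
#'
#' @param masks named list of [oar_mask()] objects (names = observer ids)
#'   on one grid.
#' @param patient_id,scan_time,organ identifiers copied into the rows.
#' @return data.frame with one row per unordered pair: observer_a,
#'   observer_b, ci.
#' @export
ci_pairs <- function(masks, patient_id = NA_character_,
                     scan_time = NA_character_, organ = NA_character_) {
  stopifnot(is.list(masks), length(masks) >= 2)
  obs <- names(masks)
  if (is.null(obs)) obs <- as.character(seq_along(masks))
  idx <- combn(length(masks), 2)
  rows <- lapply(seq_len(ncol(idx)), function(c_) {
    i <- idx[1, c_]; j <- idx[2, c_]
    data.frame(patient_id = patient_id, scan_time = scan_time, organ = organ,
               observer_a = obs[i], observer_b = obs[j],
               ci = pairwise_ci(masks[[i]], masks[[j]]))
  })
  do.call(rbind, rows)
}

#' Aggregate pairwise concordance indices per organ
#'
#' Unweighted mean, minimum and maximum over the pooled (pair x scan)
#' records of the organ — all observer pairs and all scans enter with
#' equal weight, no per-scan averaging first.
#'
#' @param pairs data.frame of pairwise records (see [ci_pairs()]).
#' @param organ organ label.
#' @return a `ci_summary` list: organ, mean_ci, min_ci, max_ci,
#'   n_pairs_total.
#' @export
aggregate_ci <- function(pairs, organ) {
  r <- pairs[pairs$organ == organ, , drop = FALSE]
  if (nrow(r) < 1) stop("no concordance records for organ ", organ)
  structure(list(organ = organ, mean_ci = mean(r$ci), min_ci = min(r$ci),
                 max_ci = max(r$ci), n_pairs_total = nrow(r)),
            class = "ci_summary")
}

#' @export
print.ci_summary <- function(x, ...) {
  cat(sprintf("<ci_summary> %s: mean CI %.2f (%.2f-%.2f), %d pair records\n",
              x$organ, x$mean_ci, x$min_ci, x$max_ci, x$n_pairs_total))
  invisible(x)
}

#' Concordance summary table over all organs
#'
#' @param pairs data.frame of pairwise records.
#' @return data.frame with one row per organ: mean, min, max CI and the
#'   pooled record count.
#' @export
ci_summary_table <- function(pairs) {
  organs <- sort(unique(pairs$organ))
  rows <- lapply(organs, function(og) {
    s <- aggregate_ci(pairs, og)
    data.frame(organ = og, ci_mean = s$mean_ci, ci_min = s$min_ci,
               ci_max = s$max_ci, n_pairs = s$n_pairs_total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
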
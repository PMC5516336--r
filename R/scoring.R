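# Reference-anchored score adjustment. A base scoring function's raw score
# is converted to logKa either by the calibrated linear map (fallback) or,
# when a qualified reference complex is found, by anchoring to the
# reference's experimental affinity:
#   adjusted = R_exp + k * (Q_raw - R_raw)
# so that systematic scoring-function error shared by similar complexes
# cancels.

#' Calibrate the scoring-function slope
#'
#' Ordinary least squares of experimental affinity (logKa, response) on
#' raw score (predictor). The slope is the `k` used in score adjustment;
#' `sd` is the residual standard deviation of the regression.
#'
#' @param score_table data.frame with columns `raw_score` and
#'   `experimental` (logKa); at least 3 complete rows and non-zero score
#'   variance.
#' @return Object of class `kgs_calibration`: list(k, b, r, sd, n).
#' @export
calibrate <- function(score_table) {
  stopifnot(all(c("raw_score", "experimental") %in% names(score_table)))
  tab <- score_table[is.finite(score_table$raw_score) &
                       is.finite(score_table$experimental), , drop = FALSE]
  if (nrow(tab) < 3L) stop("calibration needs at least 3 rows with experimental values")
  if (stats::var(tab$raw_score) == 0) stop("undefined slope: zero score variance")
  fit <- lm(experimental ~ raw_score, data = tab)
  structure(list(k = unname(coef(fit)[2L]), b = unname(coef(fit)[1L]),
                 r = cor(tab$raw_score, tab$experimental),
                 sd = summary(fit)$sigma, n = nrow(tab)),
            class = "kgs_calibration")
}

#' @export
print.kgs_calibration <- function(x, ...) {
  cat(sprintf("<kgs_calibration> k=%.4g b=%.4g R=%.3f SD=%.3f (n=%d)\n",
              x$k, x$b, x$r, x$sd, x$n))
  invisible(x)
}

#' Reference-anchored score adjustment
#'
#' `adjusted = r_exp + k * (q_raw - r_raw)` (logKa units). Vectorized.
#'
#' @param q_raw raw score of the query.
#' @param r_raw raw score of the reference.
#' @param r_exp experimental affinity of the reference (logKa).
#' @param k calibrated slope.
#' @return Adjusted affinity in logKa units.
#' @export
adjust_score <- function(q_raw, r_raw, r_exp, k) {
  stopifnot(all(is.finite(q_raw)), all(is.finite(r_raw)),
            all(is.finite(r_exp)), is.finite(k))
  r_exp + k * (q_raw - r_raw)
}

#' Absolute prediction error in logKa units
#' @param experimental,predicted affinities (logKa).
#' @return `|experimental - predicted|`.
#' @export
abs_error <- function(experimental, predicted) {
  stopifnot(all(is.finite(experimental)), all(is.finite(predicted)))
  abs(experimental - predicted)
}

#' Score one query complex
#'
#' Builds the query fingerprint, searches the reference library, and
#' applies the anchored adjustment when a qualified reference with
#' `si >= min_si` exists; otherwise falls back to the calibrated linear
#' map `b + k * q_raw` (fallback flag set).
#'
#' @param query a `kgs_complex`.
#' @param q_raw the query's raw score from the base scoring function.
#' @param fingerprints named list of reference fingerprints.
#' @param ref_scores named numeric vector: complex_id -> raw score of the
#'   reference complexes under the same scoring function.
#' @param calibration a `kgs_calibration`.
#' @param pattern_library a `kgs_pattern_library`.
#' @param config a [kgs_config()].
#' @param exclude_ids reference ids to skip.
#' @return Object of class `kgs_adjusted`: list(query_id, reference_id,
#'   q_raw, r_raw, r_exp, adjusted, si_used, n_pq, fallback).
#' @export
score_query <- function(query, q_raw, fingerprints, ref_scores, calibration,
                        pattern_library, config = kgs_config(),
                        exclude_ids = character(0)) {
  fp <- build_fingerprint(query, pattern_library, config)
  hit <- search_reference(fp, fingerprints, config, exclude_ids = exclude_ids)
  ref <- hit$reference
  if (is.null(ref)) {
    return(structure(list(query_id = query$complex_id, reference_id = NA_character_,
                          q_raw = q_raw, r_raw = NA_real_, r_exp = NA_real_,
                          adjusted = calibration$b + calibration$k * q_raw,
                          si_used = NA_real_, n_pq = NA_integer_, fallback = TRUE),
                     class = "kgs_adjusted"))
  }
  ref_id <- ref$id_q
  ref_fp <- fingerprints[[ref_id]]
  r_exp <- ref_fp$affinity
  if (is.na(r_exp))
    stop("reference '", ref_id, "' has no experimental affinity")
  if (!(ref_id %in% names(ref_scores)) || !is.finite(ref_scores[[ref_id]]))
    stop("reference '", ref_id, "' found but its raw score is missing")
  r_raw <- ref_scores[[ref_id]]
  structure(list(query_id = query$complex_id, reference_id = ref_id,
                 q_raw = q_raw, r_raw = r_raw, r_exp = r_exp,
                 adjusted = adjust_score(q_raw, r_raw, r_exp, calibration$k),
                 si_used = ref$si, n_pq = ref$n_pq, fallback = FALSE),
            class = "kgs_adjusted")
}

#' Score a set of query complexes
#'
#' @param queries named list of `kgs_complex` objects.
#' @param raw_scores named numeric vector: query complex_id -> raw score.
#' @param fingerprints,ref_scores,calibration,pattern_library,config see
#'   [score_query()].
#' @param exclude_self exclude each query's own id from its reference
#'   search (default TRUE; always excluded anyway by id equality).
#' @return data.frame with one row per query: query_id, reference_id,
#'   q_raw, r_raw, r_exp, adjusted, si_used, n_pq, fallback.
#' @export
score_set <- function(queries, raw_scores, fingerprints, ref_scores,
                      calibration, pattern_library, config = kgs_config(),
                      exclude_self = TRUE) {
  rows <- lapply(queries, function(qc) {
    a <- score_query(qc, raw_scores[[qc$complex_id]], fingerprints, ref_scores,
                     calibration, pattern_library, config)
    data.frame(query_id = a$query_id, reference_id = a$reference_id,
               q_raw = a$q_raw, r_raw = a$r_raw, r_exp = a$r_exp,
               adjusted = a$adjusted, si_used = a$si_used, n_pq = a$n_pq,
               fallback = a$fallback, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a prediction set (Pearson R and SD)
#'
#' `r_p` is the Pearson correlation between predictions and experimental
#' affinities. `sd` is the residual standard deviation of the linear fit
#' of experimental on predicted (the regression-SD accuracy indicator,
#' independent of sample size); the raw RMSE is reported alongside.
#'
#' @param predicted,experimental numeric vectors (logKa), length >= 3.
#' @return list(r_p, sd, rmse, n).
#' @export
evaluate_set <- function(predicted, experimental) {
  ok <- is.finite(predicted) & is.finite(experimental)
  predicted <- predicted[ok]; experimental <- experimental[ok]
  n <- length(predicted)
  if (n < 3L) stop("need at least 3 prediction pairs")
  if (stats::var(predicted) == 0 || stats::var(experimental) == 0)
    stop("correlation undefined: zero variance")
  fit <- lm(experimental ~ predicted)
  list(r_p = cor(predicted, experimental),
       sd = summary(fit)$sigma,
       rmse = sqrt(mean((experimental - predicted)^2)),
       n = n)
}

#' Applicability sweep over similarity cutoffs
#'
#' From a [score_set()] result, recomputes predictions at each similarity
#' cutoff: queries whose selected reference has `si_used >= cutoff` keep
#' the anchored score, the rest fall back to the calibrated linear map.
#' Reports the number of anchored predictions and, when experimental data
#' are supplied, Pearson R and SD of the mixed prediction set (the data
#' behind cutoff-sweep performance curves).
#'
#' @param scored data.frame from [score_set()].
#' @param calibration a `kgs_calibration`.
#' @param cutoffs numeric vector of similarity cutoffs.
#' @param experimental optional named vector: query_id -> logKa.
#' @return data.frame: cutoff, n_anchored, n_total, and (if experimental
#'   given) r_p and sd.
#' @export
sweep_applicability <- function(scored, calibration, cutoffs = seq(0.1, 0.9, 0.1),
                                experimental = NULL) {
  rows <- lapply(cutoffs, function(ct) {
    anchored <- !scored$fallback & !is.na(scored$si_used) & scored$si_used >= ct
    pred <- ifelse(anchored, scored$adjusted,
                   calibration$b + calibration$k * scored$q_raw)
    row <- data.frame(cutoff = ct, n_anchored = sum(anchored),
                      n_total = nrow(scored))
    if (!is.null(experimental)) {
      ev <- evaluate_set(pred, experimental[scored$query_id])
      row$r_p <- ev$r_p; row$sd <- ev$sd
    }
    row
  })
  do.call(rbind, rows)
}

#' Re-rank docking poses by anchored scores
#'
#' Each pose (same ligand, different geometry) is independently
#' fingerprinted, referenced and adjusted; poses are sorted by adjusted
#' score (descending) and the top pose's adjusted score is the ligand's
#' predicted affinity. Poses that find no reference fall back to the
#' calibrated linear map, so an all-fallback ligand keeps its raw-score
#' ranking (the linear map is monotone for k > 0).
#'
#' @param poses named list of `kgs_complex` objects, one per pose (names =
#'   pose ids).
#' @param pose_scores named numeric vector: pose id -> raw score.
#' @param fingerprints,ref_scores,calibration,pattern_library,config see
#'   [score_query()].
#' @return list with `ranking` (data.frame sorted by adjusted score) and
#'   `top` (the top row).
#' @export
rerank_poses <- function(poses, pose_scores, fingerprints, ref_scores,
                         calibration, pattern_library, config = kgs_config()) {
  stopifnot(length(poses) >= 1L)
  rows <- lapply(names(poses), function(pid) {
    a <- score_query(poses[[pid]], pose_scores[[pid]], fingerprints, ref_scores,
                     calibration, pattern_library, config)
    data.frame(pose_id = pid, reference_id = a$reference_id, q_raw = a$q_raw,
               adjusted = a$adjusted, si_used = a$si_used,
               fallback = a$fallback, stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$adjusted, ranking$pose_id), , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, top = ranking[1L, , drop = FALSE])
}
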
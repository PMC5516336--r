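# Mining statistically preferred interaction-unit geometries ("patterns")
# across a structure library. Each unit type's cloud of local-frame ligand
# positions is modelled as a Gaussian mixture; retained components become
# interaction patterns.

#' Aggregate interaction units across a library
#'
#' @param complexes list of `kgs_complex` objects (or a single one).
#' @param pocket_only passed to [extract_units()]; library mining uses the
#'   whole interface (`FALSE`, the default here).
#' @param margin,pocket_cutoff contact parameters.
#' @return data.frame of all units (class `kgs_units`), with an
#'   `occurrence` table by type key available via [unit_occurrence()].
#'   Unreadable or failing complexes are skipped with a warning.
#' @export
aggregate_units <- function(complexes, pocket_only = FALSE, margin = 1.0,
                            pocket_cutoff = 4.5) {
  if (inherits(complexes, "kgs_complex")) complexes <- list(complexes)
  parts <- list()
  for (cx in complexes) {
    u <- tryCatch(extract_units(cx, pocket_only = pocket_only, margin = margin,
                                pocket_cutoff = pocket_cutoff),
                  error = function(e) {
                    warning("skipping complex '", cx$complex_id, "': ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(u) && nrow(u)) parts[[length(parts) + 1L]] <- u
  }
  out <- if (length(parts)) do.call(rbind, parts) else
    extract_units_empty_frame()
  rownames(out) <- NULL
  class(out) <- c("kgs_units", class(out))
  out
}

extract_units_empty_frame <- function() {
  data.frame(complex_id = character(0), type_key = character(0),
             resname = character(0), res_key = character(0),
             n1 = character(0), n2 = character(0), n3 = character(0),
             s1 = integer(0), s2 = integer(0), s3 = integer(0),
             lig_serial = integer(0), lig_type = character(0),
             lx = numeric(0), ly = numeric(0), lz = numeric(0),
             stringsAsFactors = FALSE)
}

#' Occurrence counts per unit type
#' @param units output of [aggregate_units()] or [extract_units()].
#' @return Named integer vector, sorted decreasing.
#' @export
unit_occurrence <- function(units) {
  sort(table(units$type_key), decreasing = TRUE)
}

# Floor the eigenvalues of a covariance matrix (regularization; the
# spec-level floor is 1e-4 A^2).
regularize_cov <- function(S, floor = 1e-4) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% diag(vals) %*% t(e$vectors)
}

#' Fit a Gaussian mixture to a unit-type point cloud
#'
#' Fits mixtures with 1..`k_max` components (mclust, EM with BIC model
#' selection) and returns the selected mixture with per-component hard and
#' soft occurrence counts. Components whose weight falls below `1e-3` are
#' flagged as pruned. Covariances are regularized to an eigenvalue floor
#' of `1e-4` A^2. Deterministic for a given input (mclust's model-based
#' hierarchical initialisation uses no randomness).
#'
#' @param points n x 3 matrix of local coordinates.
#' @param k_max maximal number of components (default 15); lowered to the
#'   point count when fewer points are available.
#' @param seed recorded for provenance (set before fitting).
#' @param cov_floor eigenvalue floor for covariance regularization (A^2).
#' @return `NULL` when fewer than 2 points are supplied (type skipped);
#'   otherwise an object of class `kgs_gmm`: list with `weights`, `means`
#'   (G x 3), `covs` (list of 3x3), `counts_hard`, `counts_soft`,
#'   `pruned` (logical), `n`, `loglik`.
#' @export
fit_gmm <- function(points, k_max = 15L, seed = 0L, cov_floor = 1e-4) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) return(NULL)
  g_max <- max(1L, min(as.integer(k_max), n - 1L))
  set.seed(seed)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(points, G = 1:g_max,
                                    modelNames = c("EII", "VII", "VVI", "VVV"),
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # Degenerate cloud (e.g. identical points): single regularized component.
    mu <- colMeans(points)
    S <- if (n > 1L) stats::cov(points) else diag(3) * cov_floor
    S[!is.finite(S)] <- 0
    return(structure(list(
      weights = 1, means = matrix(mu, 1L, 3L),
      covs = list(regularize_cov(S, cov_floor)),
      counts_hard = n, counts_soft = n, pruned = FALSE,
      n = n, loglik = NA_real_), class = "kgs_gmm"))
  }
  G <- fit$G
  means <- t(fit$parameters$mean)
  if (is.null(dim(means))) means <- matrix(means, nrow = G)
  sig <- fit$parameters$variance$sigma # 3 x 3 x G for multivariate models
  covs <- lapply(seq_len(G), function(g) regularize_cov(sig[, , g], cov_floor))
  weights <- fit$parameters$pro
  if (is.null(weights)) weights <- 1
  cls <- fit$classification
  counts_hard <- as.integer(tabulate(cls, nbins = G))
  z <- fit$z
  if (is.null(z)) z <- matrix(1, n, 1L)
  counts_soft <- colSums(z)
  structure(list(weights = weights, means = means, covs = covs,
                 counts_hard = counts_hard, counts_soft = counts_soft,
                 pruned = weights < 1e-3, n = n, loglik = fit$loglik),
            class = "kgs_gmm")
}

#' Extract significant interaction patterns from a fitted mixture
#'
#' A unit type with occurrence below `min_type_occurrence` yields nothing.
#' A component is recorded as a pattern iff its occurrence (hard-assignment
#' count by default, soft expected count with `soft = TRUE`) exceeds
#' `min_component_occurrence` (strict >) and its weight is at least
#' `min_weight`.
#'
#' @param type_key the unit type string.
#' @param occurrence number of units of this type.
#' @param fit a `kgs_gmm` from [fit_gmm()] (or `NULL`).
#' @param min_type_occurrence keep types with occurrence >= this (100).
#' @param min_component_occurrence keep components with count > this (100).
#' @param min_weight keep components with weight >= this (0.01).
#' @param soft use soft (expected) counts instead of hard assignments.
#' @return list of patterns; each is a list(type_key, mean, cov, weight,
#'   occurrence).
#' @export
extract_patterns <- function(type_key, occurrence, fit,
                             min_type_occurrence = 100L,
                             min_component_occurrence = 100L,
                             min_weight = 0.01, soft = FALSE) {
  if (is.null(fit) || occurrence < min_type_occurrence) return(list())
  counts <- if (soft) fit$counts_soft else fit$counts_hard
  keep <- which(counts > min_component_occurrence &
                  fit$weights >= min_weight & !fit$pruned)
  lapply(keep, function(g) list(
    type_key = type_key,
    mean = as.numeric(fit$means[g, ]),
    cov = fit$covs[[g]],
    weight = as.numeric(fit$weights[g]),
    occurrence = as.numeric(counts[g])))
}

#' Mine an interaction-pattern library from unit data
#'
#' Groups units by type key, fits a Gaussian mixture per type, and applies
#' the significance filters.
#'
#' @param units data.frame from [aggregate_units()].
#' @param k_max,seed,min_type_occurrence,min_component_occurrence,min_weight,soft
#'   see [fit_gmm()] and [extract_patterns()].
#' @return Object of class `kgs_pattern_library`: list with `patterns`
#'   (named list: type_key -> list of patterns), and `meta` (parameters,
#'   totals, seed).
#' @export
mine_patterns <- function(units, k_max = 15L, seed = 0L,
                          min_type_occurrence = 100L,
                          min_component_occurrence = 100L,
                          min_weight = 0.01, soft = FALSE) {
  patterns <- list()
  if (nrow(units)) {
    by_type <- split(seq_len(nrow(units)), units$type_key)
    for (tk in names(by_type)) {
      idx <- by_type[[tk]]
      if (length(idx) < min_type_occurrence) next
      pts <- as.matrix(units[idx, c("lx", "ly", "lz")])
      fit <- fit_gmm(pts, k_max = k_max, seed = seed)
      pats <- extract_patterns(tk, length(idx), fit,
                               min_type_occurrence = min_type_occurrence,
                               min_component_occurrence = min_component_occurrence,
                               min_weight = min_weight, soft = soft)
      if (length(pats)) patterns[[tk]] <- pats
    }
  }
  structure(list(
    patterns = patterns,
    meta = list(schema_version = "1.0",
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                n_units = nrow(units),
                n_types = length(unique(units$type_key)),
                n_patterns = sum(lengths(patterns)),
                params = list(k_max = k_max, seed = seed,
                              min_type_occurrence = min_type_occurrence,
                              min_component_occurrence = min_component_occurrence,
                              min_weight = min_weight, soft = soft))),
    class = "kgs_pattern_library")
}

#' @export
print.kgs_pattern_library <- function(x, ...) {
  cat("<kgs_pattern_library>", x$meta$n_patterns, "patterns across",
      length(x$patterns), "unit types (from", x$meta$n_units, "units)\n")
  invisible(x)
}

#' Look up patterns by unit type
#' @param library a `kgs_pattern_library`.
#' @param type_key unit type string.
#' @return list of patterns (possibly empty).
#' @export
patterns_for_type <- function(library, type_key) {
  p <- library$patterns[[type_key]]
  if (is.null(p)) list() else p
}

#' Save / load a pattern library (versioned JSON)
#'
#' Lossless round trip of means, covariances, weights and counts at full
#' double precision.
#'
#' @param library a `kgs_pattern_library`.
#' @param path output file.
#' @return `save_pattern_library` returns `path` invisibly;
#'   `load_pattern_library` returns the library.
#' @export
save_pattern_library <- function(library, path) {
  stopifnot(inherits(library, "kgs_pattern_library"))
  obj <- list(
    schema_version = "1.0",
    meta = library$meta,
    patterns = lapply(library$patterns, function(pats) lapply(pats, function(p)
      list(type_key = p$type_key, mean = p$mean, cov = as.numeric(p$cov),
           weight = p$weight, occurrence = p$occurrence))))
  # 17 significant digits: doubles round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  invisible(path)
}

#' @rdname save_pattern_library
#' @export
load_pattern_library <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("failed to parse pattern library '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(obj$schema_version) || !identical(obj$schema_version, "1.0"))
    stop("pattern library schema version mismatch (expected 1.0, got ",
         if (is.null(obj$schema_version)) "none" else obj$schema_version, ")")
  patterns <- lapply(obj$patterns, function(pats) lapply(pats, function(p)
    list(type_key = p$type_key,
         mean = as.numeric(unlist(p$mean)),
         cov = matrix(as.numeric(unlist(p$cov)), 3L, 3L),
         weight = as.numeric(p$weight),
         occurrence = as.numeric(p$occurrence))))
  structure(list(patterns = patterns, meta = obj$meta),
            class = "kgs_pattern_library")
}
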
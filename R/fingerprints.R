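# Matching pocket interaction units against the pattern library and
# degrading matched patterns into the node fingerprint: one node on the
# residue's C-alpha (labelled by residue type) and one on the ligand atom
# (labelled by SYBYL atom type).

#' Mahalanobis distance of a unit to a pattern
#'
#' `D = sqrt((x - mu)' Sigma^-1 (x - mu))`; the pattern covariance is
#' positive-definite by regularization.
#'
#' @param x length-3 local coordinates of an interaction unit.
#' @param pattern a pattern (list with `mean`, `cov`).
#' @return Non-negative scalar.
#' @export
mahalanobis_distance <- function(x, pattern) {
  sqrt(stats::mahalanobis(matrix(x, 1L, 3L), pattern$mean, pattern$cov))
}

#' Match one interaction unit against the pattern library
#'
#' Returns every pattern of the unit's type whose Mahalanobis distance to
#' the unit is strictly below `threshold` (default 2.5); a unit can match
#' several components, or none. A type absent from the library yields an
#' empty match list (not an error).
#'
#' @param local_coords length-3 local coordinates.
#' @param type_key the unit's type string.
#' @param library a `kgs_pattern_library`.
#' @param threshold match cutoff (strict `<`).
#' @return list of matches: each list(pattern, distance).
#' @export
match_unit <- function(local_coords, type_key, library, threshold = 2.5) {
  pats <- patterns_for_type(library, type_key)
  if (length(pats) == 0L) return(list())
  out <- list()
  for (p in pats) {
    d <- mahalanobis_distance(local_coords, p)
    if (d < threshold) out[[length(out) + 1L]] <- list(pattern = p, distance = d)
  }
  out
}

#' Build the 3D interaction fingerprint of a complex
#'
#' Extracts pocket interaction units, matches each against the pattern
#' library, and degrades every matched pattern into a (C-alpha node,
#' ligand-atom node) pair. Nodes are deduplicated on (kind, anchor,
#' label); a multiplicity count is retained. Residues lacking a C-alpha
#' cannot host protein nodes and are dropped with a warning.
#'
#' The full node set is always stored; the `protein_only` comparison mode
#' (reference selection using pocket-residue nodes only) is applied at
#' comparison time.
#'
#' @param complex a `kgs_complex`.
#' @param library a `kgs_pattern_library`.
#' @param config a [kgs_config()] (uses mahalanobis_cutoff, contact_margin,
#'   pocket_cutoff).
#' @return Object of class `kgs_fingerprint`: list with `complex_id`,
#'   `nodes` (data.frame: kind, label, anchor, x, y, z, multiplicity),
#'   `n_nodes`, `affinity`.
#' @export
build_fingerprint <- function(complex, library, config = kgs_config()) {
  stopifnot(inherits(complex, "kgs_complex"),
            inherits(library, "kgs_pattern_library"))
  units <- extract_units(complex, pocket_only = TRUE,
                         margin = config$contact_margin,
                         pocket_cutoff = config$pocket_cutoff)
  ca <- residue_calpha(complex$protein)
  rownames(ca) <- ca$res_key
  la <- complex$ligand$atoms
  rownames(la) <- as.character(la$serial)

  nodes <- list(); ni <- 1L
  missing_ca <- character(0)
  if (nrow(units)) {
    for (i in seq_len(nrow(units))) {
      m <- match_unit(c(units$lx[i], units$ly[i], units$lz[i]),
                      units$type_key[i], library,
                      threshold = config$mahalanobis_cutoff)
      if (length(m) == 0L) next
      rk <- units$res_key[i]
      if (!(rk %in% rownames(ca))) {
        missing_ca <- union(missing_ca, rk)
        next
      }
      ls <- as.character(units$lig_serial[i])
      # one node pair per matched pattern; duplicates collapse below with a
      # multiplicity count
      nodes[[ni]] <- data.frame(
        kind = c("protein", "ligand"),
        label = c(units$resname[i], units$lig_type[i]),
        anchor = c(rk, ls),
        x = c(ca[rk, "x"], la[ls, "x"]),
        y = c(ca[rk, "y"], la[ls, "y"]),
        z = c(ca[rk, "z"], la[ls, "z"]),
        n_matches = length(m),
        stringsAsFactors = FALSE)
      ni <- ni + 1L
    }
  }
  if (length(missing_ca))
    warning("residue(s) without C-alpha dropped from fingerprint: ",
            paste(missing_ca, collapse = ", "))
  if (length(nodes)) {
    all_nodes <- do.call(rbind, nodes)
    key <- paste(all_nodes$kind, all_nodes$anchor, all_nodes$label, sep = "\r")
    mult <- tapply(all_nodes$n_matches, key, sum)
    all_nodes$multiplicity <- as.integer(mult[key])
    all_nodes <- all_nodes[!duplicated(key), , drop = FALSE]
    all_nodes$n_matches <- NULL
    rownames(all_nodes) <- NULL
  } else {
    all_nodes <- data.frame(kind = character(0), label = character(0),
                            anchor = character(0), x = numeric(0),
                            y = numeric(0), z = numeric(0),
                            multiplicity = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(complex_id = complex$complex_id, nodes = all_nodes,
                 n_nodes = nrow(all_nodes), affinity = complex$affinity),
            class = "kgs_fingerprint")
}

#' @export
print.kgs_fingerprint <- function(x, ...) {
  cat("<kgs_fingerprint>", x$complex_id, "-", x$n_nodes, "nodes (",
      sum(x$nodes$kind == "protein"), "protein /",
      sum(x$nodes$kind == "ligand"), "ligand )\n")
  invisible(x)
}

# Node table under a comparison mode.
fingerprint_nodes <- function(fp, mode = c("full", "protein_only")) {
  mode <- match.arg(mode)
  n <- fp$nodes
  if (mode == "protein_only") n <- n[n$kind == "protein", , drop = FALSE]
  n
}

#' Fingerprint every complex in a list
#'
#' @param complexes named list of `kgs_complex` objects.
#' @param library a `kgs_pattern_library`.
#' @param config a [kgs_config()].
#' @return Named list of `kgs_fingerprint` objects.
#' @export
fingerprint_library <- function(complexes, library, config = kgs_config()) {
  out <- lapply(complexes, build_fingerprint, library = library, config = config)
  names(out) <- vapply(out, `[[`, character(1L), "complex_id")
  out
}
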
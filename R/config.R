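#' Default run configuration
#'
#' All tunable parameters of the pipeline with their default values:
#' the van der Waals contact margin (1 A), the binding-pocket radius
#' (4.5 A), the maximal number of Gaussian components per interaction-unit
#' type (15), the Mahalanobis match cutoff (2.5), the correspondence-graph
#' distance-compatibility ratio (1.1), the geometric overlap cutoff (1 A),
#' the minimum number of overlapped node pairs for a qualified reference
#' (5), the minimum similarity index for reference selection (0.10), and
#' the pattern-significance filters (type occurrence 100, component
#' occurrence 100, component weight 0.01).
#'
#' @param ... named overrides for any default listed above.
#' @return A named list of class `kgs_config`.
#' @examples
#' cfg <- kgs_config(min_si = 0.3)
#' cfg$pocket_cutoff
#' @export
kgs_config <- function(...) {
  cfg <- list(
    contact_margin = 1.0,       # A, added to sum of vdW radii
    pocket_cutoff = 4.5,        # A, residue inclusion radius
    k_max = 15L,                # max Gaussian components per unit type
    mahalanobis_cutoff = 2.5,   # unit-to-pattern match threshold (strict <)
    distance_ratio = 1.1,       # edge compatibility ratio in graph G
    overlap_cutoff = 1.0,       # A, post-superposition node overlap (strict <)
    min_overlap = 5L,           # overlapped pairs needed for a reference
    min_si = 0.10,              # similarity-index cutoff in reference search
    min_type_occurrence = 100L, # unit-type filter (keep if >= 100)
    min_component_occurrence = 100L, # component filter (keep if > 100)
    min_weight = 0.01,          # component weight filter (keep if >= 0.01)
    clique_cap = 2000L,         # abort comparison above this vertex count
    mode = "full",              # "full" or "protein_only" fingerprints
    seed = 0L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "kgs_config")
}
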
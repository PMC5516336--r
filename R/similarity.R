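# Fingerprint comparison: correspondence-graph construction, maximum-clique
# detection, Kabsch superposition, one-to-one geometric overlap counting,
# Tanimoto similarity index, and reference-library search.

#' Distance compatibility test
#'
#' Two inter-node distances are compatible iff
#' `max(d1, d2) < ratio * min(d1, d2)`; equal distances (including 0/0)
#' are compatible by convention.
#'
#' @param d1,d2 distances in A (vectorized).
#' @param ratio adjustable ratio, default 1.1.
#' @return Logical vector.
#' @export
distance_compatible <- function(d1, d2, ratio = 1.1) {
  d1 == d2 | pmax(d1, d2) < ratio * pmin(d1, d2)
}

#' Build the correspondence graph between two fingerprints
#'
#' Vertices are matched node pairs (same kind, same label) between P and
#' Q. Two vertices (p1,q1) and (p2,q2) are joined iff p1 != p2, q1 != q2,
#' and the p1-p2 distance in P is compatible with the q1-q2 distance in Q.
#'
#' @param P,Q `kgs_fingerprint` objects.
#' @param ratio distance-compatibility ratio.
#' @param mode `"full"` or `"protein_only"` (ligand nodes ignored).
#' @return Object of class `kgs_corr_graph`: list with `vertices`
#'   (data.frame p_idx, q_idx into the mode-filtered node tables), `edges`
#'   (two-column matrix of vertex indices), `p_nodes`, `q_nodes`.
#' @export
build_correspondence_graph <- function(P, Q, ratio = 1.1, mode = "full") {
  pn <- fingerprint_nodes(P, mode)
  qn <- fingerprint_nodes(Q, mode)
  verts <- NULL
  if (nrow(pn) && nrow(qn)) {
    grid <- expand.grid(p_idx = seq_len(nrow(pn)), q_idx = seq_len(nrow(qn)))
    ok <- pn$kind[grid$p_idx] == qn$kind[grid$q_idx] &
      pn$label[grid$p_idx] == qn$label[grid$q_idx]
    verts <- grid[ok, , drop = FALSE]
    rownames(verts) <- NULL
  }
  if (is.null(verts) || nrow(verts) == 0L) {
    return(structure(list(vertices = data.frame(p_idx = integer(0), q_idx = integer(0)),
                          edges = matrix(integer(0), 0L, 2L),
                          p_nodes = pn, q_nodes = qn), class = "kgs_corr_graph"))
  }
  dp <- as.matrix(dist(as.matrix(pn[, c("x", "y", "z")])))
  dq <- as.matrix(dist(as.matrix(qn[, c("x", "y", "z")])))
  nv <- nrow(verts)
  pairs <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
  i1 <- verts$p_idx[pairs[, 1L]]; j1 <- verts$q_idx[pairs[, 1L]]
  i2 <- verts$p_idx[pairs[, 2L]]; j2 <- verts$q_idx[pairs[, 2L]]
  ok <- i1 != i2 & j1 != j2 &
    distance_compatible(dp[cbind(i1, i2)], dq[cbind(j1, j2)], ratio)
  edges <- pairs[ok, , drop = FALSE]
  structure(list(vertices = verts, edges = unname(edges),
                 p_nodes = pn, q_nodes = qn), class = "kgs_corr_graph")
}

#' All maximum-cardinality cliques of a correspondence graph
#'
#' Clique detection runs igraph's Bron-Kerbosch (with pivoting); all
#' cliques of maximum size are returned in a deterministic order (each
#' clique sorted by vertex index, cliques ordered lexicographically).
#'
#' @param graph a `kgs_corr_graph`.
#' @param cap abort with a "too-large comparison" error above this vertex
#'   count (default 2000).
#' @return list of integer vectors (vertex indices); empty when the graph
#'   has no vertices.
#' @export
maximal_cliques <- function(graph, cap = 2000L) {
  nv <- nrow(graph$vertices)
  if (nv == 0L) return(list())
  if (nv > cap) {
    stop(structure(class = c("kgs_too_large", "error", "condition"),
                   list(message = sprintf(
                     "correspondence graph too large (%d vertices > cap %d)", nv, cap),
                     call = sys.call(-1L))))
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, t(graph$edges))
  cl <- igraph::largest_cliques(g)
  cl <- lapply(cl, function(v) sort(as.integer(v)))
  ord <- order(vapply(cl, function(v) paste(sprintf("%06d", v), collapse = ","),
                      character(1L)))
  cl[ord]
}

#' Superimpose clique-matched nodes (Kabsch)
#'
#' Least-squares proper-rotation rigid transform mapping Q's clique node
#' coordinates onto P's. Cliques with fewer than 3 vertices give an
#' under-determined rotation; a translation-only transform (centroid
#' alignment) is returned instead.
#'
#' @param clique integer vector of vertex indices.
#' @param graph the `kgs_corr_graph` the clique belongs to.
#' @return A [kgs_transform()] mapping Q coordinates onto P.
#' @export
superimpose <- function(clique, graph) {
  v <- graph$vertices[clique, , drop = FALSE]
  p <- as.matrix(graph$p_nodes[v$p_idx, c("x", "y", "z")])
  q <- as.matrix(graph$q_nodes[v$q_idx, c("x", "y", "z")])
  kabsch(p, q)
}

#' Count geometrically overlapped node pairs
#'
#' After transforming Q onto P, every matched vertex (over ALL matched
#' pairs, not only clique members) whose two nodes lie within `threshold`
#' (strict <) is an overlap candidate; a one-to-one assignment is resolved
#' greedily by increasing distance so each node is used at most once.
#'
#' @param transform a [kgs_transform()] mapping Q onto P.
#' @param graph a `kgs_corr_graph`.
#' @param threshold overlap cutoff in A (default 1.0).
#' @return list with `n_pq` (count) and `mapping` (data.frame p_idx,
#'   q_idx, dist).
#' @export
count_overlaps <- function(transform, graph, threshold = 1.0) {
  v <- graph$vertices
  if (nrow(v) == 0L)
    return(list(n_pq = 0L, mapping = data.frame(p_idx = integer(0),
                                                q_idx = integer(0),
                                                dist = numeric(0))))
  p <- as.matrix(graph$p_nodes[v$p_idx, c("x", "y", "z")])
  q <- apply_transform(as.matrix(graph$q_nodes[v$q_idx, c("x", "y", "z")]),
                       transform)
  d <- sqrt(rowSums((p - q)^2))
  cand <- which(d < threshold)
  cand <- cand[order(d[cand], cand)]
  used_p <- logical(nrow(graph$p_nodes))
  used_q <- logical(nrow(graph$q_nodes))
  keep <- integer(0)
  for (i in cand) {
    if (used_p[v$p_idx[i]] || used_q[v$q_idx[i]]) next
    used_p[v$p_idx[i]] <- TRUE
    used_q[v$q_idx[i]] <- TRUE
    keep <- c(keep, i)
  }
  list(n_pq = length(keep),
       mapping = data.frame(p_idx = v$p_idx[keep], q_idx = v$q_idx[keep],
                            dist = d[keep]))
}

#' Tanimoto similarity index over fingerprint nodes
#'
#' `SI = Npq / (Np + Nq - Npq)`; two empty fingerprints give 0 by
#' convention.
#'
#' @param n_p,n_q node counts of the two fingerprints.
#' @param n_pq number of overlapped node pairs (must not exceed
#'   `min(n_p, n_q)`).
#' @return Similarity index in [0, 1].
#' @export
similarity_index <- function(n_p, n_q, n_pq) {
  stopifnot(n_pq <= min(n_p, n_q))
  denom <- n_p + n_q - n_pq
  if (denom == 0) return(0)
  n_pq / denom
}

#' Compare two fingerprints
#'
#' Builds the correspondence graph, enumerates all maximum cliques, seeds
#' a superposition from each, counts overlapped node pairs over all
#' matched pairs, and retains the solution with the maximal overlap count
#' (ties resolved by the deterministic clique order). Comparison runs in a
#' canonical direction (the lexicographically smaller complex_id acts as
#' P) so that `si(P, Q) == si(Q, P)`.
#'
#' @param P,Q `kgs_fingerprint` objects.
#' @param config a [kgs_config()] (distance_ratio, overlap_cutoff,
#'   min_overlap, clique_cap, mode).
#' @return Object of class `kgs_similarity`: list with `id_p`, `id_q`,
#'   `n_p`, `n_q`, `n_pq`, `si`, `qualified` (n_pq >= min_overlap),
#'   `mapping`, `transform` (maps Q onto P in the *caller's* orientation).
#' @export
compare_fingerprints <- function(P, Q, config = kgs_config()) {
  swapped <- Q$complex_id < P$complex_id
  A <- if (swapped) Q else P
  B <- if (swapped) P else Q
  g <- build_correspondence_graph(A, B, ratio = config$distance_ratio,
                                  mode = config$mode)
  n_a <- nrow(g$p_nodes); n_b <- nrow(g$q_nodes)
  best <- list(n_pq = 0L,
               mapping = data.frame(p_idx = integer(0), q_idx = integer(0),
                                    dist = numeric(0)))
  best_tr <- kgs_transform()
  cliques <- maximal_cliques(g, cap = config$clique_cap)
  for (cl in cliques) {
    tr <- superimpose(cl, g)
    ov <- count_overlaps(tr, g, threshold = config$overlap_cutoff)
    if (ov$n_pq > best$n_pq) {
      best <- ov
      best_tr <- tr
    }
  }
  si <- similarity_index(n_a, n_b, best$n_pq)
  mapping <- best$mapping
  transform <- best_tr
  if (swapped) {
    mapping <- data.frame(p_idx = mapping$q_idx, q_idx = mapping$p_idx,
                          dist = mapping$dist)
    transform <- invert_transform(transform)
  }
  structure(list(id_p = P$complex_id, id_q = Q$complex_id,
                 n_p = if (swapped) n_b else n_a,
                 n_q = if (swapped) n_a else n_b,
                 n_pq = best$n_pq, si = si,
                 qualified = best$n_pq >= config$min_overlap,
                 mapping = mapping, transform = transform),
            class = "kgs_similarity")
}

#' @export
print.kgs_similarity <- function(x, ...) {
  cat(sprintf("<kgs_similarity> %s vs %s: Np=%d Nq=%d Npq=%d SI=%.3f%s\n",
              x$id_p, x$id_q, x$n_p, x$n_q, x$n_pq, x$si,
              if (x$qualified) " (qualified)" else ""))
  invisible(x)
}

#' Search a reference library for the best reference complex
#'
#' Compares the query fingerprint against every library fingerprint
#' (excluding the query's own id and any id in `exclude_ids`), keeps
#' qualified candidates (at least `min_overlap` overlapped pairs) with
#' `si >= min_si`, and returns the best by (si desc, n_pq desc,
#' complex_id asc). Candidates whose comparison exceeds the clique cap are
#' skipped with a warning.
#'
#' @param query a `kgs_fingerprint`.
#' @param fingerprints named list of reference `kgs_fingerprint`s.
#' @param config a [kgs_config()] (min_si and comparison parameters).
#' @param exclude_ids complex ids to skip (besides the query itself).
#' @return list with `reference` (best `kgs_similarity`, or `NULL` if none
#'   qualifies) and `ranking` (data.frame over all compared candidates:
#'   complex_id, si, n_pq, qualified).
#' @export
search_reference <- function(query, fingerprints, config = kgs_config(),
                             exclude_ids = character(0)) {
  if (length(fingerprints) == 0L) {
    warning("empty reference library")
    return(list(reference = NULL,
                ranking = data.frame(complex_id = character(0), si = numeric(0),
                                     n_pq = integer(0), qualified = logical(0))))
  }
  rows <- list(); results <- list()
  for (fp in fingerprints) {
    id <- fp$complex_id
    if (id == query$complex_id || id %in% exclude_ids) next
    res <- tryCatch(compare_fingerprints(query, fp, config),
                    kgs_too_large = function(e) {
                      warning("skipping '", id, "': ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      complex_id = id, si = res$si, n_pq = res$n_pq,
      qualified = res$qualified, stringsAsFactors = FALSE)
    results[[id]] <- res
  }
  if (length(rows) == 0L)
    return(list(reference = NULL,
                ranking = data.frame(complex_id = character(0), si = numeric(0),
                                     n_pq = integer(0), qualified = logical(0))))
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$si, -ranking$n_pq, ranking$complex_id), , drop = FALSE]
  rownames(ranking) <- NULL
  ok <- ranking$qualified & ranking$si >= config$min_si
  reference <- if (any(ok)) results[[ranking$complex_id[which(ok)[1L]]]] else NULL
  list(reference = reference, ranking = ranking)
}
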
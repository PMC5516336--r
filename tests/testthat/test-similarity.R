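test_that("distance compatibility implements the ratio rule with equality convention", {
  expect_true(distance_compatible(10, 9.2))    # 10 < 1.1 * 9.2 = 10.12
  expect_false(distance_compatible(10, 9.0))   # 10 >= 9.9
  expect_true(distance_compatible(0, 0))       # stated convention
  expect_true(distance_compatible(5, 5))
  expect_false(distance_compatible(0, 0.5))
  expect_equal(distance_compatible(c(10, 10, 0), c(9.2, 9, 0)),
               c(TRUE, FALSE, TRUE))
})

test_that("correspondence graph: vertices by label, edges by distance compatibility", {
  set.seed(61)
  xyz <- matrix(rnorm(18, sd = 5), 6, 3)
  P <- make_fp("P", rep(c("protein", "ligand"), 3),
               c("GLY", "O.2", "ALA", "N.3", "ASP", "C.3"), xyz)
  # identical fingerprint: diagonal vertices form a clique of size n
  g <- build_correspondence_graph(P, P)
  diag_v <- which(g$vertices$p_idx == g$vertices$q_idx)
  expect_length(diag_v, 6L)
  cl <- maximal_cliques(g)
  expect_gte(length(cl[[1]]), 6L)
  expect_true(all(diag_v %in% cl[[1]]))

  # disjoint labels -> zero vertices
  Q <- make_fp("Q", rep("protein", 3), c("TRP", "TYR", "PHE"), xyz[1:3, ])
  g0 <- build_correspondence_graph(P, Q)
  expect_equal(nrow(g0$vertices), 0L)
  expect_length(maximal_cliques(g0), 0L)

  # mixed kinds never pair even with equal labels
  R <- make_fp("R", c("protein", "ligand"), c("GLY", "GLY"), xyz[1:2, ])
  gR <- build_correspondence_graph(P, R)
  expect_true(all(gR$p_nodes$kind[gR$vertices$p_idx] ==
                    gR$q_nodes$kind[gR$vertices$q_idx]))

  # edge set equals the brute-force all-pairs compatibility check
  set.seed(62)
  Q2 <- make_fp("Q2", rep(c("protein", "ligand"), 3),
                c("GLY", "O.2", "ALA", "N.3", "ASP", "C.3"),
                xyz + matrix(rnorm(18, sd = 0.5), 6, 3))
  g2 <- build_correspondence_graph(P, Q2)
  v <- g2$vertices
  expected <- matrix(integer(0), 0L, 2L)
  dp <- as.matrix(dist(as.matrix(g2$p_nodes[, c("x", "y", "z")])))
  dq <- as.matrix(dist(as.matrix(g2$q_nodes[, c("x", "y", "z")])))
  for (i in seq_len(nrow(v) - 1L)) for (j in (i + 1L):nrow(v)) {
    if (v$p_idx[i] == v$p_idx[j] || v$q_idx[i] == v$q_idx[j]) next
    if (distance_compatible(dp[v$p_idx[i], v$p_idx[j]], dq[v$q_idx[i], v$q_idx[j]]))
      expected <- rbind(expected, c(i, j))
  }
  got <- g2$edges[order(g2$edges[, 1L], g2$edges[, 2L]), , drop = FALSE]
  expect_equal(got, expected[order(expected[, 1L], expected[, 2L]), , drop = FALSE])
})

test_that("maximum cliques match exhaustive enumeration and known graphs", {
  # 5-cycle: maximum cliques are its 5 edges
  c5 <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(1L, 5L))
  cl <- maximal_cliques(abstract_graph(5L, c5))
  expect_length(cl, 5L)
  expect_true(all(lengths(cl) == 2L))
  # complete graph K4: a single maximum clique of size 4
  k4 <- t(combn(4L, 2L))
  cl4 <- maximal_cliques(abstract_graph(4L, k4))
  expect_length(cl4, 1L)
  expect_equal(cl4[[1]], 1:4)
  # edgeless graph: all single-vertex cliques
  cl1 <- maximal_cliques(abstract_graph(3L, matrix(integer(0), 0L, 2L)))
  expect_true(all(lengths(cl1) == 1L))

  # random graphs vs exhaustive subset enumeration
  set.seed(63)
  for (i in 1:40) {
    n <- sample(4:12, 1L)
    p <- runif(1L, 0.2, 0.8)
    all_pairs <- t(combn(n, 2L))
    edges <- all_pairs[runif(nrow(all_pairs)) < p, , drop = FALSE]
    cl <- maximal_cliques(abstract_graph(n, edges))
    expect_equal(length(cl[[1]]), bf_max_clique_size(n, edges))
  }

  # deterministic order: sorted within and across cliques
  cl <- maximal_cliques(abstract_graph(5L, c5))
  keys <- vapply(cl, paste, character(1L), collapse = ",")
  expect_equal(keys, sort(keys))

  # vertex cap -> explicit too-large condition
  big <- structure(list(vertices = data.frame(p_idx = 1:10, q_idx = 1:10),
                        edges = matrix(integer(0), 0L, 2L),
                        p_nodes = NULL, q_nodes = NULL),
                   class = "kgs_corr_graph")
  expect_error(maximal_cliques(big, cap = 5L), class = "kgs_too_large")
})

test_that("Kabsch superposition recovers planted rigid motions, never reflects", {
  set.seed(64)
  p <- matrix(rnorm(24, sd = 4), 8, 3)
  tr <- random_transform()
  q <- apply_transform(p, invert_transform(tr))
  got <- kgs2:::kabsch(p, q)
  expect_equal(apply_transform(q, got), p, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(got$R), 1, tolerance = 1e-9)

  # 3 non-collinear pairs with a hand-built rotation
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  p3 <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  q3 <- p3 %*% Rz # = Rz^T applied row-wise
  got3 <- kgs2:::kabsch(p3, q3)
  expect_equal(got3$R, Rz, tolerance = 1e-9, ignore_attr = TRUE)

  # mirrored point set: proper rotation enforced, residual nonzero
  qm <- p; qm[, 1L] <- -qm[, 1L]
  gotm <- kgs2:::kabsch(p, qm)
  expect_equal(det(gotm$R), 1, tolerance = 1e-9)
  expect_gt(sqrt(mean(rowSums((apply_transform(qm, gotm) - p)^2))), 0.1)

  # < 3 pairs: translation-only
  got2 <- kgs2:::kabsch(p[1:2, ], q[1:2, ])
  expect_equal(got2$R, diag(3))
})

test_that("overlap counting is strict, one-to-one, over all matched pairs", {
  set.seed(65)
  xyz <- matrix(rnorm(15, sd = 6), 5, 3)
  labels <- c("GLY", "ALA", "ASP", "SER", "THR")
  P <- make_fp("P", rep("protein", 5), labels, xyz)
  Qxyz <- xyz
  Qxyz[5L, ] <- Qxyz[5L, ] + c(1.5, 0, 0) # one node displaced beyond 1 A
  Q <- make_fp("Q", rep("protein", 5), labels, Qxyz)
  g <- build_correspondence_graph(P, Q)
  ident <- kgs_transform()
  ov <- count_overlaps(ident, g)
  expect_equal(ov$n_pq, 4L)
  # exact copy -> all nodes overlap
  gP <- build_correspondence_graph(P, P)
  expect_equal(count_overlaps(ident, gP)$n_pq, 5L)
  # conflict: two q-nodes within 1 A of one p-node -> exactly one counted
  P1 <- make_fp("P1", rep("protein", 2), c("GLY", "GLY"),
                rbind(c(0, 0, 0), c(20, 0, 0)))
  Q1 <- make_fp("Q1", rep("protein", 2), c("GLY", "GLY"),
                rbind(c(0.2, 0, 0), c(0.4, 0, 0)))
  g1 <- build_correspondence_graph(P1, Q1)
  ov1 <- count_overlaps(ident, g1)
  expect_equal(ov1$n_pq, 1L)
  expect_equal(ov1$mapping$dist, 0.2, tolerance = 1e-9) # nearest-first greedy
})

test_that("similarity index follows the Tanimoto form with conventions", {
  expect_equal(similarity_index(10, 10, 5), 1 / 3)
  expect_equal(similarity_index(7, 7, 7), 1)
  expect_equal(similarity_index(8, 6, 0), 0)
  expect_equal(similarity_index(0, 0, 0), 0)
  expect_error(similarity_index(3, 3, 4))
})

test_that("fingerprint comparison: self-identity, pruned copies, qualification", {
  set.seed(66)
  xyz <- matrix(rnorm(24, sd = 6), 8, 3)
  labels <- c("GLY", "ALA", "ASP", "SER", "O.2", "N.3", "C.3", "O.3")
  kinds <- c(rep("protein", 4), rep("ligand", 4))
  P <- make_fp("AAA", kinds, labels, xyz)

  # P vs itself
  self <- compare_fingerprints(P, P)
  expect_equal(self$si, 1)
  expect_equal(self$n_pq, 8L)
  expect_true(self$qualified)

  # rigidly moved copy with 3 nodes displaced: n_pq = 5, SI = 5/11
  tr <- random_transform()
  Qxyz <- apply_transform(xyz, tr)
  Qxyz[c(2, 5, 8), ] <- Qxyz[c(2, 5, 8), ] + matrix(c(4, 3, -5, 2, 6, 1, -3, 4, 2), 3, 3)
  Q <- make_fp("BBB", kinds, labels, Qxyz)
  res <- compare_fingerprints(P, Q)
  expect_equal(res$n_pq, 5L)
  expect_equal(res$si, 5 / 11)
  expect_true(res$qualified)

  # only 4 correspondences left -> not qualified
  Q2xyz <- apply_transform(xyz, tr)
  Q2xyz[c(2, 5, 8, 3), ] <- Q2xyz[c(2, 5, 8, 3), ] + 5
  Q2 <- make_fp("CCC", kinds, labels, Q2xyz)
  res2 <- compare_fingerprints(P, Q2)
  expect_equal(res2$n_pq, 4L)
  expect_false(res2$qualified)

  # empty vs empty
  E <- make_fp("EEE", character(0), character(0), matrix(0, 0, 3))
  res0 <- compare_fingerprints(E, E)
  expect_equal(res0$si, 0)
  expect_false(res0$qualified)
})

test_that("similarity is symmetric and bounded on library fixtures", {
  sh <- shared_library()
  ids <- names(sh$fps)
  set.seed(67)
  for (i in 1:8) {
    a <- sample(ids, 1L); b <- sample(setdiff(ids, a), 1L)
    r1 <- compare_fingerprints(sh$fps[[a]], sh$fps[[b]])
    r2 <- compare_fingerprints(sh$fps[[b]], sh$fps[[a]])
    expect_equal(r1$si, r2$si)
    expect_equal(r1$n_pq, r2$n_pq)
    expect_lte(r1$n_pq, min(r1$n_p, r1$n_q))
    expect_gte(r1$si, 0); expect_lte(r1$si, 1)
  }
  # si(P, P) = 1 whenever n >= 5
  fp <- sh$fps[[ids[1L]]]
  fp2 <- fp; fp2$complex_id <- "ZZZ"
  expect_equal(compare_fingerprints(fp, fp2)$si, 1)
})

test_that("adding a shared node never decreases the overlap count", {
  sh <- shared_library()
  P <- sh$fps[["CPX001"]]
  Q <- sh$fps[["CPX002"]]
  base <- compare_fingerprints(P, Q)
  extra_p <- data.frame(kind = "protein", label = "TRP", anchor = "A:99:",
                        x = 40, y = 40, z = 40, multiplicity = 1L,
                        stringsAsFactors = FALSE)
  tr <- base$transform # maps Q onto P
  inv <- invert_transform(tr)
  pos_q <- apply_transform(c(40, 40, 40), inv)
  extra_q <- extra_p
  extra_q$x <- pos_q[1L]; extra_q$y <- pos_q[2L]; extra_q$z <- pos_q[3L]
  P2 <- P; P2$nodes <- rbind(P$nodes, extra_p); P2$n_nodes <- P$n_nodes + 1L
  Q2 <- Q; Q2$nodes <- rbind(Q$nodes, extra_q); Q2$n_nodes <- Q$n_nodes + 1L
  grown <- compare_fingerprints(P2, Q2)
  expect_gte(grown$n_pq, base$n_pq)
})

test_that("reference search excludes self, honours min_si, breaks ties deterministically", {
  sh <- shared_library()
  cfg <- kgs_config()
  # library containing the query itself + its twin: twin wins (self excluded)
  hit <- search_reference(sh$fps[["CPX001"]],
                          sh$fps[c("CPX001", "CPX002")], cfg)
  expect_equal(hit$reference$id_q, "CPX002")
  # explicit exclusion removes the twin too
  hit2 <- search_reference(sh$fps[["CPX001"]], sh$fps[c("CPX001", "CPX002")],
                           cfg, exclude_ids = "CPX002")
  expect_null(hit2$reference)
  # all candidates below min_si -> none (cross-pair similarities are ~0)
  others <- sh$fps[setdiff(names(sh$fps), c("CPX001", "CPX002"))]
  hi_cfg <- kgs_config(min_si = 0.9)
  hit3 <- search_reference(sh$fps[["CPX001"]], others, hi_cfg)
  expect_null(hit3$reference)
  # ranking table covers all candidates, sorted by si then n_pq then id
  expect_equal(nrow(hit3$ranking), length(others))
  expect_true(!is.unsorted(rev(hit3$ranking$si)))
  # empty library -> warning and no reference
  expect_warning(hit4 <- search_reference(sh$fps[["CPX001"]], list()), "empty")
  expect_null(hit4$reference)
})
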
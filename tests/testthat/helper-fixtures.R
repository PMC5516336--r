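# Shared fixtures and independent brute-force oracles.

# ---- memoized heavy fixture: twinned library + mined patterns ----------
.fixture_cache <- new.env(parent = emptyenv())

shared_library <- function() {
  if (!exists("shared", envir = .fixture_cache)) {
    lib <- make_library(n_pairs = 12, seed = 1)
    units <- aggregate_units(lib$complexes)
    set.seed(99)
    patterns <- mine_patterns(replicate_units(units, times = 5, jitter_sd = 0.2))
    fps <- fingerprint_library(lib$complexes, patterns)
    assign("shared", list(lib = lib, units = units, patterns = patterns,
                          fps = fps), envir = .fixture_cache)
  }
  get("shared", envir = .fixture_cache)
}

# ---- small literal PDB fixtures ----------------------------------------
# Three residues (GLY, ALA, GLY) spaced 15 A apart; idealized coordinates.
fixture_pdb_lines <- function(altloc = FALSE) {
  mk <- function(serial, name, alt, res, resno, x, y, z, occ, el) {
    sprintf("ATOM  %5d %4s%1s%-3s A%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
            serial, sprintf(" %-3s", name), alt, res, resno, x, y, z, occ, el)
  }
  gly <- function(s0, resno, dx) c(
    mk(s0 + 0L, "N", " ", "GLY", resno, dx - 0.525, 1.362, 0, 1, "N"),
    mk(s0 + 1L, "CA", " ", "GLY", resno, dx + 0.000, 0.000, 0, 1, "C"),
    mk(s0 + 2L, "C", " ", "GLY", resno, dx + 1.526, 0.000, 0, 1, "C"),
    mk(s0 + 3L, "O", " ", "GLY", resno, dx + 2.160, 1.055, 0, 1, "O"))
  ala_cb <- if (altloc) c(
    mk(9L, "CB", "A", "ALA", 2L, 15 - 0.518, -0.774, -1.208, 0.60, "C"),
    mk(10L, "CB", "B", "ALA", 2L, 15 - 0.418, -0.674, -1.108, 0.40, "C"))
  else
    mk(9L, "CB", " ", "ALA", 2L, 15 - 0.518, -0.774, -1.208, 1.00, "C")
  c(gly(1L, 1L, 0),
    mk(5L, "N", " ", "ALA", 2L, 15 - 0.525, 1.362, 0, 1, "N"),
    mk(6L, "CA", " ", "ALA", 2L, 15 + 0.000, 0.000, 0, 1, "C"),
    mk(7L, "C", " ", "ALA", 2L, 15 + 1.526, 0.000, 0, 1, "C"),
    mk(8L, "O", " ", "ALA", 2L, 15 + 2.160, 1.055, 0, 1, "O"),
    ala_cb,
    gly(11L, 3L, 30),
    "END")
}

write_fixture_pdb <- function(path, altloc = FALSE) {
  writeLines(fixture_pdb_lines(altloc), path)
  path
}

fixture_mol2_lines <- function() {
  c("@<TRIPOS>MOLECULE", "toy5", "5 4 1", "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    "1 C1  0.0000  0.0000 0.0000 C.3 1 LIG 0.0",
    "2 C2  1.5260  0.0000 0.0000 C.2 1 LIG 0.0",
    "3 O1  2.1600  1.0550 0.0000 O.2 1 LIG 0.0",
    "4 N1  2.2000 -1.3000 0.0000 N.3 1 LIG 0.0",
    "5 O2  3.7000 -1.3000 0.0000 O.3 1 LIG 0.0",
    "@<TRIPOS>BOND",
    "1 1 2 1", "2 2 3 2", "3 2 4 1", "4 4 5 1")
}

fixture_sdf_acetone <- function() {
  c("acetone", "  synthetic", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.1000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.2000   -1.3000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  2  0", "  2  4  1  0",
    "M  END", "$$$$")
}

# One synthetic complex with identity layout (no rotation, origin), no
# jitter: planted geometry is exactly reproducible by hand.
identity_complex <- function(residues = "GLY", lig_types = "O.2", ...) {
  n <- length(residues)
  layout <- list(positions = cbind((seq_len(n) - 1) * 15, 0, 0),
                 rotations = replicate(n, diag(3), simplify = FALSE))
  make_complex("IDENT", residues, lig_types, layout = layout, jitter_sd = 0, ...)
}

# Hand-built fingerprint for similarity tests.
make_fp <- function(id, kind, label, xyz, affinity = NA_real_) {
  xyz <- as.matrix(xyz)
  structure(list(
    complex_id = id,
    nodes = data.frame(kind = kind, label = label,
                       anchor = as.character(seq_along(kind)),
                       x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                       multiplicity = rep(1L, length(kind)),
                       stringsAsFactors = FALSE),
    n_nodes = length(kind), affinity = affinity), class = "kgs_fingerprint")
}

# Fake correspondence graph over an arbitrary abstract graph (for clique
# oracle tests): n vertices, edges as a 2-column matrix.
abstract_graph <- function(n, edges) {
  structure(list(vertices = data.frame(p_idx = seq_len(n), q_idx = seq_len(n)),
                 edges = edges,
                 p_nodes = data.frame(x = numeric(n)),
                 q_nodes = data.frame(x = numeric(n))),
            class = "kgs_corr_graph")
}

# ---- brute-force oracles ------------------------------------------------

# All-pairs contact scan.
bf_contacts <- function(protein, ligand, margin = 1.0) {
  pa <- protein$atoms[!protein$atoms$is_hydrogen, , drop = FALSE]
  la <- ligand$atoms[!ligand$atoms$is_hydrogen, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(la))) {
    d <- sqrt((pa$x[i] - la$x[j])^2 + (pa$y[i] - la$y[j])^2 + (pa$z[i] - la$z[j])^2)
    if (d < pa$vdw[i] + la$vdw[j] + margin)
      out[[length(out) + 1L]] <- c(pa$serial[i], la$serial[j])
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, function(p) paste(p, collapse = "-"), character(1L)))
}

# All simple 3-paths in a bond graph, canonicalized like the package does.
bf_3paths <- function(atoms, bonds, anchor = NULL) {
  ser <- atoms$serial
  nm <- setNames(atoms$name, as.character(ser))
  has_bond <- function(a, b) any((bonds[, 1L] == a & bonds[, 2L] == b) |
                                   (bonds[, 1L] == b & bonds[, 2L] == a))
  out <- character(0)
  for (u in ser) for (m in ser) for (w in ser) {
    if (u >= w || u == m || w == m) next
    if (!has_bond(u, m) || !has_bond(m, w)) next
    if (!is.null(anchor) && !(anchor %in% c(u, m, w))) next
    a <- c(u, m, w)
    if (nm[[as.character(w)]] < nm[[as.character(u)]] ||
        (nm[[as.character(w)]] == nm[[as.character(u)]] && w < u))
      a <- c(w, m, u)
    out <- c(out, paste(a, collapse = "-"))
  }
  sort(unique(out))
}

# Exhaustive maximum-clique size via subset enumeration (n <= 16).
bf_max_clique_size <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    mem <- which(bitwAnd(mask, 2^(0:(n - 1L))) > 0L)
    k <- length(mem)
    if (k <= best) next
    ok <- TRUE
    if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k)
      if (!adj[mem[i], mem[j]]) { ok <- FALSE; break }
    if (ok) best <- k
  }
  best
}

bf_mahalanobis <- function(x, mu, S) {
  d <- as.numeric(x - mu)
  sqrt(drop(t(d) %*% solve(S) %*% d))
}

random_spd <- function() {
  A <- matrix(rnorm(9L), 3L)
  A %*% t(A) + diag(3) * 0.1
}
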
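# Synthetic fixture generator. Builds toy protein-ligand complexes with
# planted interaction units at known local-frame geometries, so that every
# pipeline stage (unit extraction, pattern mining, fingerprinting,
# similarity search, scoring) can be tested against exact ground truth
# without any external data.
#
# Geometry: each "residue" is an idealized glycine/alanine/aspartate
# template placed with a random rotation at well-separated positions
# (>= 15 A), so no cross-residue contacts occur. Each planted ligand atom
# sits 0.55 A inside the vdW+1 A contact limit of the backbone carbonyl O along the C=O axis (plus a
# 0.8 A out-of-plane lift), which puts exactly one protein atom (O) within
# vdW + 1 A contact, and O lies on exactly one intra-residue 3-path
# (CA-C-O) - so each planted atom yields exactly one interaction unit of a
# known type key. The ligand is a chemically nonsensical but syntactically
# valid Mol2 molecule (atoms chained by single bonds); these fixtures are
# synthetic test articles, not chemistry.

residue_template <- function(resname) {
  N <- c(-0.525, 1.362, 0)
  CA <- c(0, 0, 0)
  C <- c(1.526, 0, 0)
  O <- C + 1.231 * c(0.515, 0.857, 0)
  base <- rbind(N = N, CA = CA, C = C, O = O)
  if (resname == "GLY") return(base)
  CB <- c(-0.518, -0.774, -1.208)
  if (resname == "ALA") return(rbind(base, CB = CB))
  if (resname == "ASP") {
    CG <- CB + 1.52 * unitv(c(-0.502, -0.396, -1.252))
    d1 <- unitv(cross3(CG - CB, c(0, 1, 0)))
    axis <- unitv(CG - CB)
    u1 <- unitv(axis * cos(pi / 3) + d1 * sin(pi / 3))
    u2 <- unitv(axis * cos(pi / 3) - d1 * sin(pi / 3))
    OD1 <- CG + 1.25 * u1
    OD2 <- CG + 1.25 * u2
    return(rbind(base, CB = CB, CG = CG, OD1 = OD1, OD2 = OD2))
  }
  stop("no template for residue ", resname)
}

# Template-frame position of the planted ligand atom: beyond the carbonyl
# O along the C=O axis with an out-of-plane lift. The distance to the
# anchor O is set 0.55 A inside the vdW + 1 A contact limit for the
# ligand element, which leaves the backbone C safely outside its own
# contact limit for every supported element (O/N/C) even under the
# capped positional jitter.
plant_point <- function(tpl, lig_element = "O", lift = 0.8) {
  r_l <- BONDI_RADII[toupper(lig_element)]
  if (is.na(r_l)) r_l <- DEFAULT_VDW
  target <- r_l + BONDI_RADII[["O"]] + 1.0 - 0.55
  along <- sqrt(target^2 - lift^2)
  u <- unitv(tpl["O", ] - tpl["C", ])
  nrm <- unitv(cross3(tpl["C", ] - tpl["CA", ], tpl["O", ] - tpl["C", ]))
  tpl["O", ] + along * u + lift * nrm
}

#' Random well-separated residue layout
#'
#' Rejection-samples `n` positions with pairwise separation of at least
#' `spacing` inside a cube, plus one random rotation per residue. Uses the
#' current RNG stream.
#'
#' @param n number of residues.
#' @param spacing minimum centre separation (A).
#' @param box cube half-width (A); grown automatically if too tight.
#' @return list with `positions` (n x 3) and `rotations` (list of 3x3).
#' @export
make_layout <- function(n, spacing = 15, box = NULL) {
  if (is.null(box)) box <- max(15, spacing * n^(1 / 3) * 1.6)
  pos <- matrix(NA_real_, n, 3L)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- runif(3L, -box, box)
    ok <- placed == 0L ||
      min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2L, cand)^2))) >= spacing
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
    tries <- tries + 1L
    if (tries > 10000L) {
      box <- box * 1.3
      tries <- 0L
    }
  }
  rots <- lapply(seq_len(n), function(i) random_transform(0)$R)
  list(positions = pos, rotations = rots)
}

#' Build one synthetic complex with planted interaction units
#'
#' One planted unit per residue: residue template `residues[i]` hosts a
#' ligand atom of SYBYL type `lig_types[i]` at the planted local geometry
#' plus isotropic Gaussian jitter. The generator verifies by plain distance
#' arithmetic that the realized contacts are exactly the planted ones and
#' errors otherwise ("unrealizable spec").
#'
#' @param complex_id identifier.
#' @param residues character vector of template names (`"GLY"`/`"ALA"`).
#' @param lig_types SYBYL types of the planted ligand atoms (same length).
#' @param layout from [make_layout()]; generated if `NULL` (current RNG).
#' @param jitter_sd isotropic positional jitter of the planted atom (A).
#' @param affinity experimental affinity to record (logKa).
#' @param transform optional [kgs_transform()] applied to the whole
#'   complex (e.g. to build a rigidly moved twin).
#' @param dir if non-`NULL`, write `<id>_protein.pdb`, `<id>_ligand.mol2`
#'   and a ground-truth manifest JSON into `dir/<id>/`.
#' @return list with `complex` (a `kgs_complex`), `manifest` (data.frame:
#'   type_key, res_key, lig_serial), and file paths when written.
#' @export
make_complex <- function(complex_id, residues, lig_types, layout = NULL,
                         jitter_sd = 0.1, affinity = NA_real_,
                         transform = NULL, dir = NULL) {
  stopifnot(length(residues) == length(lig_types), length(residues) >= 1L)
  n <- length(residues)
  if (is.null(layout)) layout <- make_layout(n)
  stopifnot(nrow(layout$positions) >= n)

  prot_rows <- list()
  lig_rows <- list()
  manifest <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    tpl <- residue_template(residues[i])
    if (!("O" %in% rownames(tpl))) stop("template lacks planting anchor O")
    R <- layout$rotations[[i]]
    pos <- layout$positions[i, ]
    world <- tpl %*% t(R) + matrix(pos, nrow(tpl), 3L, byrow = TRUE)
    for (j in seq_len(nrow(tpl))) {
      serial <- serial + 1L
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        serial = serial, name = rownames(tpl)[j],
        element = substr(rownames(tpl)[j], 1L, 1L),
        resname = residues[i], chain = "A", resno = i, insert = "",
        x = world[j, 1L], y = world[j, 2L], z = world[j, 3L],
        stringsAsFactors = FALSE)
    }
    jit <- rnorm(3L, 0, jitter_sd)
    if (vnorm(jit) > 3 * jitter_sd) jit <- jit * (3 * jitter_sd) / vnorm(jit)
    lp <- plant_point(tpl, toupper(sub("\\..*$", "", lig_types[i]))) + jit
    lw <- drop(R %*% lp) + pos
    lig_rows[[i]] <- data.frame(
      serial = i, name = paste0("L", i), sybyl_type = lig_types[i],
      element = toupper(sub("\\..*$", "", lig_types[i])),
      x = lw[1L], y = lw[2L], z = lw[3L], stringsAsFactors = FALSE)
    manifest[[i]] <- data.frame(
      type_key = unit_type_key(residues[i], "CA", "C", "O", lig_types[i]),
      res_key = residue_key("A", i, ""), lig_serial = i,
      stringsAsFactors = FALSE)
  }
  prot_atoms <- do.call(rbind, prot_rows)
  lig_atoms <- do.call(rbind, lig_rows)
  manifest <- do.call(rbind, manifest)

  if (!is.null(transform)) {
    for (tab in c("prot_atoms", "lig_atoms")) {
      m <- get(tab)
      xyz <- apply_transform(as.matrix(m[, c("x", "y", "z")]), transform)
      m$x <- xyz[, 1L]; m$y <- xyz[, 2L]; m$z <- xyz[, 3L]
      assign(tab, m)
    }
  }

  validate_planted_contacts(prot_atoms, lig_atoms, manifest)

  if (!is.null(dir)) {
    sub <- file.path(dir, complex_id)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    ppath <- file.path(sub, paste0(complex_id, "_protein.pdb"))
    lpath <- file.path(sub, paste0(complex_id, "_ligand.mol2"))
    write_pdb_atoms(prot_atoms, ppath)
    write_mol2_atoms(lig_atoms, lpath, name = complex_id)
    jsonlite::write_json(manifest, file.path(sub, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    cx <- kgs_complex(complex_id, read_protein_pdb(ppath), read_ligand(lpath),
                      affinity = affinity)
    return(list(complex = cx, manifest = manifest,
                protein_path = ppath, ligand_path = lpath))
  }
  prot <- structure(list(atoms = within_protein_frame(prot_atoms), bonds = NULL,
                         source = NA_character_), class = "kgs_protein")
  prot$bonds <- perceive_protein_bonds(prot$atoms)
  lig <- structure(list(atoms = within_ligand_frame(lig_atoms), bonds = chain_bonds(nrow(lig_atoms)),
                        name = complex_id, source = NA_character_), class = "kgs_ligand")
  list(complex = kgs_complex(complex_id, prot, lig, affinity = affinity),
       manifest = manifest)
}

within_protein_frame <- function(a) {
  a$is_hydrogen <- a$element %in% c("H", "D")
  a$standard_aa <- a$resname %in% STANDARD_AA
  a$res_key <- residue_key(a$chain, a$resno, a$insert)
  a
}

within_ligand_frame <- function(a) {
  a$is_hydrogen <- a$element %in% c("H", "D")
  a
}

chain_bonds <- function(n) {
  if (n < 2L) return(data.frame(origin = integer(0), target = integer(0),
                                order = character(0)))
  data.frame(origin = seq_len(n - 1L), target = 2:n,
             order = rep("1", n - 1L), stringsAsFactors = FALSE)
}

# Plain distance arithmetic check (independent of the extraction code):
# ligand atom i must contact the carbonyl O of its own residue and nothing
# else, with a 0.05 A safety margin on non-contacts.
validate_planted_contacts <- function(prot_atoms, lig_atoms, manifest) {
  pv <- BONDI_RADII[prot_atoms$element]
  pv[is.na(pv)] <- DEFAULT_VDW
  lv <- BONDI_RADII[lig_atoms$element]
  lv[is.na(lv)] <- DEFAULT_VDW
  pk <- residue_key(prot_atoms$chain, prot_atoms$resno, prot_atoms$insert)
  for (i in seq_len(nrow(lig_atoms))) {
    l <- c(lig_atoms$x[i], lig_atoms$y[i], lig_atoms$z[i])
    d <- sqrt((prot_atoms$x - l[1L])^2 + (prot_atoms$y - l[2L])^2 +
                (prot_atoms$z - l[3L])^2)
    lim <- pv + lv[i] + 1.0
    planted <- prot_atoms$name == "O" & pk == manifest$res_key[i]
    if (!any(d[planted] < lim[planted] - 0.05))
      stop("unrealizable fixture: planted atom ", i, " lost its anchor contact")
    if (any(d[!planted] < lim[!planted] + 0.05))
      stop("unrealizable fixture: planted atom ", i, " contacts a non-anchor atom")
  }
  invisible(TRUE)
}

# Minimal fixed-width PDB ATOM writer for fixture proteins.
write_pdb_atoms <- function(a, path) {
  name4 <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name), a$name)
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, name4, a$resname, a$chain, a$resno,
    a$x, a$y, a$z, 1.0, 0.0, a$element)
  writeLines(c(lines, "END"), path)
}

# Minimal SYBYL Mol2 writer for fixture ligands.
write_mol2_atoms <- function(a, path, name = "LIG") {
  n <- nrow(a)
  bonds <- chain_bonds(n)
  lines <- c(
    "@<TRIPOS>MOLECULE", name,
    sprintf("%d %d 1", n, nrow(bonds)),
    "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %4d %-8s %10.4f",
            a$serial, a$name, a$x, a$y, a$z, a$sybyl_type, 1L, "LIG", 0),
    "@<TRIPOS>BOND")
  if (nrow(bonds))
    lines <- c(lines, sprintf("%6d %5d %5d %4s", seq_len(nrow(bonds)),
                              bonds$origin, bonds$target, bonds$order))
  writeLines(lines, path)
}

#' Write a ligand back to Mol2
#'
#' Round-trips atom order, SYBYL types and coordinates (4 decimals).
#'
#' @param ligand a `kgs_ligand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ligand_mol2 <- function(ligand, path) {
  a <- ligand$atoms
  b <- ligand$bonds
  lines <- c(
    "@<TRIPOS>MOLECULE",
    if (is.null(ligand$name) || is.na(ligand$name)) "LIG" else ligand$name,
    sprintf("%d %d 1", nrow(a), nrow(b)),
    "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %4d %-8s %10.4f",
            a$serial, a$name, a$x, a$y, a$z, a$sybyl_type, 1L, "LIG", 0))
  lines <- c(lines, "@<TRIPOS>BOND")
  if (nrow(b))
    lines <- c(lines, sprintf("%6d %5d %5d %4s", seq_len(nrow(b)),
                              b$origin, b$target, b$order))
  writeLines(lines, path)
  invisible(path)
}

#' Default planted pattern vocabulary
#'
#' Four (residue template, ligand SYBYL type) combinations; each complex
#' built by [make_library()] carries one planted unit per vocabulary entry.
#'
#' @return data.frame with columns residue, lig_type.
#' @export
fixture_vocab <- function() {
  data.frame(residue = c("GLY", "ALA", "GLY", "ALA"),
             lig_type = c("O.2", "N.3", "C.3", "O.3"),
             stringsAsFactors = FALSE)
}

#' Build a synthetic reference library of twinned complexes
#'
#' Generates `n_pairs` twin pairs. Twins share the residue layout (so
#' their fingerprints are nearly identical up to positional jitter and a
#' random global rigid motion); distinct pairs get independent random
#' layouts, so cross-pair similarity is low. Each twin's planted nearest
#' neighbour is therefore its partner.
#'
#' Affinities are uniform in `affinity_range`; the second twin's affinity
#' equals the first's plus `N(0, sigma_ref)` (the reference-affinity
#' error). Raw scores follow the linear model
#' `raw = (affinity - b)/k + (e_pair + e_ind)/k`, where `e_pair ~ N(0,
#' sigma_sf)` is a scoring-function error shared within a twin pair (the
#' systematic error that anchored scoring cancels) and `e_ind ~ N(0,
#' sigma_ind)` is independent noise.
#'
#' @param n_pairs number of twin pairs.
#' @param vocab data.frame(residue, lig_type) of planted combinations.
#' @param seed RNG seed; byte-identical output per seed.
#' @param affinity_range logKa range for true affinities.
#' @param k,b linear score model (logKa per score unit; intercept).
#' @param sigma_sf pair-shared scoring-function error (logKa).
#' @param sigma_ind independent scoring noise (logKa).
#' @param sigma_ref reference-affinity error between twins (logKa).
#' @param jitter_sd planted-atom positional jitter (A).
#' @param dir if non-`NULL`, write per-complex files plus `INDEX.tsv` and
#'   `scores.tsv` under it.
#' @return list with `complexes` (named list of `kgs_complex`), `index`
#'   (data.frame), `scores` (data.frame complex_id, raw_score,
#'   experimental), `truth` (twin map, true affinities, model parameters),
#'   `manifests` (named list).
#' @export
make_library <- function(n_pairs = 12L, vocab = fixture_vocab(), seed = 1L,
                         affinity_range = c(2, 11), k = 0.5, b = 1.0,
                         sigma_sf = 1.0, sigma_ind = 0, sigma_ref = 0.25,
                         jitter_sd = 0.1, dir = NULL) {
  set.seed(seed)
  n_res <- nrow(vocab)
  complexes <- list(); manifests <- list()
  idx_rows <- list(); score_rows <- list()
  twin <- character(0); true_aff <- numeric(0)
  for (p in seq_len(n_pairs)) {
    layout <- make_layout(n_res)
    aff_a <- runif(1L, affinity_range[1L], affinity_range[2L])
    aff_b <- aff_a + rnorm(1L, 0, sigma_ref)
    e_pair <- rnorm(1L, 0, sigma_sf)
    ids <- sprintf("CPX%03d", c(2L * p - 1L, 2L * p))
    affs <- c(aff_a, aff_b)
    for (t in 1:2) {
      tr <- if (t == 2L) random_transform(30) else NULL
      mc <- make_complex(ids[t], vocab$residue, vocab$lig_type, layout = layout,
                         jitter_sd = jitter_sd, affinity = affs[t],
                         transform = tr, dir = dir)
      complexes[[ids[t]]] <- mc$complex
      manifests[[ids[t]]] <- mc$manifest
      raw <- (affs[t] - b) / k + (e_pair + rnorm(1L, 0, sigma_ind)) / k
      score_rows[[ids[t]]] <- data.frame(complex_id = ids[t], raw_score = raw,
                                         experimental = affs[t],
                                         stringsAsFactors = FALSE)
      idx_rows[[ids[t]]] <- data.frame(
        complex_id = ids[t],
        protein_path = if (is.null(dir)) NA_character_ else
          file.path(ids[t], paste0(ids[t], "_protein.pdb")),
        ligand_path = if (is.null(dir)) NA_character_ else
          file.path(ids[t], paste0(ids[t], "_ligand.mol2")),
        affinity_logKa = affs[t], stringsAsFactors = FALSE)
    }
    twin[ids[1L]] <- ids[2L]
    twin[ids[2L]] <- ids[1L]
    true_aff[ids] <- affs
  }
  index <- do.call(rbind, idx_rows)
  scores <- do.call(rbind, score_rows)
  rownames(index) <- rownames(scores) <- NULL
  if (!is.null(dir)) {
    write.table(index, file.path(dir, "INDEX.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(scores, file.path(dir, "scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(complexes = complexes, index = index, scores = scores,
       truth = list(twin = twin, true_affinity = true_aff, k = k, b = b,
                    sigma_sf = sigma_sf, sigma_ind = sigma_ind,
                    sigma_ref = sigma_ref, seed = seed),
       manifests = manifests)
}

#' Inflate unit occurrences by jittered replication
#'
#' Pattern-significance thresholds are calibrated for large structure
#' libraries (occurrence > 100); small fixture libraries reach them by
#' replicating their unit clouds with fresh positional jitter. Uses the
#' current RNG stream.
#'
#' @param units data.frame from [aggregate_units()].
#' @param times replication factor (total = times x original).
#' @param jitter_sd isotropic jitter added to replicated local coordinates
#'   (A).
#' @return Inflated units data.frame.
#' @export
replicate_units <- function(units, times = 5L, jitter_sd = 0.2) {
  parts <- vector("list", times)
  parts[[1L]] <- units
  for (t in seq_len(times - 1L)) {
    u <- units
    n <- nrow(u)
    u$lx <- u$lx + rnorm(n, 0, jitter_sd)
    u$ly <- u$ly + rnorm(n, 0, jitter_sd)
    u$lz <- u$lz + rnorm(n, 0, jitter_sd)
    parts[[t + 1L]] <- u
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate anchored vs linear-fallback scoring error
#'
#' Generative model of the anchoring premise: query and reference are
#' similar complexes, so the scoring function makes the same systematic
#' error `e_sf ~ N(0, sigma_sf)` on both and it cancels in the anchored
#' score; what remains is the reference's experimental-affinity error
#' `e_ref ~ N(0, sigma_ref)`. The linear fallback keeps the full `e_sf`.
#'
#' @param n number of simulated queries.
#' @param k,b linear score model.
#' @param sigma_sf scoring-function error SD (logKa).
#' @param sigma_ref reference experimental-affinity error SD (logKa).
#' @param seed RNG seed.
#' @return data.frame: true_aff, q_raw, r_raw, r_exp, eq1_pred, kgs2_pred.
#' @export
simulate_anchoring <- function(n = 200L, k = 0.5, b = 1.0, sigma_sf = 1.0,
                               sigma_ref = 0.3, seed = 0L) {
  set.seed(seed)
  true_aff <- runif(n, 2, 11)
  e_sf <- rnorm(n, 0, sigma_sf)
  ref_true <- true_aff + rnorm(n, 0, 0.5)   # reference resembles the query
  e_ref <- rnorm(n, 0, sigma_ref)
  q_raw <- (true_aff - b) / k + e_sf / k
  r_raw <- (ref_true - b) / k + e_sf / k    # shared systematic error
  r_exp <- ref_true + e_ref
  data.frame(true_aff = true_aff, q_raw = q_raw, r_raw = r_raw, r_exp = r_exp,
             eq1_pred = b + k * q_raw,
             kgs2_pred = adjust_score(q_raw, r_raw, r_exp, k))
}
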
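# Reading and normalising protein (PDB) and ligand (Mol2/SDF) structures,
# van der Waals radii, pocket definition, and library index handling.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# Bondi (1964) van der Waals radii, A.
BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90, SI = 2.10, B = 1.92, AS = 1.85, TE = 2.06
)
DEFAULT_VDW <- 1.70

# Covalent radii (A) used for distance-based bond perception.
COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
  S = 1.05, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20, B = 0.84
)
BOND_TOLERANCE <- 0.45

element_from_name <- function(name) {
  # Strip digits/primes; for PDB names like "1HB" the element is H.
  x <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(x, 1L, 2L)
  ifelse(two %in% names(BONDI_RADII) & !(substr(x, 1L, 1L) %in% c("C", "N", "O", "H", "S", "P")),
         two, substr(x, 1L, 1L))
}

residue_key <- function(chain, resno, insert) {
  chain <- ifelse(is.na(chain) | chain == "", "_", chain)
  insert <- ifelse(is.na(insert) | insert == "", "", insert)
  paste(chain, resno, insert, sep = ":")
}

#' Read a protein structure from a PDB file
#'
#' Parses `ATOM` records (via bio3d), resolves alternate locations by
#' keeping the highest-occupancy conformer (ties: first encountered),
#' flags hydrogens and nonstandard residues, and perceives covalent bonds
#' by the covalent-radii-plus-tolerance rule within residues plus peptide
#' C-N links between consecutive residues.
#'
#' @param path path to a PDB file.
#' @return An object of class `kgs_protein`: a list with `atoms`
#'   (data.frame: serial, name, element, resname, chain, resno, insert,
#'   res_key, x, y, z, is_hydrogen, standard_aa) and `bonds` (two-column
#'   matrix of atom serials).
#' @export
read_protein_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no protein (ATOM) records in '", path, "'")

  # altLoc: keep highest occupancy per (residue, atom name); tie -> first.
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]

  element <- toupper(at$elesy)
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- element_from_name(at$elety[missing_el])

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = element,
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "_", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    is_hydrogen = element %in% c("H", "D"),
    standard_aa = at$resid %in% STANDARD_AA,
    stringsAsFactors = FALSE
  )
  atoms$res_key <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in '", path, "'")

  prot <- structure(list(atoms = atoms, bonds = NULL, source = path),
                    class = "kgs_protein")
  prot$bonds <- perceive_protein_bonds(atoms)
  prot
}

# Distance-based bond perception: intra-residue pairs within the sum of
# covalent radii + tolerance, plus peptide C(i)-N(i+1) links.
perceive_protein_bonds <- function(atoms) {
  heavy <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  out <- vector("list", length(unique(heavy$res_key)) + 1L)
  i <- 1L
  for (rk in unique(heavy$res_key)) {
    res <- heavy[heavy$res_key == rk, , drop = FALSE]
    n <- nrow(res)
    if (n < 2L) next
    xyz <- as.matrix(res[, c("x", "y", "z")])
    dmat <- as.matrix(dist(xyz))
    rad <- COVALENT_RADII[res$element]
    rad[is.na(rad)] <- 0.76
    lim <- outer(rad, rad, "+") + BOND_TOLERANCE
    idx <- which(dmat < lim & upper.tri(dmat), arr.ind = TRUE)
    if (nrow(idx))
      out[[i]] <- cbind(res$serial[idx[, 1L]], res$serial[idx[, 2L]])
    i <- i + 1L
  }
  # Peptide links between consecutive residues of the same chain.
  cn <- heavy[heavy$name %in% c("C", "N"), , drop = FALSE]
  pep <- NULL
  if (nrow(cn) > 1L) {
    cc <- cn[cn$name == "C", , drop = FALSE]
    nn <- cn[cn$name == "N", , drop = FALSE]
    for (j in seq_len(nrow(cc))) {
      cand <- nn[nn$chain == cc$chain[j] & nn$resno == cc$resno[j] + 1L, , drop = FALSE]
      if (nrow(cand)) {
        d <- sqrt((cand$x - cc$x[j])^2 + (cand$y - cc$y[j])^2 + (cand$z - cc$z[j])^2)
        keep <- which(d < 1.8)
        if (length(keep))
          pep <- rbind(pep, cbind(cc$serial[j], cand$serial[keep[1L]]))
      }
    }
  }
  bonds <- do.call(rbind, c(out[!vapply(out, is.null, logical(1L))], list(pep)))
  if (is.null(bonds)) bonds <- matrix(integer(0), 0L, 2L)
  bonds
}

#' Read a ligand structure from a Mol2 or SDF file
#'
#' Mol2 files carry SYBYL atom types verbatim. For SDF (V2000) input the
#' SYBYL type is perceived from element plus bond orders: aromatic (order
#' 4) carbon/nitrogen become `C.ar`/`N.ar`, triple bonds give `.1`, double
#' bonds `.2`, otherwise `.3` for C/N/O/S; P becomes `P.3`; halogens and
#' hydrogens keep their element symbol. Atoms whose type cannot be
#' determined are recorded as `"Any"` with a warning.
#'
#' @param path path to the ligand file.
#' @param format `"auto"` (by extension), `"mol2"`, or `"sdf"`.
#' @return An object of class `kgs_ligand`: list with `atoms` (data.frame:
#'   serial, name, element, sybyl_type, x, y, z, is_hydrogen) and `bonds`
#'   (data.frame: origin, target, order).
#' @export
read_ligand <- function(path, format = c("auto", "mol2", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("ligand file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mol2 = "mol2", sdf = "sdf", sd = "sdf",
                     stop("cannot infer ligand format from extension '", ext, "'"))
  }
  if (format == "mol2") read_ligand_mol2(path) else read_ligand_sdf(path)
}

read_ligand_mol2 <- function(path) {
  mol <- tryCatch(bio3d::read.mol2(path),
                  error = function(e) stop("failed to parse Mol2 '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (is.list(mol) && is.null(mol$atom) && length(mol) >= 1L && inherits(mol[[1L]], "mol2"))
    mol <- mol[[1L]]
  at <- mol$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in Mol2 file '", path, "'")
  sybyl <- as.character(at$elety)
  bad <- is.na(sybyl) | sybyl == "" | toupper(sybyl) %in% c("DU", "ANY")
  if (any(bad)) {
    warning(sum(bad), " ligand atom(s) with unknown SYBYL type recorded as 'Any'")
    sybyl[bad] <- "Any"
  }
  element <- toupper(sub("\\..*$", "", sybyl))
  element[sybyl == "Any"] <- element_from_name(at$elena[sybyl == "Any"])
  atoms <- data.frame(
    serial = at$eleno, name = at$elena, element = element,
    sybyl_type = sybyl, x = at$x, y = at$y, z = at$z,
    is_hydrogen = element %in% c("H", "D"), stringsAsFactors = FALSE
  )
  if (sum(!atoms$is_hydrogen) < 1L) stop("ligand has no heavy atoms")
  bonds <- if (!is.null(mol$bond) && nrow(mol$bond))
    data.frame(origin = mol$bond$origin, target = mol$bond$target,
               order = as.character(mol$bond$type), stringsAsFactors = FALSE)
  else data.frame(origin = integer(0), target = integer(0), order = character(0))
  structure(list(atoms = atoms, bonds = bonds, name = mol$name, source = path),
            class = "kgs_ligand")
}

# Documented SYBYL-type perception table for SDF input (element x max
# incident bond order; 4 denotes aromatic in V2000).
perceive_sybyl <- function(element, max_order) {
  el <- toupper(element)
  if (el == "C") return(switch(as.character(max_order), "4" = "C.ar", "3" = "C.1", "2" = "C.2", "C.3"))
  if (el == "N") return(switch(as.character(max_order), "4" = "N.ar", "3" = "N.1", "2" = "N.2", "N.3"))
  if (el == "O") return(if (max_order >= 2) "O.2" else "O.3")
  if (el == "S") return(if (max_order >= 2) "S.2" else "S.3")
  if (el == "P") return("P.3")
  if (el %in% c("H", "F", "CL", "BR", "I")) {
    return(switch(el, H = "H", F = "F", CL = "Cl", BR = "Br", I = "I"))
  }
  NA_character_
}

read_ligand_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) stop("failed to parse SDF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(sdf) == 0L) stop("no molecules in SDF file '", path, "'")
  ab <- ChemmineR::atomblock(sdf[[1L]])
  if (nrow(ab) == 0L) stop("zero-atom molecule in '", path, "'")
  bb <- ChemmineR::bondblock(sdf[[1L]])
  element <- toupper(sub("_.*$", "", rownames(ab)))
  n <- nrow(ab)
  max_order <- integer(n)
  if (!is.null(bb) && nrow(bb)) {
    for (i in seq_len(nrow(bb))) {
      a <- bb[i, 1L]; b <- bb[i, 2L]; o <- bb[i, 3L]
      max_order[a] <- max(max_order[a], o)
      max_order[b] <- max(max_order[b], o)
    }
  }
  sybyl <- vapply(seq_len(n), function(i) perceive_sybyl(element[i], max_order[i]),
                  character(1L))
  if (anyNA(sybyl)) {
    warning(sum(is.na(sybyl)), " ligand atom(s) with unknown SYBYL type recorded as 'Any'")
    sybyl[is.na(sybyl)] <- "Any"
  }
  atoms <- data.frame(
    serial = seq_len(n),
    name = paste0(element, seq_len(n)),
    element = element, sybyl_type = sybyl,
    x = ab[, 1L], y = ab[, 2L], z = ab[, 3L],
    is_hydrogen = element %in% c("H", "D"), stringsAsFactors = FALSE
  )
  if (sum(!atoms$is_hydrogen) < 1L) stop("ligand has no heavy atoms")
  bonds <- if (!is.null(bb) && nrow(bb))
    data.frame(origin = as.integer(bb[, 1L]), target = as.integer(bb[, 2L]),
               order = as.character(bb[, 3L]), stringsAsFactors = FALSE)
  else data.frame(origin = integer(0), target = integer(0), order = character(0))
  structure(list(atoms = atoms, bonds = bonds, name = NA_character_, source = path),
            class = "kgs_ligand")
}

#' Assign Bondi van der Waals radii
#'
#' Adds a `vdw` column (A) to the atom table of a protein or ligand.
#' Unknown elements receive the 1.70 A default with a warning.
#'
#' @param x a `kgs_protein` or `kgs_ligand`.
#' @return `x` with `atoms$vdw` filled in.
#' @export
assign_vdw_radii <- function(x) {
  stopifnot(inherits(x, "kgs_protein") || inherits(x, "kgs_ligand"))
  el <- toupper(x$atoms$element)
  vdw <- unname(BONDI_RADII[el])
  unknown <- is.na(vdw)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            ": using default vdW radius ", DEFAULT_VDW, " A")
    vdw[unknown] <- DEFAULT_VDW
  }
  x$atoms$vdw <- vdw
  x
}

#' Assemble a protein-ligand complex record
#'
#' @param complex_id identifier (e.g. PDB code); unique within a library.
#' @param protein a `kgs_protein`.
#' @param ligand a `kgs_ligand`.
#' @param affinity experimental binding constant in logKa units
#'   (-logKd/-logKi/-logIC50), or `NA` for query complexes.
#' @return Object of class `kgs_complex`.
#' @export
kgs_complex <- function(complex_id, protein, ligand, affinity = NA_real_) {
  stopifnot(inherits(protein, "kgs_protein"), inherits(ligand, "kgs_ligand"))
  if (is.null(protein$atoms$vdw)) protein <- assign_vdw_radii(protein)
  if (is.null(ligand$atoms$vdw)) ligand <- assign_vdw_radii(ligand)
  structure(list(complex_id = as.character(complex_id), protein = protein,
                 ligand = ligand, affinity = as.numeric(affinity)),
            class = "kgs_complex")
}

#' @export
print.kgs_complex <- function(x, ...) {
  cat("<kgs_complex>", x$complex_id, "\n",
      " protein:", nrow(x$protein$atoms), "atoms,",
      length(unique(x$protein$atoms$res_key)), "residues\n",
      " ligand: ", sum(!x$ligand$atoms$is_hydrogen), "heavy atoms\n",
      " affinity:", if (is.na(x$affinity)) "unknown" else sprintf("%.2f logKa", x$affinity), "\n")
  invisible(x)
}

#' Define the ligand binding pocket
#'
#' A residue belongs to the pocket iff any of its heavy atoms lies within
#' `cutoff` A (centre-to-centre, inclusive) of any ligand heavy atom.
#'
#' @param complex a `kgs_complex`.
#' @param cutoff pocket radius in A (default 4.5).
#' @return Character vector of residue keys (`chain:resno:insert`).
#' @export
define_pocket <- function(complex, cutoff = 4.5) {
  stopifnot(inherits(complex, "kgs_complex"))
  pa <- complex$protein$atoms
  pa <- pa[!pa$is_hydrogen, , drop = FALSE]
  la <- complex$ligand$atoms
  la <- la[!la$is_hydrogen, , drop = FALSE]
  if (nrow(pa) == 0L || nrow(la) == 0L) {
    warning("empty pocket: no heavy atoms to compare")
    return(character(0))
  }
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  d2min <- apply(pxyz, 1L, function(p) min(colSums((t(lxyz) - p)^2)))
  keep <- unique(pa$res_key[d2min <= cutoff^2])
  if (length(keep) == 0L) warning("empty pocket: no residue within ", cutoff, " A")
  keep
}

#' C-alpha coordinates per residue
#'
#' @param protein a `kgs_protein`.
#' @return data.frame with res_key, resname, x, y, z; residues without a
#'   C-alpha atom are omitted.
#' @export
residue_calpha <- function(protein) {
  a <- protein$atoms
  ca <- a[a$name == "CA" & !a$is_hydrogen, , drop = FALSE]
  ca <- ca[!duplicated(ca$res_key), , drop = FALSE]
  data.frame(res_key = ca$res_key, resname = ca$resname,
             x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
}

#' Apply a rigid transform to a whole complex
#'
#' Used mainly to test rigid-motion invariance of the pipeline.
#'
#' @param complex a `kgs_complex`.
#' @param transform a [kgs_transform()].
#' @return The transformed `kgs_complex`.
#' @export
transform_complex <- function(complex, transform) {
  for (part in c("protein", "ligand")) {
    xyz <- as.matrix(complex[[part]]$atoms[, c("x", "y", "z")])
    xyz <- apply_transform(xyz, transform)
    complex[[part]]$atoms$x <- xyz[, 1L]
    complex[[part]]$atoms$y <- xyz[, 2L]
    complex[[part]]$atoms$z <- xyz[, 3L]
  }
  complex
}

#' Read a reference-library index file
#'
#' Tab-separated with header columns `complex_id`, `protein_path`,
#' `ligand_path`, `affinity_logKa`; paths are resolved relative to the
#' index file's directory (mirroring the PDBbind INDEX layout).
#'
#' @param path path to the index TSV.
#' @return data.frame with absolute paths.
#' @export
read_library_index <- function(path) {
  idx <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("complex_id", "protein_path", "ligand_path", "affinity_logKa")
  if (!all(need %in% names(idx)))
    stop("library index must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(idx$complex_id))
    stop("duplicate complex_id in library index")
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", idx$protein_path)
  idx$protein_path[rel] <- file.path(base, idx$protein_path[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", idx$ligand_path)
  idx$ligand_path[rel] <- file.path(base, idx$ligand_path[rel])
  idx
}

#' Load one complex from a library-index row
#'
#' @param index_row single row of [read_library_index()] output.
#' @return A `kgs_complex`.
#' @export
load_complex <- function(index_row) {
  kgs_complex(index_row$complex_id,
              read_protein_pdb(index_row$protein_path),
              read_ligand(index_row$ligand_path),
              affinity = index_row$affinity_logKa)
}

#' Load every complex in a library index
#'
#' Unreadable complexes are skipped with a warning rather than aborting.
#'
#' @param index data.frame from [read_library_index()].
#' @return Named list of `kgs_complex` objects.
#' @export
load_library <- function(index) {
  out <- list()
  for (i in seq_len(nrow(index))) {
    cx <- tryCatch(load_complex(index[i, , drop = FALSE]), error = function(e) {
      warning("skipping complex '", index$complex_id[i], "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(cx)) out[[cx$complex_id]] <- cx
  }
  out
}
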
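# Enumeration of four-atom protein-ligand interaction units: three
# covalently bonded heavy atoms on one protein residue (the "fragment")
# plus one ligand heavy atom in vdW contact, with the ligand atom's
# position expressed in the fragment's local coordinate frame.

#' Find protein-ligand van der Waals contacts
#'
#' A heavy-atom pair (p, l) is a contact iff its centre-to-centre distance
#' is strictly below the sum of the two Bondi radii plus `margin`.
#'
#' @param protein a `kgs_protein` with vdW radii assigned.
#' @param ligand a `kgs_ligand` with vdW radii assigned.
#' @param margin contact margin in A (default 1.0).
#' @return data.frame: protein_serial, ligand_serial, dist.
#' @export
find_contacts <- function(protein, ligand, margin = 1.0) {
  pa <- protein$atoms[!protein$atoms$is_hydrogen, , drop = FALSE]
  la <- ligand$atoms[!ligand$atoms$is_hydrogen, , drop = FALSE]
  if (nrow(pa) == 0L || nrow(la) == 0L)
    return(data.frame(protein_serial = integer(0), ligand_serial = integer(0),
                      dist = numeric(0)))
  if (is.null(pa$vdw) || is.null(la$vdw))
    stop("vdW radii not assigned; call assign_vdw_radii() first")
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  d2 <- outer(rowSums(pxyz^2), rowSums(lxyz^2), "+") - 2 * pxyz %*% t(lxyz)
  d2[d2 < 0] <- 0
  lim <- outer(pa$vdw, la$vdw, "+") + margin
  hit <- which(d2 < lim^2, arr.ind = TRUE)
  data.frame(protein_serial = pa$serial[hit[, 1L]],
             ligand_serial = la$serial[hit[, 2L]],
             dist = sqrt(d2[hit]))
}

# Canonical orientation of a 3-path: middle atom fixed; ends ordered so
# the first end's atom name is lexicographically <= the last's; identical
# names -> order by serial.
canonical_triple <- function(s, n) {
  swap <- (n[3L] < n[1L]) || (n[3L] == n[1L] && s[3L] < s[1L])
  if (swap) list(s = s[c(3L, 2L, 1L)], n = n[c(3L, 2L, 1L)])
  else list(s = s, n = n)
}

#' Enumerate intra-residue three-atom fragments containing an anchor atom
#'
#' All simple covalent paths a-b-c of three distinct heavy atoms within
#' one residue that contain `anchor_serial` at any position, in canonical
#' orientation, deduplicated.
#'
#' @param residue_atoms data.frame of one residue's heavy atoms (needs
#'   serial and name columns).
#' @param bonds two-column matrix of bonded serial pairs.
#' @param anchor_serial serial of the contacting protein atom.
#' @return data.frame: s1, s2, s3 (serials), n1, n2, n3 (names); zero rows
#'   if the residue has fewer than 3 bonded heavy atoms.
#' @export
enumerate_fragments <- function(residue_atoms, bonds, anchor_serial) {
  ser <- residue_atoms$serial
  nm <- setNames(residue_atoms$name, as.character(ser))
  b <- bonds[bonds[, 1L] %in% ser & bonds[, 2L] %in% ser, , drop = FALSE]
  empty <- data.frame(s1 = integer(0), s2 = integer(0), s3 = integer(0),
                      n1 = character(0), n2 = character(0), n3 = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(b) == 0L) return(empty)
  adj <- split(c(b[, 2L], b[, 1L]), as.character(c(b[, 1L], b[, 2L])))
  rows <- list(); ri <- 1L
  for (m in ser) {
    nb <- adj[[as.character(m)]]
    if (is.null(nb) || length(nb) < 2L) next
    nb <- sort(unique(nb))
    for (i in seq_len(length(nb) - 1L)) {
      for (j in (i + 1L):length(nb)) {
        u <- nb[i]; w <- nb[j]
        if (!(anchor_serial %in% c(u, m, w))) next
        ct <- canonical_triple(c(u, m, w),
                               c(nm[[as.character(u)]], nm[[as.character(m)]], nm[[as.character(w)]]))
        rows[[ri]] <- data.frame(s1 = ct$s[1L], s2 = ct$s[2L], s3 = ct$s[3L],
                                 n1 = ct$n[1L], n2 = ct$n[2L], n3 = ct$n[3L],
                                 stringsAsFactors = FALSE)
        ri <- ri + 1L
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("s1", "s2", "s3")]), , drop = FALSE]
}

#' Local coordinate frame of a protein fragment
#'
#' Origin at the middle atom b; x axis along a - b; the xy plane contains
#' all three fragment atoms; the z axis points toward the ligand atom's
#' side (an exactly in-plane ligand atom keeps the default + convention).
#'
#' @param a,b,c coordinates (length-3) of the fragment atoms in canonical
#'   order.
#' @param ligand_xyz coordinates of the ligand atom.
#' @param min_angle_deg fragments with an internal angle at b below this
#'   are rejected as collinear (default 1 degree).
#' @return list with `R` (3x3, rows = x/y/z axes), `origin`, and `local`
#'   (ligand atom in the fragment frame), or `NULL` if collinear.
#' @export
local_frame <- function(a, b, c, ligand_xyz, min_angle_deg = 1) {
  v1 <- a - b
  v2 <- c - b
  n1 <- vnorm(v1); n2 <- vnorm(v2)
  if (n1 == 0 || n2 == 0) return(NULL)
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (ang < min_angle_deg || ang > 180 - min_angle_deg) return(NULL)
  x <- v1 / n1
  z <- cross3(x, v2 / n2)
  z <- z / vnorm(z)
  if (sum(z * (ligand_xyz - b)) < 0) z <- -z
  y <- cross3(z, x)
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  list(R = R, origin = b, local = drop(R %*% (ligand_xyz - b)))
}

unit_type_key <- function(resname, n1, n2, n3, lig_type) {
  paste0(resname, ":", n1, "-", n2, "-", n3, "|", lig_type)
}

#' Parse a unit type key back into its components
#' @param key string such as `"ASP:CA-C-O|O.2"`.
#' @return list(resname, fragment_atom_names, ligand_atom_type).
#' @export
parse_type_key <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):([^|]+)\\|(.+)$", key))[[1L]]
  if (length(m) != 4L) stop("malformed unit type key: ", key)
  list(resname = m[2L], fragment_atom_names = strsplit(m[3L], "-", fixed = TRUE)[[1L]],
       ligand_atom_type = m[4L])
}

#' Extract all interaction units of a complex
#'
#' For every contact pair (p, l), every intra-residue fragment triple that
#' contains p is paired with l; duplicates arising from multiple contacts
#' within the same fragment collapse. Nonstandard residues are excluded.
#' Collinear fragments are skipped (counted in the `skipped_collinear`
#' attribute).
#'
#' @param complex a `kgs_complex`.
#' @param pocket_only if `TRUE`, restrict to residues within
#'   `pocket_cutoff` of the ligand (fingerprint construction); if `FALSE`,
#'   use the whole interface (library mining).
#' @param margin contact margin in A.
#' @param pocket_cutoff pocket radius in A.
#' @return data.frame of units: complex_id, type_key, resname, res_key,
#'   frag names/serials, lig_serial, lig_type, lx, ly, lz (local
#'   coordinates, A).
#' @export
extract_units <- function(complex, pocket_only = TRUE, margin = 1.0,
                          pocket_cutoff = 4.5) {
  stopifnot(inherits(complex, "kgs_complex"))
  prot <- complex$protein
  pa <- prot$atoms[!prot$atoms$is_hydrogen & prot$atoms$standard_aa, , drop = FALSE]
  if (pocket_only) {
    pocket <- suppressWarnings(define_pocket(complex, cutoff = pocket_cutoff))
    pa <- pa[pa$res_key %in% pocket, , drop = FALSE]
  }
  empty <- data.frame(complex_id = character(0), type_key = character(0),
                      resname = character(0), res_key = character(0),
                      n1 = character(0), n2 = character(0), n3 = character(0),
                      s1 = integer(0), s2 = integer(0), s3 = integer(0),
                      lig_serial = integer(0), lig_type = character(0),
                      lx = numeric(0), ly = numeric(0), lz = numeric(0),
                      stringsAsFactors = FALSE)
  attr(empty, "skipped_collinear") <- 0L
  if (nrow(pa) == 0L) return(empty)

  sub <- prot; sub$atoms <- pa
  contacts <- find_contacts(sub, complex$ligand, margin = margin)
  if (nrow(contacts) == 0L) return(empty)

  la <- complex$ligand$atoms
  lig_xyz <- as.matrix(la[, c("x", "y", "z")])
  rownames(lig_xyz) <- as.character(la$serial)
  lig_type <- setNames(la$sybyl_type, as.character(la$serial))
  atom_by_serial <- pa
  rownames(atom_by_serial) <- as.character(pa$serial)

  rows <- list(); ri <- 1L; skipped <- 0L
  seen <- character(0)
  for (ci in seq_len(nrow(contacts))) {
    p <- contacts$protein_serial[ci]
    l <- contacts$ligand_serial[ci]
    rk <- atom_by_serial[as.character(p), "res_key"]
    res_atoms <- pa[pa$res_key == rk, , drop = FALSE]
    frags <- enumerate_fragments(res_atoms, prot$bonds, p)
    if (nrow(frags) == 0L) next
    for (fi in seq_len(nrow(frags))) {
      keyid <- paste(frags$s1[fi], frags$s2[fi], frags$s3[fi], l, sep = "_")
      if (keyid %in% seen) next
      seen <- c(seen, keyid)
      a <- unlist(atom_by_serial[as.character(frags$s1[fi]), c("x", "y", "z")])
      b <- unlist(atom_by_serial[as.character(frags$s2[fi]), c("x", "y", "z")])
      cc <- unlist(atom_by_serial[as.character(frags$s3[fi]), c("x", "y", "z")])
      fr <- local_frame(a, b, cc, lig_xyz[as.character(l), ])
      if (is.null(fr)) { skipped <- skipped + 1L; next }
      rn <- atom_by_serial[as.character(p), "resname"]
      rows[[ri]] <- data.frame(
        complex_id = complex$complex_id,
        type_key = unit_type_key(rn, frags$n1[fi], frags$n2[fi], frags$n3[fi],
                                 lig_type[[as.character(l)]]),
        resname = rn, res_key = rk,
        n1 = frags$n1[fi], n2 = frags$n2[fi], n3 = frags$n3[fi],
        s1 = frags$s1[fi], s2 = frags$s2[fi], s3 = frags$s3[fi],
        lig_serial = l, lig_type = lig_type[[as.character(l)]],
        lx = fr$local[1L], ly = fr$local[2L], lz = fr$local[3L],
        stringsAsFactors = FALSE)
      ri <- ri + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "skipped_collinear") <- skipped
  out
}
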
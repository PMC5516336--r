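test_that("contact detection matches the brute-force all-pairs scan", {
  set.seed(21)
  mc <- make_complex("CNT", c("GLY", "ALA", "ASP", "GLY"),
                     c("O.2", "N.3", "C.3", "O.3"))
  cx <- mc$complex
  got <- find_contacts(cx$protein, cx$ligand)
  got_keys <- sort(paste(got$protein_serial, got$ligand_serial, sep = "-"))
  expect_equal(got_keys, bf_contacts(cx$protein, cx$ligand))
  expect_gte(nrow(got), 4L) # at least the planted anchors

  # strict inequality at the contact limit: C (1.70) vs O (1.52), limit 4.22
  pa <- cx$protein$atoms
  la <- cx$ligand$atoms
  # widen the margin: contact set can only grow
  got2 <- find_contacts(cx$protein, cx$ligand, margin = 2.0)
  expect_true(all(got_keys %in%
                    paste(got2$protein_serial, got2$ligand_serial, sep = "-")))
  # shrink to zero margin on a fixture whose planted distance sits 0.55
  # inside the +1 A margin: anchors must drop out at margin 0.3
  got3 <- find_contacts(cx$protein, cx$ligand, margin = 0.3)
  expect_lt(nrow(got3), nrow(got))
})

test_that("fragment enumeration equals the brute-force 3-path enumerator", {
  set.seed(22)
  mc <- make_complex("FRG", c("GLY", "ALA", "ASP"), c("O.2", "O.2", "O.2"))
  prot <- mc$complex$protein
  for (rk in unique(prot$atoms$res_key)) {
    res <- prot$atoms[prot$atoms$res_key == rk & !prot$atoms$is_hydrogen, ]
    for (anchor in res$serial) {
      got <- enumerate_fragments(res, prot$bonds, anchor)
      got_keys <- sort(paste(got$s1, got$s2, got$s3, sep = "-"))
      expect_equal(got_keys, bf_3paths(res, prot$bonds, anchor),
                   info = paste(rk, anchor))
    }
  }
  # carbonyl O lies on exactly one 3-path (CA-C-O) in every template
  res1 <- prot$atoms[prot$atoms$res_key == "A:1:", ]
  o_serial <- res1$serial[res1$name == "O"]
  frag <- enumerate_fragments(res1, prot$bonds, o_serial)
  expect_equal(nrow(frag), 1L)
  expect_equal(c(frag$n1, frag$n2, frag$n3), c("CA", "C", "O"))
})

test_that("fragment enumeration degenerate cases", {
  atoms <- data.frame(serial = 1:3, name = c("A1", "A2", "A3"),
                      stringsAsFactors = FALSE)
  chain <- rbind(c(1L, 2L), c(2L, 3L))
  # linear 3-atom chain, anchor at the middle -> exactly one triple
  got <- enumerate_fragments(atoms, chain, 2L)
  expect_equal(nrow(got), 1L)
  # anchor with no bonds -> empty
  expect_equal(nrow(enumerate_fragments(atoms, matrix(integer(0), 0L, 2L), 1L)), 0L)
  # canonical orientation: ends ordered by name, ties by serial
  atoms2 <- data.frame(serial = c(5L, 6L, 7L), name = c("O", "C", "CA"),
                       stringsAsFactors = FALSE)
  got2 <- enumerate_fragments(atoms2, rbind(c(5L, 6L), c(6L, 7L)), 6L)
  expect_equal(c(got2$n1, got2$n2, got2$n3), c("CA", "C", "O"))
  atoms3 <- data.frame(serial = c(9L, 2L, 4L), name = c("X", "C", "X"),
                       stringsAsFactors = FALSE)
  got3 <- enumerate_fragments(atoms3, rbind(c(9L, 2L), c(2L, 4L)), 2L)
  expect_equal(got3$s1, 4L) # equal names -> smaller serial first
})

test_that("local frame follows the stated axis construction", {
  a <- c(1, 0, 0); b <- c(0, 0, 0); cc <- c(0, 1, 0)
  fr <- local_frame(a, b, cc, c(0, 0, 1))
  expect_equal(fr$local, c(0, 0, 1), tolerance = 1e-12)
  # mirror-side ligand: z axis flips so local coordinates are identical
  fr2 <- local_frame(a, b, cc, c(0, 0, -1))
  expect_equal(fr2$local, c(0, 0, 1), tolerance = 1e-12)
  # frame orthonormal and right-handed
  expect_equal(fr$R %*% t(fr$R), diag(3), tolerance = 1e-12)
  expect_equal(det(fr$R), 1, tolerance = 1e-12)
  # collinear fragment rejected
  expect_null(local_frame(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0), c(0, 0, 1)))
  # local coordinates invariant under rigid motion of all four atoms
  set.seed(23)
  for (i in 1:20) {
    pts <- matrix(rnorm(12L, sd = 2), 4L, 3L)
    fr0 <- local_frame(pts[1L, ], pts[2L, ], pts[3L, ], pts[4L, ])
    if (is.null(fr0)) next
    tr <- random_transform()
    moved <- apply_transform(pts, tr)
    fr1 <- local_frame(moved[1L, ], moved[2L, ], moved[3L, ], moved[4L, ])
    expect_equal(fr1$local, fr0$local, tolerance = 1e-9)
  }
})

test_that("extract_units recovers planted units with hand-checked geometry", {
  mc <- identity_complex(c("GLY", "ALA", "GLY"), c("O.2", "N.3", "C.3"))
  u <- extract_units(mc$complex, pocket_only = FALSE)
  expect_equal(nrow(u), 3L)
  expect_setequal(u$type_key, mc$manifest$type_key)

  # hand-computed local coordinates for the GLY|O.2 unit (identity layout,
  # zero jitter): rebuild the frame from the template coordinates
  CA <- c(0, 0, 0); C <- c(1.526, 0, 0); O <- C + 1.231 * c(0.515, 0.857, 0)
  lig <- c(u$lx[1L], u$ly[1L], u$lz[1L])
  la <- mc$complex$ligand$atoms
  world <- c(la$x[1L], la$y[1L], la$z[1L])
  x <- (CA - C) / sqrt(sum((CA - C)^2))
  v2 <- (O - C) / sqrt(sum((O - C)^2))
  z <- c(x[2] * v2[3] - x[3] * v2[2],
         x[3] * v2[1] - x[1] * v2[3],
         x[1] * v2[2] - x[2] * v2[1])
  z <- z / sqrt(sum(z^2))
  if (sum(z * (world - C)) < 0) z <- -z
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  expected_local <- drop(rbind(x, y, z) %*% (world - C))
  expect_equal(lig, unname(expected_local), tolerance = 1e-9)
  # norm of local coords = world distance to the middle fragment atom
  expect_equal(sqrt(sum(lig^2)), sqrt(sum((world - C)^2)), tolerance = 1e-9)
  expect_gte(u$lz[1L], 0)

  # ligand atom moved out of range -> no units
  far <- mc$complex
  far$ligand$atoms$x <- far$ligand$atoms$x + 500
  expect_equal(nrow(suppressWarnings(extract_units(far, pocket_only = FALSE))), 0L)
})

test_that("unit enumeration equals brute force over triples x ligand atoms", {
  set.seed(24)
  mc <- make_complex("BFU", c("GLY", "ALA", "ASP", "ALA"),
                     c("O.2", "N.3", "C.3", "O.3"))
  cx <- mc$complex
  u <- extract_units(cx, pocket_only = FALSE)

  # oracle: every (intra-residue 3-path, ligand heavy atom) combination
  # where any fragment atom passes the vdW + 1 A contact test
  prot <- cx$protein; la <- cx$ligand$atoms
  expected <- character(0)
  for (rk in unique(prot$atoms$res_key)) {
    res <- prot$atoms[prot$atoms$res_key == rk & !prot$atoms$is_hydrogen, ]
    paths <- bf_3paths(res, prot$bonds)
    for (p in paths) {
      ser <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      ra <- res[match(ser, res$serial), ]
      for (j in seq_len(nrow(la))) {
        d <- sqrt((ra$x - la$x[j])^2 + (ra$y - la$y[j])^2 + (ra$z - la$z[j])^2)
        if (any(d < ra$vdw + la$vdw[j] + 1.0))
          expected <- c(expected, paste(p, la$serial[j], sep = "|"))
      }
    }
  }
  got <- paste(paste(u$s1, u$s2, u$s3, sep = "-"), u$lig_serial, sep = "|")
  expect_setequal(got, expected)
})

test_that("units are invariant under rigid motion of the whole complex", {
  set.seed(25)
  mc <- make_complex("INV", c("GLY", "ALA"), c("O.2", "N.3"))
  u0 <- extract_units(mc$complex, pocket_only = FALSE)
  u0 <- u0[order(u0$type_key), ]
  for (i in 1:10) {
    cx <- transform_complex(mc$complex, random_transform())
    u1 <- extract_units(cx, pocket_only = FALSE)
    u1 <- u1[order(u1$type_key), ]
    expect_equal(u1$type_key, u0$type_key)
    expect_equal(u1$lx, u0$lx, tolerance = 1e-9)
    expect_equal(u1$ly, u0$ly, tolerance = 1e-9)
    expect_equal(u1$lz, u0$lz, tolerance = 1e-9)
  }
})
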
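# Structure I/O, backbone geometry and conformation labels.

test_that("PDB round trip preserves topology and coordinates", {
  fr1 <- build_chain("CREKA", noise_sigma = 0.02, seed = 11)
  fr2 <- build_chain("CREKA", noise_sigma = 0.02, seed = 12)
  traj <- trajectory(list(fr1, fr2))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(traj, path)

  back <- read_structure(path)
  expect_length(back, 2L)
  for (k in 1:2) {
    a0 <- traj$frames[[k]]$atoms
    a1 <- back$frames[[k]]$atoms
    expect_equal(a1$name, a0$name)
    expect_equal(a1$resid, a0$resid)
    expect_equal(a1$chain, a0$chain)
    # file stores angstrom with 3 decimals -> 1e-3 A = 1e-4 nm
    expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                        as.matrix(a0[, c("x", "y", "z")]))), 1e-4)
  }

  # independent reader cross-check
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  expect_equal(nrow(pdb$atom), nrow(fr1$atoms))
  expect_equal(nrow(pdb$xyz), 2L)
  expect_equal(matrix(pdb$xyz[1L, ], ncol = 3L, byrow = TRUE) / 10,
               unname(as.matrix(fr1$atoms[, c("x", "y", "z")])),
               tolerance = 1e-3)

  # deterministic byte output
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(traj, path2)
  expect_identical(readLines(path), readLines(path2))

  # a 15-chain frame writes 15 distinct chain identifiers
  box <- build_minimum_bias_box(seed = 3)
  path3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(box, path3)
  lines <- readLines(path3)
  atom_lines <- lines[startsWith(lines, "ATOM")]
  expect_length(unique(substr(atom_lines, 22, 22)), 15L)
  round2 <- read_structure(path3)
  expect_equal(round2$frames[[1L]]$box, c(9.5, 8.5, 9.0))

  expect_error(write_structure(trajectory(list())), "frames")
})

test_that("reader rejects malformed and chemically invalid input", {
  fr <- build_chain("CREKA")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fr, path)
  lines <- readLines(path)

  # six-residue chain: duplicate the last residue block as residue 6
  res5 <- lines[grepl("^ATOM", lines) & substr(lines, 23, 26) == "   5"]
  res6 <- sub("ALA A   5", "ALA A   6", res5)
  writeLines(c(lines[seq_len(length(lines) - 1L)], res6, "END"),
             path6 <- withr::local_tempfile(fileext = ".pdb"))
  expect_error(read_structure(path6), "topology error")

  # garbled coordinate field names the offending line
  bad <- lines
  substr(bad[3L], 31, 38) <- "  xx.xxx"
  writeLines(bad, pathg <- withr::local_tempfile(fileext = ".pdb"))
  expect_error(read_structure(pathg), "line 3")

  # unknown residue code
  unk <- sub("CYS", "XXX", lines)
  writeLines(unk, pathu <- withr::local_tempfile(fileext = ".pdb"))
  expect_error(read_structure(pathu), "topology error")

  # strict hydrogen check and reconstruction fallback
  drop_h <- lines[!(grepl("^ATOM", lines) &
                      trimws(substr(lines, 13, 16)) == "H" &
                      substr(lines, 23, 26) == "   3")]
  writeLines(drop_h, pathh <- withr::local_tempfile(fileext = ".pdb"))
  expect_error(read_structure(pathh, strict_h = TRUE),
               "missing-hydrogen")
  rec <- read_structure(pathh, strict_h = FALSE)
  at <- rec$frames[[1L]]$atoms
  h3 <- at[at$resno == 3L & at$name == "H", ]
  expect_equal(nrow(h3), 1L)
  # reconstructed H sits on the amide nitrogen at bonding distance
  n3 <- at[at$resno == 3L & at$name == "N", ]
  d <- sqrt(sum((as.numeric(h3[, c("x", "y", "z")]) -
                   as.numeric(n3[, c("x", "y", "z")]))^2))
  expect_equal(d, 0.101, tolerance = 1e-6)
})

test_that("backbone dihedrals invert the builder and are rigid-motion invariant", {
  pp <- rbind(c(NA, 140), c(-139, 135), c(-75, 80), c(-60, -40),
              c(-139, NA))
  fr <- build_chain("CREKA", phi_psi = pp)
  dh <- backbone_dihedrals(fr, "A")
  expect_true(is.na(dh$phi[1L]) && is.na(dh$psi[5L]))
  expect_equal(dh$phi[2:5], c(-139, -75, -60, -139), tolerance = 0.5)
  expect_equal(dh$psi[1:4], c(140, 135, 80, -40), tolerance = 0.5)

  # four points with perpendicular half-planes give a +/-90 dihedral
  expect_equal(abs(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                                  c(0, 1, 1))), 90)

  # invariance under rigid rotation + translation
  for (s in 1:5) {
    moved <- rigid_move(fr, seed = s)
    dh2 <- backbone_dihedrals(moved, "A")
    expect_equal(dh2$phi, dh$phi, tolerance = 1e-8)
    expect_equal(dh2$psi, dh$psi, tolerance = 1e-8)
  }

  # small coordinate noise perturbs dihedrals mildly
  noisy <- build_chain("CREKA", noise_sigma = 0.001, seed = 99)
  dhn <- backbone_dihedrals(noisy, "A")
  expect_lt(max(abs(dhn$phi - backbone_dihedrals(
    build_chain("CREKA"), "A")$phi), na.rm = TRUE), 2)
})

test_that("conformation labels are total, exclusive and match canonical points", {
  expect_equal(assign_conformation(-139, 135), "BETA")
  expect_equal(assign_conformation(-60, -45), "TURN_REGION")
  expect_equal(assign_conformation(120, 10), "OTHER")
  expect_equal(assign_conformation(NA, 135), "UNDEFINED")

  # total and single-valued over a dense grid
  grid <- expand.grid(phi = seq(-179, 180, by = 13),
                      psi = seq(-179, 180, by = 13))
  labs <- assign_conformation(grid$phi, grid$psi)
  expect_true(all(labs %in% c("BETA", "TURN_REGION", "OTHER")))
  # the beta and turn boxes do not overlap
  beta <- labs == "BETA"
  turn <- labs == "TURN_REGION"
  expect_false(any(beta & turn))
  # custom regions are honoured
  wide <- conformation_regions(beta_phi = c(-180, 0),
                               beta_psi_ranges = list(c(-180, 180)),
                               turn_phi = c(1, 2), turn_psi = c(1, 2))
  expect_equal(assign_conformation(-60, -45, wide), "BETA")
})
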
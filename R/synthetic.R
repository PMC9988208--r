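# Synthetic all-atom pentapeptide generators: single chains at requested
# backbone dihedrals, docked beta-sheet pairs, turn chains, salt-bridged
# dimers and minimum-bias multi-chain boxes.
#
# Internal geometry uses ideal (textbook) bond lengths and angles; only
# polar hydrogens are built. All builders are deterministic for a fixed
# seed; seeds drive only the stochastic elements (coordinate noise,
# random placement). Units: nm, degrees.

# ideal internal coordinates (nm / degrees)
GEO <- list(
  n_ca = 0.1458, ca_c = 0.1525, c_n = 0.1329, c_o = 0.1231,
  n_h = 0.101, n_cn = 0.1449,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_c_n_h = 119.0, ang_cterm_o = 117.0,
  omega = 180
)

#' Canonical backbone dihedral presets
#'
#' Textbook (phi, psi) presets used by the builders: antiparallel and
#' parallel beta strand, polyproline-II-like extended, type-I beta-turn
#' interior residues and classic gamma-turn residue. All are
#' configuration defaults, overridable in every builder.
#'
#' @return Named list of numeric `c(phi, psi)` pairs (degrees).
#' @export
dihedral_presets <- function() {
  list(antiparallel_beta = c(-139, 135),
       parallel_beta = c(-119, 113),
       ppii = c(-80, 150),
       turn1_i1 = c(-60, -30),
       turn1_i2 = c(-90, 0),
       gamma = c(75, -65))
}

# phi_psi: 5 x 2 matrix; NA entries fall back to the strand preset for
# geometry bootstrap (phi of residue 1 and psi of residue 5 are not
# observable but are still needed to place the first carbonyl direction
# and the terminal carboxylate).
normalize_phi_psi <- function(phi_psi, default = c(-139, 135)) {
  if (is.null(phi_psi)) {
    phi_psi <- matrix(rep(default, each = 5L), ncol = 2L)
  }
  if (is.list(phi_psi)) phi_psi <- do.call(rbind, phi_psi)
  phi_psi <- as.matrix(phi_psi)
  stopifnot(nrow(phi_psi) == 5L, ncol(phi_psi) == 2L)
  phi_psi[is.na(phi_psi[, 1L]), 1L] <- default[1L]
  phi_psi[is.na(phi_psi[, 2L]), 2L] <- default[2L]
  phi_psi
}

#' Build one all-atom pentapeptide chain
#'
#' Grows an all-atom chain (polar hydrogens only) by internal
#' coordinates at the requested backbone dihedrals. Residue 3 of CRENKA
#' (code MEG) receives an N-methyl carbon `CN` in place of the amide
#' hydrogen. Termini are charged by default: N-terminal ammonium
#' (H1/H2/H3) and C-terminal carboxylate (O/OXT). At `noise_sigma = 0`
#' the requested dihedrals are realised within numerical precision.
#'
#' @param sequence `"CREKA"` or `"CRENKA"` (or any registered sequence).
#' @param phi_psi 5 x 2 matrix (or list of 5 `c(phi, psi)` pairs) in
#'   degrees; `NULL` for an antiparallel beta strand; `NA` entries at
#'   the termini are tolerated.
#' @param noise_sigma Isotropic Gaussian noise s.d. per coordinate, nm.
#' @param seed Integer seed for the noise (ignored when
#'   `noise_sigma = 0` and no other randomness is used).
#' @param chain_id One-character chain identifier.
#' @param glu_protonated Build the Glu/MEG side carboxylate in its
#'   neutral (protonated, HE2-bearing) form, the dominant state at pH 4.
#' @param serial_start First atom serial number.
#' @return A single-chain [system_frame()].
#' @export
build_chain <- function(sequence = "CREKA", phi_psi = NULL,
                        noise_sigma = 0, seed = NULL, chain_id = "A",
                        glu_protonated = FALSE, serial_start = 1L) {
  stopifnot(noise_sigma >= 0)
  codes <- sequence_codes(sequence)
  pp <- normalize_phi_psi(phi_psi)
  atoms <- build_chain_atoms(codes, pp, glu_protonated)
  df <- assemble_chain_df(atoms, codes, chain_id, serial_start)
  if (noise_sigma > 0) {
    noise <- function() {
      m <- matrix(rnorm(3L * nrow(df), sd = noise_sigma), ncol = 3L)
      df[, c("x", "y", "z")] <- df[, c("x", "y", "z")] + m
      df
    }
    df <- if (is.null(seed)) noise() else withr::with_seed(seed, noise())
  }
  system_frame(df, validate = TRUE)
}

# returns nested list pos[[resno]][[atom_name]] = xyz
build_chain_atoms <- function(codes, pp, glu_protonated = FALSE) {
  n_res <- length(codes)
  pos <- rep(list(list()), n_res)
  g <- GEO
  # bootstrap residue 1
  pos[[1L]]$N <- c(0, 0, 0)
  pos[[1L]]$CA <- c(g$n_ca, 0, 0)
  th <- deg2rad(180 - g$ang_n_ca_c)
  pos[[1L]]$C <- pos[[1L]]$CA + g$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n_res - 1L)) {
    psi <- pp[i, 2L]
    pos[[i + 1L]]$N <- place_atom(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                                  g$c_n, g$ang_ca_c_n, psi)
    pos[[i + 1L]]$CA <- place_atom(pos[[i]]$CA, pos[[i]]$C,
                                   pos[[i + 1L]]$N,
                                   g$n_ca, g$ang_c_n_ca, g$omega)
    pos[[i + 1L]]$C <- place_atom(pos[[i]]$C, pos[[i + 1L]]$N,
                                  pos[[i + 1L]]$CA,
                                  g$ca_c, g$ang_n_ca_c, pp[i + 1L, 1L])
    # carbonyl O of residue i: anti to the next amide N across C
    pos[[i]]$O <- place_atom(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                             g$c_o, g$ang_ca_c_o, psi + 180)
    # amide H (or N-methyl carbon) on residue i+1, anti to O(i)
    if (codes[i + 1L] == "MEG") {
      pos[[i + 1L]]$CN <- place_atom(pos[[i]]$O, pos[[i]]$C,
                                     pos[[i + 1L]]$N,
                                     g$n_cn, g$ang_c_n_h, 180)
    } else {
      pos[[i + 1L]]$H <- place_atom(pos[[i]]$O, pos[[i]]$C,
                                    pos[[i + 1L]]$N,
                                    g$n_h, g$ang_c_n_h, 180)
    }
  }
  # C-terminal carboxylate
  psi5 <- pp[n_res, 2L]
  pos[[n_res]]$O <- place_atom(pos[[n_res]]$N, pos[[n_res]]$CA,
                               pos[[n_res]]$C,
                               g$c_o, g$ang_cterm_o, psi5 + 180)
  pos[[n_res]]$OXT <- place_atom(pos[[n_res]]$N, pos[[n_res]]$CA,
                                 pos[[n_res]]$C,
                                 g$c_o, g$ang_cterm_o, psi5)
  # N-terminal ammonium
  for (k in 1:3) {
    pos[[1L]][[paste0("H", k)]] <-
      place_atom(pos[[1L]]$C, pos[[1L]]$CA, pos[[1L]]$N,
                 0.103, 109.5, c(180, 60, -60)[k])
  }
  # side chains
  for (i in seq_len(n_res)) {
    pos[[i]] <- c(pos[[i]],
                  build_sidechain(codes[i], pos[[i]], glu_protonated))
  }
  pos
}

# side-chain atom positions given backbone N/CA/C of the residue;
# improper dihedral(N, C, CA, CB) = +123 deg selects the L-configuration
build_sidechain <- function(code, bb, glu_protonated = FALSE,
                            chis = NULL) {
  n <- bb$N; ca <- bb$CA; c <- bb$C
  s <- list()
  s$CB <- place_atom(n, c, ca, 0.1530, 110.1, 123)
  chi <- function(k) if (is.null(chis) || length(chis) < k ||
                         is.na(chis[k])) 180 else chis[k]
  if (code == "CYS") {
    s$SG <- place_atom(n, ca, s$CB, 0.1808, 114.4, chi(1))
    s$HG <- place_atom(ca, s$CB, s$SG, 0.0134 * 10, 96.0, 180)
  } else if (code == "ARG") {
    s$CG <- place_atom(n, ca, s$CB, 0.1530, 114.1, chi(1))
    s$CD <- place_atom(ca, s$CB, s$CG, 0.1530, 111.3, chi(2))
    s$NE <- place_atom(s$CB, s$CG, s$CD, 0.1463, 112.0, chi(3))
    s$CZ <- place_atom(s$CG, s$CD, s$NE, 0.1340, 124.2, chi(4))
    s$HE <- place_atom(s$CG, s$CD, s$NE, 0.101, 118.0, chi(4) + 180)
    s$NH1 <- place_atom(s$CD, s$NE, s$CZ, 0.1326, 120.0, 0)
    s$NH2 <- place_atom(s$CD, s$NE, s$CZ, 0.1326, 120.0, 180)
    s$HH11 <- place_atom(s$NE, s$CZ, s$NH1, 0.101, 120.0, 180)
    s$HH12 <- place_atom(s$NE, s$CZ, s$NH1, 0.101, 120.0, 0)
    s$HH21 <- place_atom(s$NE, s$CZ, s$NH2, 0.101, 120.0, 180)
    s$HH22 <- place_atom(s$NE, s$CZ, s$NH2, 0.101, 120.0, 0)
  } else if (code %in% c("GLU", "MEG")) {
    s$CG <- place_atom(n, ca, s$CB, 0.1530, 114.1, chi(1))
    s$CD <- place_atom(ca, s$CB, s$CG, 0.1516, 112.6, chi(2))
    s$OE1 <- place_atom(s$CB, s$CG, s$CD, 0.1249, 118.4, 0)
    s$OE2 <- place_atom(s$CB, s$CG, s$CD, 0.1249, 118.4, 180)
    if (glu_protonated) {
      s$HE2 <- place_atom(s$CG, s$CD, s$OE2, 0.097, 106.0, 0)
    }
  } else if (code == "LYS") {
    s$CG <- place_atom(n, ca, s$CB, 0.1530, 114.1, chi(1))
    s$CD <- place_atom(ca, s$CB, s$CG, 0.1530, 111.3, chi(2))
    s$CE <- place_atom(s$CB, s$CG, s$CD, 0.1530, 111.3, chi(3))
    s$NZ <- place_atom(s$CG, s$CD, s$CE, 0.1489, 111.9, chi(4))
    s$HZ1 <- place_atom(s$CD, s$CE, s$NZ, 0.103, 109.5, 180)
    s$HZ2 <- place_atom(s$CD, s$CE, s$NZ, 0.103, 109.5, 60)
    s$HZ3 <- place_atom(s$CD, s$CE, s$NZ, 0.103, 109.5, -60)
  }
  s
}

# canonical atom emission order per residue
atom_order <- function(code, resno, n_res, names_present) {
  base <- c("N",
            if (resno == 1L) c("H1", "H2", "H3") else c("H", "CN"),
            "CA", "CB")
  side <- setdiff(SIDECHAIN_ATOMS[[code]], "CB")
  tailn <- c("C", "O", if (resno == n_res) "OXT")
  ord <- c(base, side, tailn)
  ord[ord %in% names_present]
}

assemble_chain_df <- function(pos, codes, chain_id, serial_start = 1L) {
  rows <- list()
  n_res <- length(codes)
  serial <- serial_start - 1L
  for (i in seq_len(n_res)) {
    present <- names(pos[[i]])
    for (nm in atom_order(codes[i], i, n_res, present)) {
      serial <- serial + 1L
      xyz <- pos[[i]][[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = nm, element = element_from_name(nm),
        chain = chain_id, resno = i, resid = codes[i],
        x = xyz[1L], y = xyz[2L], z = xyz[3L], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# combine single-chain frames into one multi-chain frame, renumbering
# serials consecutively
combine_chains <- function(chain_frames, box = NULL) {
  dfs <- list()
  serial <- 0L
  for (fr in chain_frames) {
    at <- fr$atoms
    at$serial <- serial + seq_len(nrow(at))
    serial <- serial + nrow(at)
    dfs[[length(dfs) + 1L]] <- at
  }
  system_frame(do.call(rbind, dfs), box = box, validate = TRUE)
}

## ------------------------------------------------------------- docking

# Rigid-body docking of chain B onto chain A by Nelder-Mead over
# (translation, rotation-vector), minimising deviation of target
# H...O (or N...O) distances from `d_ref`, with an angle reward for
# H-bond targets and a soft steric clash penalty; `avoid` pairs are
# pushed beyond `avoid_cut`.
dock_chains <- function(atA, atB, targets, inits, d_ref = 0.195,
                        avoid = NULL, avoid_cut = 0.40) {
  xyzB0 <- as.matrix(atB[, c("x", "y", "z")])
  centB <- colMeans(xyzB0)
  heavyA <- as.matrix(atA[atA$element != "H", c("x", "y", "z")])
  heavyB_idx <- which(atB$element != "H")

  aidx <- function(at, resno, name) {
    i <- which(at$resno == resno & at$name == name)
    if (length(i) != 1L) NA_integer_ else i
  }

  # resolve targets to row indices; drop targets whose atoms are absent
  # (e.g. the MEG amide hydrogen)
  resolved <- list()
  for (t in targets) {
    ia <- aidx(atA, t$a_res, t$a_name)
    ib <- aidx(atB, t$b_res, t$b_name)
    if (is.na(ia) || is.na(ib)) next
    iheavy <- NA_integer_
    heavy_on_a <- NA
    if (!is.null(t$heavy_name)) {
      if (t$heavy_on == "A") {
        iheavy <- aidx(atA, t$a_res, t$heavy_name); heavy_on_a <- TRUE
      } else {
        iheavy <- aidx(atB, t$b_res, t$heavy_name); heavy_on_a <- FALSE
      }
    }
    resolved[[length(resolved) + 1L]] <-
      list(ia = ia, ib = ib, d = if (is.null(t$d)) d_ref else t$d,
           iheavy = iheavy, heavy_on_a = heavy_on_a)
  }
  if (!length(resolved)) stop("no dockable targets")

  avoid_res <- list()
  for (t in if (is.null(avoid)) list() else avoid) {
    ia <- aidx(atA, t$a_res, t$a_name)
    ib <- aidx(atB, t$b_res, t$b_name)
    if (!is.na(ia) && !is.na(ib)) {
      avoid_res[[length(avoid_res) + 1L]] <- c(ia, ib)
    }
  }

  xyzA <- as.matrix(atA[, c("x", "y", "z")])
  obj <- function(par) {
    rot <- rotvec_matrix(par[4:6])
    xyzB <- transform_coords(xyzB0, rot, centB, par[1:3])
    cost <- 0
    for (t in resolved) {
      dv <- xyzB[t$ib, ] - xyzA[t$ia, ]
      d <- sqrt(sum(dv * dv))
      cost <- cost + (d - t$d)^2
      if (!is.na(t$iheavy)) {
        # angle at the hydrogen: heavy - H ... partner
        if (t$heavy_on_a) {
          hv <- xyzA[t$iheavy, ] - xyzA[t$ia, ]; pv <- xyzB[t$ib, ] - xyzA[t$ia, ]
        } else {
          hv <- xyzB[t$iheavy, ] - xyzB[t$ib, ]; pv <- xyzA[t$ia, ] - xyzB[t$ib, ]
        }
        ca <- sum(hv * pv) / (sqrt(sum(hv^2)) * sqrt(sum(pv^2)))
        ang <- rad2deg(acos(max(-1, min(1, ca))))
        cost <- cost + (max(0, 155 - ang) / 150)^2 * 0.5
      }
    }
    for (p in avoid_res) {
      dv <- xyzB[p[2L], ] - xyzA[p[1L], ]
      d <- sqrt(sum(dv * dv))
      if (d < avoid_cut) cost <- cost + 3 * (avoid_cut - d)^2
    }
    # steric clash between heavy atoms
    hB <- xyzB[heavyB_idx, , drop = FALSE]
    dmat <- outer(rowSums(heavyA^2), rep(1, nrow(hB))) +
      outer(rep(1, nrow(heavyA)), rowSums(hB^2)) -
      2 * heavyA %*% t(hB)
    dmat[dmat < 0] <- 0
    dm <- sqrt(dmat)
    clash <- dm < 0.26
    if (any(clash)) cost <- cost + 5 * sum((0.26 - dm[clash])^2)
    cost
  }

  best <- NULL
  for (init in inits) {
    fit <- optim(init, obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  rot <- rotvec_matrix(best$par[4:6])
  atB[, c("x", "y", "z")] <-
    transform_coords(xyzB0, rot, centB, best$par[1:3])
  list(atoms = atB, value = best$value)
}

# local frame of a strand: u along the chain, h the carbonyl (H-bond)
# direction orthogonalised against u, s = u x h
strand_frame <- function(at) {
  ca1 <- backbone_xyz(at, 1L, "CA")
  ca5 <- backbone_xyz(at, 5L, "CA")
  u <- vec_unit(ca5 - ca1)
  co <- backbone_xyz(at, 2L, "O") - backbone_xyz(at, 2L, "C")
  h <- co - sum(co * u) * u
  h <- vec_unit(h)
  list(u = u, h = h, s = vec_cross(u, h))
}

#' Build a two-stranded beta-sheet pair
#'
#' Builds two ideal strands and rigid-docks the second onto the first so
#' that the canonical inter-main-chain hydrogen-bond ladder of the
#' requested orientation forms under the default detection criteria.
#' For CRENKA the residue-3 rungs are unavailable (no amide hydrogen on
#' the methylated nitrogen), so the docked pair carries strictly fewer
#' backbone hydrogen bonds than its CREKA twin.
#'
#' @param orientation `"ANTIPARALLEL"` or `"PARALLEL"`.
#' @param sequence Registered sequence name.
#' @param separation Target inter-strand axis distance, nm (realisable
#'   roughly in 0.45-0.55; values outside `[0.40, 0.60]` are rejected).
#' @param seed Seed for the coordinate noise.
#' @param noise_sigma Gaussian coordinate noise, nm.
#' @param phi_psi Optional 5 x 2 dihedral override for both strands
#'   (e.g. a polyproline-II conformation to obtain backbone bonds
#'   between strands outside the beta region).
#' @return A two-chain [system_frame()] (chains `"A"`, `"B"`).
#' @export
build_sheet_pair <- function(orientation = c("ANTIPARALLEL", "PARALLEL"),
                             sequence = "CREKA", separation = 0.50,
                             seed = NULL, noise_sigma = 0,
                             phi_psi = NULL) {
  orientation <- match.arg(orientation)
  if (!is.finite(separation) || separation < 0.40 || separation > 0.60) {
    stop("parameter error: separation must lie in [0.40, 0.60] nm")
  }
  preset <- if (orientation == "ANTIPARALLEL") {
    dihedral_presets()$antiparallel_beta
  } else {
    dihedral_presets()$parallel_beta
  }
  if (is.null(phi_psi)) {
    phi_psi <- matrix(rep(preset, each = 5L), ncol = 2L)
  }
  frA <- build_chain(sequence, phi_psi, chain_id = "A")
  frB <- build_chain(sequence, phi_psi, chain_id = "B")
  atA <- frA$atoms
  atB <- frB$atoms
  sf <- strand_frame(atA)

  mk_t <- function(d_res, d_chain, a_res) {
    # donor amide H on d_chain bonds the carbonyl O of a_res on the other
    if (d_chain == "A") {
      list(a_res = d_res, a_name = "H", b_res = a_res, b_name = "O",
           heavy_name = "N", heavy_on = "A")
    } else {
      list(a_res = a_res, a_name = "O", b_res = d_res, b_name = "H",
           heavy_name = "N", heavy_on = "B")
    }
  }
  if (orientation == "ANTIPARALLEL") {
    # alternating rungs of the 6 - i register: pairs (3,3) and (5,1)
    targets <- list(mk_t(3L, "A", 3L), mk_t(3L, "B", 3L),
                    mk_t(5L, "A", 1L), mk_t(5L, "B", 1L))
  } else {
    # parallel register: alternating rungs, donor strand switching along
    # the ladder (the subset realisable with rigid ideal strands)
    targets <- list(mk_t(2L, "B", 1L), mk_t(3L, "A", 2L),
                    mk_t(4L, "B", 3L), mk_t(5L, "A", 4L))
  }

  centA <- colMeans(as.matrix(atA[, c("x", "y", "z")]))
  centB <- colMeans(as.matrix(atB[, c("x", "y", "z")]))
  inits <- list()
  flips <- if (orientation == "ANTIPARALLEL") {
    list(sf$s * pi, sf$h * pi)
  } else {
    list(c(0, 0, 0))
  }
  for (rot in flips) {
    for (side in c(1, -1)) {
      for (du in c(0, 0.17, -0.17, 0.34, -0.34)) {
        shift <- centA - centB + side * separation * sf$h + du * sf$u
        inits[[length(inits) + 1L]] <- c(shift, rot)
      }
    }
  }
  dock <- dock_chains(atA, atB, targets, inits)
  fr <- combine_chains(list(frA, system_frame(dock$atoms,
                                              validate = FALSE)))
  if (noise_sigma > 0) {
    fr <- add_noise(fr, noise_sigma, seed)
  }
  fr
}

#' Perturb every atom of a frame with Gaussian noise
#'
#' Adds isotropic, seeded Gaussian displacement (s.d. `sigma` nm per
#' coordinate) to all atoms. This is the noise model used by every
#' builder; exposing it separately allows noise ladders over a single
#' docked fixture.
#'
#' @param frame A [system_frame()].
#' @param sigma Noise standard deviation, nm (>= 0).
#' @param seed Integer seed.
#' @return The perturbed frame.
#' @export
perturb_frame <- function(frame, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(frame)
  jitter_fun <- function() {
    m <- matrix(rnorm(3L * nrow(frame$atoms), sd = sigma), ncol = 3L)
    frame$atoms[, c("x", "y", "z")] <-
      frame$atoms[, c("x", "y", "z")] + m
    frame
  }
  if (is.null(seed)) jitter_fun() else withr::with_seed(seed, jitter_fun())
}

add_noise <- function(frame, sigma, seed = NULL) {
  perturb_frame(frame, sigma, seed)
}

#' Build a chain exhibiting a beta- or gamma-turn hydrogen bond
#'
#' Starts from the textbook turn presets (type-I beta-turn interior
#' residues -60/-30 and -90/0; classic gamma-turn residue +75/-65) and
#' refines the free backbone dihedrals so that the defining
#' intramolecular bond - acceptor carbonyl of residue i, donor amide of
#' residue i+3 (beta, i = 1) or i+2 (gamma, i = 2) - satisfies the
#' default detection criteria.
#'
#' @param kind `"BETA_TURN"` or `"GAMMA_TURN"`.
#' @param sequence Registered sequence name.
#' @param seed Seed for the coordinate noise.
#' @param noise_sigma Gaussian coordinate noise, nm.
#' @param chain_id Chain identifier.
#' @return A single-chain [system_frame()].
#' @export
build_turn_chain <- function(kind = c("BETA_TURN", "GAMMA_TURN"),
                             sequence = "CREKA", seed = NULL,
                             noise_sigma = 0, chain_id = "A") {
  kind <- match.arg(kind)
  codes <- sequence_codes(sequence)
  pr <- dihedral_presets()
  ext <- pr$antiparallel_beta
  if (kind == "BETA_TURN") {
    # free: psi1, (phi, psi) of residues 2 and 3; target O(1)...H-N(4)
    base <- rbind(c(ext[1L], 150), pr$turn1_i1, pr$turn1_i2, ext, ext)
    free_idx <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 2L), c(3L, 1L),
                      c(3L, 2L))
    acc_res <- 1L
  } else {
    # free: psi2, (phi, psi) of residue 3; target O(2)...H-N(4)
    base <- rbind(c(ext[1L], 150), c(ext[1L], 150), pr$gamma, ext, ext)
    free_idx <- rbind(c(2L, 2L), c(3L, 1L), c(3L, 2L))
    acc_res <- 2L
  }
  theta0 <- apply(free_idx, 1L, function(ij) base[ij[1L], ij[2L]])
  obj <- function(theta) {
    pp <- base
    for (k in seq_len(nrow(free_idx))) {
      pp[free_idx[k, 1L], free_idx[k, 2L]] <- theta[k]
    }
    pos <- build_backbone_only(codes, pp)
    o <- pos[[acc_res]]$O
    h <- pos[[4L]]$H
    n <- pos[[4L]]$N
    if (is.null(h)) stop("turn donor residue lacks an amide hydrogen")
    d <- vec_norm(o - h)
    ang <- point_angle(n, h, o)
    (d - 0.195)^2 + (max(0, 155 - ang) / 150)^2 * 0.05 +
      1e-6 * sum((theta - theta0)^2)
  }
  fit <- optim(theta0, obj, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
  pp <- base
  for (k in seq_len(nrow(free_idx))) {
    pp[free_idx[k, 1L], free_idx[k, 2L]] <- fit$par[k]
  }
  build_chain(sequence, pp, noise_sigma = noise_sigma, seed = seed,
              chain_id = chain_id)
}

# backbone + amide H only (fast path for the turn optimiser)
build_backbone_only <- function(codes, pp) {
  build_chain_atoms_backbone(codes, pp)
}

build_chain_atoms_backbone <- function(codes, pp) {
  n_res <- length(codes)
  pos <- rep(list(list()), n_res)
  g <- GEO
  pos[[1L]]$N <- c(0, 0, 0)
  pos[[1L]]$CA <- c(g$n_ca, 0, 0)
  th <- deg2rad(180 - g$ang_n_ca_c)
  pos[[1L]]$C <- pos[[1L]]$CA + g$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n_res - 1L)) {
    psi <- pp[i, 2L]
    pos[[i + 1L]]$N <- place_atom(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                                  g$c_n, g$ang_ca_c_n, psi)
    pos[[i + 1L]]$CA <- place_atom(pos[[i]]$CA, pos[[i]]$C,
                                   pos[[i + 1L]]$N,
                                   g$n_ca, g$ang_c_n_ca, g$omega)
    pos[[i + 1L]]$C <- place_atom(pos[[i]]$C, pos[[i + 1L]]$N,
                                  pos[[i + 1L]]$CA,
                                  g$ca_c, g$ang_n_ca_c, pp[i + 1L, 1L])
    pos[[i]]$O <- place_atom(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                             g$c_o, g$ang_ca_c_o, psi + 180)
    if (codes[i + 1L] != "MEG") {
      pos[[i + 1L]]$H <- place_atom(pos[[i]]$O, pos[[i]]$C,
                                    pos[[i + 1L]]$N,
                                    g$n_h, g$ang_c_n_h, 180)
    }
  }
  pos
}

#' Build a chain with an intramolecular side-chain hydrogen bond
#'
#' Starts from a beta-turn chain and rotates the arginine side-chain
#' chi torsions so that a guanidinium N-H donates to the Glu/MEG side
#' carboxylate (or, whichever refines better, the C-terminal
#' carboxylate) of the same chain, producing an intramolecular bond
#' involving side-chain groups.
#'
#' @param sequence Registered sequence name.
#' @param seed Seed for the coordinate noise.
#' @param noise_sigma Gaussian coordinate noise, nm.
#' @param chain_id Chain identifier.
#' @return A single-chain [system_frame()].
#' @export
build_intra_side_chain <- function(sequence = "CREKA", seed = NULL,
                                   noise_sigma = 0, chain_id = "A") {
  fr <- build_turn_chain("BETA_TURN", sequence, chain_id = chain_id)
  at <- fr$atoms
  bb <- list(N = backbone_xyz2(at, 2L, "N"),
             CA = backbone_xyz2(at, 2L, "CA"),
             C = backbone_xyz2(at, 2L, "C"))
  other_heavy <- as.matrix(
    at[at$element != "H" & !(at$resno == 2L & !(at$name %in%
      c("N", "CA", "C", "O"))), c("x", "y", "z")])
  refine <- function(target) {
    obj <- function(chis) {
      s <- build_sidechain("ARG", bb, chis = chis)
      d <- vec_norm(s$HH11 - target)
      ang <- point_angle(s$NH1, s$HH11, target)
      cost <- (d - 0.195)^2 + (max(0, 155 - ang) / 150)^2 * 0.5
      side_heavy <- do.call(rbind, s[c("CB", "CG", "CD", "NE", "CZ",
                                       "NH1", "NH2")])
      d2 <- outer(rowSums(side_heavy^2), rep(1, nrow(other_heavy))) +
        outer(rep(1, nrow(side_heavy)), rowSums(other_heavy^2)) -
        2 * side_heavy %*% t(other_heavy)
      d2[d2 < 0] <- 0
      dm <- sqrt(d2)
      clash <- dm < 0.26 & dm > 1e-6
      if (any(clash)) cost <- cost + 5 * sum((0.26 - dm[clash])^2)
      cost
    }
    best <- NULL
    for (init in list(c(180, 180, 180, 180), c(-60, 180, 180, 180),
                      c(60, -60, 180, 60), c(-60, -60, 180, -60))) {
      fit <- optim(init, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    best
  }
  cand <- list(oe1 = backbone_xyz2(at, 3L, "OE1"),
               cterm = backbone_xyz2(at, 5L, "OXT"))
  fits <- lapply(cand, refine)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
  s <- build_sidechain("ARG", bb, chis = best$par)
  for (nm in names(s)) {
    sel <- at$resno == 2L & at$name == nm
    if (any(sel)) at[sel, c("x", "y", "z")] <- rbind(s[[nm]])
  }
  out <- system_frame(at, box = fr$box, validate = TRUE)
  if (noise_sigma > 0) out <- perturb_frame(out, noise_sigma, seed)
  out
}

#' Build a minimum-bias multi-chain box
#'
#' Randomly places `n_chains` copies of an ideal chain (random uniform
#' rotation, uniform position) in an orthorhombic box by rejection
#' sampling, so that every pair of chain centres is at least
#' `min_spacing` apart and no inter-chain heavy-atom pair comes within
#' `clearance`. The defaults reproduce the starting conditions of the
#' simulated systems: 15 chains in a 9.5 x 8.5 x 9.0 nm box at >= 1.8 nm
#' spacing, i.e. mostly non-interacting chains.
#'
#' @param n_chains Number of chains (>= 1).
#' @param box Numeric 3-vector of box lengths, nm.
#' @param min_spacing Minimum centre-to-centre distance, nm.
#' @param sequence Registered sequence name.
#' @param seed Integer seed (placement is deterministic given the seed).
#' @param clearance Minimum inter-chain heavy-atom distance, nm.
#' @param max_attempts Placement attempts per chain before giving up.
#' @return A [system_frame()] with `n_chains` chains and the box set.
#' @export
build_minimum_bias_box <- function(n_chains = 15L,
                                   box = c(9.5, 8.5, 9.0),
                                   min_spacing = 1.8,
                                   sequence = "CREKA", seed = NULL,
                                   clearance = 0.5,
                                   max_attempts = 2000L) {
  stopifnot(n_chains >= 1L, length(box) == 3L, all(box > 0),
            min_spacing > 0)
  alphabet <- c(LETTERS, letters, 0:9)
  if (n_chains > length(alphabet)) {
    stop("at most ", length(alphabet), " chains supported")
  }
  # coarse feasibility: exclusion spheres must not crowd the box
  if (n_chains * (4 / 3) * pi * (min_spacing / 2)^3 > 0.55 * prod(box)) {
    stop("feasibility error: ", n_chains, " chains at ", min_spacing,
         " nm spacing do not fit the box")
  }
  template <- build_chain(sequence, chain_id = "A")
  t_xyz <- as.matrix(template$atoms[, c("x", "y", "z")])
  t_xyz <- sweep(t_xyz, 2L, colMeans(t_xyz))
  radius <- max(sqrt(rowSums(t_xyz^2)))
  margin <- pmin(radius + 0.05, box / 2 - 0.01)
  if (any(box - 2 * margin <= 0)) {
    stop("feasibility error: box too small for the chain")
  }
  heavy <- template$atoms$element != "H"

  place <- function() {
    placed_heavy <- list()
    centers <- matrix(numeric(0), ncol = 3L)
    out <- vector("list", n_chains)
    for (k in seq_len(n_chains)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        rot <- random_rotation()
        cen <- margin + runif(3L) * (box - 2 * margin)
        if (nrow(centers) &&
            min(sqrt(rowSums(sweep(centers, 2L, cen)^2))) < min_spacing) {
          next
        }
        xyz <- sweep(t_xyz %*% t(rot), 2L, cen, `+`)
        hx <- xyz[heavy, , drop = FALSE]
        clash <- FALSE
        for (p in placed_heavy) {
          d2 <- outer(rowSums(hx^2), rep(1, nrow(p))) +
            outer(rep(1, nrow(hx)), rowSums(p^2)) - 2 * hx %*% t(p)
          if (min(d2) < clearance^2) { clash <- TRUE; break }
        }
        if (clash) next
        placed_heavy[[k]] <- hx
        centers <- rbind(centers, cen)
        out[[k]] <- xyz
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("feasibility error: could not place chain ", k, " after ",
             max_attempts, " attempts")
      }
    }
    out
  }
  all_xyz <- if (is.null(seed)) place() else withr::with_seed(seed, place())

  chains <- vector("list", n_chains)
  for (k in seq_len(n_chains)) {
    at <- template$atoms
    at$chain <- alphabet[k]
    at[, c("x", "y", "z")] <- all_xyz[[k]]
    chains[[k]] <- system_frame(at, validate = FALSE)
  }
  combine_chains(chains, box = box)
}

#' Build a salt-bridged dimer
#'
#' Two turn-conformation chains docked so that an arginine guanidinium
#' nitrogen of chain A contacts a side-chain carboxylate oxygen of
#' chain B below the salt-bridge cutoff, while backbone amide H...O
#' pairs between the chains are kept apart (no inter-main-chain
#' hydrogen bond).
#'
#' @param sequence Registered sequence name.
#' @param seed Seed for the coordinate noise.
#' @param noise_sigma Gaussian coordinate noise, nm.
#' @return A two-chain [system_frame()].
#' @export
build_salt_bridge_dimer <- function(sequence = "CREKA", seed = NULL,
                                    noise_sigma = 0) {
  frA <- build_turn_chain("BETA_TURN", sequence, chain_id = "A")
  frB <- build_turn_chain("BETA_TURN", sequence, chain_id = "B")
  atA <- frA$atoms
  atB <- frB$atoms
  # salt-bridge targets: Arg(2) guanidinium of A to Glu/MEG(3)
  # carboxylate of B (heavy-atom N...O distance 0.32 nm)
  targets <- list(
    list(a_res = 2L, a_name = "NH1", b_res = 3L, b_name = "OE1",
         d = 0.32),
    list(a_res = 2L, a_name = "NH2", b_res = 3L, b_name = "OE2",
         d = 0.32))
  # keep all inter-chain backbone amide H...O pairs beyond 0.40 nm
  avoid <- list()
  for (dres in 2:5) {
    for (ares in 1:5) {
      avoid[[length(avoid) + 1L]] <-
        list(a_res = dres, a_name = "H", b_res = ares, b_name = "O")
      avoid[[length(avoid) + 1L]] <-
        list(a_res = ares, a_name = "O", b_res = dres, b_name = "H")
    }
  }
  # init: B displaced outward along the guanidinium direction
  nh1 <- backbone_xyz2(atA, 2L, "NH1")
  cz <- backbone_xyz2(atA, 2L, "CZ")
  dir <- vec_unit(nh1 - cz)
  oe1B <- backbone_xyz2(atB, 3L, "OE1")
  # inits place B's OE1 near the guanidinium approach point under a few
  # orientations
  inits <- list()
  for (rotax in list(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi))) {
    inits[[length(inits) + 1L]] <- c(nh1 + 0.32 * dir - oe1B, rotax)
  }
  dock <- dock_chains(atA, atB, targets, inits, avoid = avoid,
                      avoid_cut = 0.40)
  fr <- combine_chains(list(frA, system_frame(dock$atoms,
                                              validate = FALSE)))
  if (noise_sigma > 0) fr <- add_noise(fr, noise_sigma, seed)
  fr
}

# like backbone_xyz but for any named atom
backbone_xyz2 <- function(atoms, resno, name) {
  row <- atoms[atoms$resno == resno & atoms$name == name, ]
  if (nrow(row) != 1L) {
    stop("atom ", name, " of residue ", resno, " not found")
  }
  as.numeric(row[1L, c("x", "y", "z")])
}
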
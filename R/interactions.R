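# Hydrogen-bond and salt-bridge detection.
#
# Criteria: an H-bond requires d(H...O) strictly below the distance
# cutoff (default 0.30 nm) and an angle at the hydrogen (donor-heavy -
# H ... acceptor) strictly above the angle cutoff (default 120 deg).
# A salt bridge is a charged-N ... carboxylate-O pair below 0.40 nm.

#' Enumerate hydrogen-bond donors of a frame
#'
#' Donor pairs are backbone amide N-H of residues 2-5 (excluding the
#' N-methylated MEG nitrogen, which has no amide hydrogen), the
#' N-terminal ammonium (up to three N-H), the arginine guanidinium
#' (Ne-He plus two H on each Nh) and the lysine ammonium (three Nz-H).
#' The cysteine thiol is excluded unless enabled in `config`.
#'
#' @param frame A [system_frame()].
#' @param config An [interaction_config()].
#' @return Data frame with one row per (donor-heavy, hydrogen) pair:
#'   `chain`, `resno`, `resid`, `heavy`, `h`, serial references, the
#'   functional `group` and a `mainchain` flag (backbone amide only).
#' @export
enumerate_donors <- function(frame, config = interaction_config()) {
  tabs <- lapply(chain_ids(frame), function(cid)
    donor_pairs(chain_atoms(frame, cid), cid, config))
  if (!length(tabs)) {
    return(donor_pairs(frame$atoms, "", config))   # typed empty table
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Enumerate hydrogen-bond acceptors of a frame
#'
#' Acceptors are the backbone carbonyl O of every residue (the
#' C-terminal residue contributing both carboxylate oxygens O and OXT),
#' and both side-chain carboxylate oxygens of Glu/MEG. With
#' `config$charged_carboxylates_only`, the oxygens of a protonated
#' (neutral) side-chain carboxylic acid are skipped.
#'
#' @inheritParams enumerate_donors
#' @return Data frame with one row per acceptor atom.
#' @export
enumerate_acceptors <- function(frame, config = interaction_config()) {
  tabs <- lapply(chain_ids(frame), function(cid)
    acceptor_atoms(chain_atoms(frame, cid), cid, config))
  if (!length(tabs)) {
    return(acceptor_atoms(frame$atoms, "", config))   # typed empty table
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

# minimum-image displacement for an orthorhombic box
min_image <- function(dxyz, box) {
  for (k in 1:3) {
    dxyz[, k] <- dxyz[, k] - box[k] * round(dxyz[, k] / box[k])
  }
  dxyz
}

serial_xyz <- function(frame, serials) {
  idx <- match(serials, frame$atoms$serial)
  if (anyNA(idx)) stop("internal error: unknown atom serial")
  as.matrix(frame$atoms[idx, c("x", "y", "z")])
}

#' Detect hydrogen bonds in a frame
#'
#' Returns exactly those (donor, hydrogen, acceptor) triples with
#' d(H...O) strictly below `d_cut` and donor-H-acceptor angle (vertex at
#' the hydrogen) strictly above `ang_cut`. Pairs within the same
#' functional unit are excluded (in particular an amide's own N-H with
#' its own C=O).
#'
#' @param frame A [system_frame()].
#' @param d_cut Distance cutoff, nm (default 0.30).
#' @param ang_cut Angle cutoff, degrees (default 120).
#' @param config An [interaction_config()].
#' @param method `"grid"` (cell lists, default) or `"exhaustive"`
#'   (all-pairs); both return identical bond sets.
#' @param pbc Apply the minimum-image convention (requires a box;
#'   forces the exhaustive path).
#' @return Data frame of class `"hbond_set"`, one row per bond, sorted
#'   canonically, with geometry (`d_HO` nm, `angle_DHA` degrees),
#'   chain/residue/atom identifiers, `donor_is_sidechain`,
#'   `acceptor_is_sidechain` and `intra` flags.
#' @export
detect_hbonds <- function(frame, d_cut = 0.30, ang_cut = 120,
                          config = interaction_config(),
                          method = c("grid", "exhaustive"),
                          pbc = FALSE) {
  if (!is.finite(d_cut) || d_cut <= 0 || !is.finite(ang_cut) ||
      ang_cut <= 0) {
    stop("parameter error: cutoffs must be positive")
  }
  method <- match.arg(method)
  if (pbc && is.null(frame$box)) stop("pbc requested but frame has no box")
  if (pbc) method <- "exhaustive"

  don <- enumerate_donors(frame, config)
  acc <- enumerate_acceptors(frame, config)
  empty <- hbond_empty()
  if (!nrow(don) || !nrow(acc)) return(empty)

  hxyz <- serial_xyz(frame, don$h_serial)
  dxyz <- serial_xyz(frame, don$heavy_serial)
  axyz <- serial_xyz(frame, acc$serial)

  cand <- if (method == "exhaustive") {
    all_pairs_within(hxyz, axyz, d_cut,
                     if (pbc) frame$box else NULL)
  } else {
    grid_pairs_within(hxyz, axyz, d_cut)
  }
  if (!nrow(cand)) return(empty)

  i <- cand$i   # donor index
  j <- cand$j   # acceptor index
  keep <- don$group[i] != acc$group[j]
  i <- i[keep]; j <- j[keep]; d <- cand$d[keep]
  if (!length(i)) return(empty)

  u <- dxyz[i, , drop = FALSE] - hxyz[i, , drop = FALSE]
  v <- axyz[j, , drop = FALSE] - hxyz[i, , drop = FALSE]
  if (pbc) v <- min_image(v, frame$box)
  cosang <- rowSums(u * v) /
    (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
  ang <- rad2deg(acos(pmax(-1, pmin(1, cosang))))
  keep <- ang > ang_cut
  i <- i[keep]; j <- j[keep]; d <- d[keep]; ang <- ang[keep]
  if (!length(i)) return(empty)

  out <- data.frame(
    donor_chain = don$chain[i], donor_resno = don$resno[i],
    donor_resid = don$resid[i], donor_heavy = don$heavy[i],
    hydrogen = don$h[i],
    acceptor_chain = acc$chain[j], acceptor_resno = acc$resno[j],
    acceptor_resid = acc$resid[j], acceptor_name = acc$name[j],
    d_HO = d, angle_DHA = ang,
    donor_is_sidechain = !don$mainchain[i],
    acceptor_is_sidechain = !acc$mainchain[j],
    intra = don$chain[i] == acc$chain[j],
    donor_serial = don$heavy_serial[i], h_serial = don$h_serial[i],
    acceptor_serial = acc$serial[j],
    stringsAsFactors = FALSE)
  ord <- order(out$donor_chain, out$donor_resno, out$hydrogen,
               out$acceptor_chain, out$acceptor_resno, out$acceptor_name)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_set", "data.frame")
  out
}

hbond_empty <- function() {
  out <- data.frame(
    donor_chain = character(), donor_resno = integer(),
    donor_resid = character(), donor_heavy = character(),
    hydrogen = character(), acceptor_chain = character(),
    acceptor_resno = integer(), acceptor_resid = character(),
    acceptor_name = character(), d_HO = numeric(),
    angle_DHA = numeric(), donor_is_sidechain = logical(),
    acceptor_is_sidechain = logical(), intra = logical(),
    donor_serial = integer(), h_serial = integer(),
    acceptor_serial = integer(), stringsAsFactors = FALSE)
  class(out) <- c("hbond_set", "data.frame")
  out
}

# all (i, j) with dist(hxyz[i,], axyz[j,]) < cut (strict)
all_pairs_within <- function(hxyz, axyz, cut, box = NULL) {
  nh <- nrow(hxyz)
  na <- nrow(axyz)
  i <- rep(seq_len(nh), times = na)
  j <- rep(seq_len(na), each = nh)
  dxyz <- axyz[j, , drop = FALSE] - hxyz[i, , drop = FALSE]
  if (!is.null(box)) dxyz <- min_image(dxyz, box)
  d <- sqrt(rowSums(dxyz * dxyz))
  keep <- d < cut
  data.frame(i = i[keep], j = j[keep], d = d[keep])
}

# cell-list neighbour search: same contract as all_pairs_within (no pbc)
grid_pairs_within <- function(hxyz, axyz, cut) {
  orig <- apply(rbind(hxyz, axyz), 2L, min) - cut
  key <- function(xyz) {
    ix <- floor((xyz[, 1L] - orig[1L]) / cut)
    iy <- floor((xyz[, 2L] - orig[2L]) / cut)
    iz <- floor((xyz[, 3L] - orig[3L]) / cut)
    list(ix = ix, iy = iy, iz = iz)
  }
  ak <- key(axyz)
  cell_of <- paste(ak$ix, ak$iy, ak$iz, sep = ",")
  cell_map <- split(seq_len(nrow(axyz)), cell_of)
  hk <- key(hxyz)
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (i in seq_len(nrow(hxyz))) {
    keys <- paste(hk$ix[i] + offs[, 1L], hk$iy[i] + offs[, 2L],
                  hk$iz[i] + offs[, 3L], sep = ",")
    cand <- unlist(cell_map[keys], use.names = FALSE)
    if (!length(cand)) next
    dxyz <- axyz[cand, , drop = FALSE] -
      matrix(hxyz[i, ], nrow = length(cand), ncol = 3L, byrow = TRUE)
    d <- sqrt(rowSums(dxyz * dxyz))
    keep <- d < cut
    if (any(keep)) {
      res_i <- c(res_i, rep.int(i, sum(keep)))
      res_j <- c(res_j, cand[keep])
      res_d <- c(res_d, d[keep])
    }
  }
  data.frame(i = res_i, j = res_j, d = res_d)
}

#' Detect salt bridges in a frame
#'
#' A salt bridge is a pair of a positively charged nitrogen (arginine
#' guanidinium Ne/Nh1/Nh2, lysine Nz, protonated N-terminal N) and a
#' carboxylate oxygen (deprotonated Glu/MEG side chain, C-terminal
#' carboxylate) at heavy-atom N...O distance strictly below `cut`.
#' Pairs are deduplicated to one record per residue pair, keeping the
#' minimum distance.
#'
#' @param frame A [system_frame()].
#' @param cut Heavy-atom N...O cutoff, nm (default 0.40).
#' @param config An [interaction_config()].
#' @return Data frame of class `"salt_bridge_set"`: cation and anion
#'   chain/residue/atom, distance `d` (nm), `same_chain` flag.
#' @export
detect_salt_bridges <- function(frame, cut = 0.40,
                                config = interaction_config()) {
  cats <- list(); ans <- list()
  for (cid in chain_ids(frame)) {
    at <- chain_atoms(frame, cid)
    codes <- chain_codes(at)
    grab <- function(resno, names_) {
      rows <- at[at$resno == resno & at$name %in% names_, , drop = FALSE]
      if (!nrow(rows)) return(NULL)
      data.frame(chain = cid, resno = resno, resid = codes[resno],
                 name = rows$name, serial = rows$serial,
                 x = rows$x, y = rows$y, z = rows$z,
                 stringsAsFactors = FALSE)
    }
    # N-terminal ammonium (protonated if it carries any H1/H2/H3)
    if (any(at$resno == 1L & at$name %in% c("H1", "H2", "H3"))) {
      cats[[length(cats) + 1L]] <- grab(1L, "N")
    }
    for (i in seq_along(codes)) {
      if (codes[i] == "ARG") {
        cats[[length(cats) + 1L]] <- grab(i, c("NE", "NH1", "NH2"))
      }
      if (codes[i] == "LYS") cats[[length(cats) + 1L]] <- grab(i, "NZ")
      if (codes[i] %in% c("GLU", "MEG") &&
          !carboxylate_protonated(at, i)) {
        ans[[length(ans) + 1L]] <- grab(i, c("OE1", "OE2"))
      }
    }
    # C-terminal carboxylate (deprotonated unless it carries HXT)
    n_res <- length(codes)
    if (!any(at$resno == n_res & at$name == "HXT")) {
      ans[[length(ans) + 1L]] <- grab(n_res, c("O", "OXT"))
    }
  }
  empty <- data.frame(
    cation_chain = character(), cation_resno = integer(),
    cation_atom = character(), anion_chain = character(),
    anion_resno = integer(), anion_atom = character(),
    d = numeric(), same_chain = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("salt_bridge_set", "data.frame")
  if (!length(cats) || !length(ans)) return(empty)
  cat_df <- do.call(rbind, cats)
  an_df <- do.call(rbind, ans)
  nc <- nrow(cat_df); na <- nrow(an_df)
  i <- rep(seq_len(nc), times = na)
  j <- rep(seq_len(na), each = nc)
  dxyz <- as.matrix(an_df[j, c("x", "y", "z")]) -
    as.matrix(cat_df[i, c("x", "y", "z")])
  d <- sqrt(rowSums(dxyz * dxyz))
  keep <- d < cut
  if (!any(keep)) return(empty)
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  out <- data.frame(
    cation_chain = cat_df$chain[i], cation_resno = cat_df$resno[i],
    cation_atom = cat_df$name[i],
    anion_chain = an_df$chain[j], anion_resno = an_df$resno[j],
    anion_atom = an_df$name[j], d = d,
    same_chain = cat_df$chain[i] == an_df$chain[j],
    stringsAsFactors = FALSE)
  # one record per residue pair, minimum distance kept
  pair_key <- paste(out$cation_chain, out$cation_resno,
                    out$anion_chain, out$anion_resno)
  out <- do.call(rbind, lapply(split(out, pair_key),
                               function(g) g[which.min(g$d), ]))
  out <- out[order(out$cation_chain, out$cation_resno,
                   out$anion_chain, out$anion_resno), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("salt_bridge_set", "data.frame")
  out
}

#' Export a bond list as TSV
#'
#' One row per hydrogen bond with chain/residue/atom identifiers,
#' distance in nm (4 decimals) and angle in degrees (2 decimals).
#'
#' @param hbonds An `"hbond_set"` from [detect_hbonds()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_hbonds_tsv <- function(hbonds, path) {
  df <- as.data.frame(hbonds)
  if (nrow(df)) {
    df$d_HO <- sprintf("%.4f", df$d_HO)
    df$angle_DHA <- sprintf("%.2f", df$angle_DHA)
  }
  df$donor_serial <- df$h_serial <- df$acceptor_serial <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
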
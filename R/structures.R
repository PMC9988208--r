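# Domain model for pentapeptide systems: frames, trajectories, PDB-dialect
# multi-model I/O, backbone dihedrals and Ramachandran-region labels.
#
# Internal length unit is nm; PDB files are in angstrom and converted on
# read/write.

#' Construct a system frame
#'
#' A frame is one structural snapshot: an atom table plus an optional
#' orthorhombic box. The atom table has one row per atom with columns
#' `serial`, `name`, `element`, `chain`, `resno` (1-5 within chain),
#' `resid` (three-letter code, `MEG` = N-methyl-glutamate) and `x`, `y`,
#' `z` in nm.
#'
#' @param atoms Atom data frame as described above.
#' @param frame_index Non-negative integer frame index.
#' @param box Optional numeric 3-vector of box lengths (nm), all > 0.
#' @param validate Check sequence and N-methylation topology.
#' @return An object of class `"system_frame"`.
#' @export
system_frame <- function(atoms, frame_index = 0L, box = NULL,
                         validate = TRUE) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "chain", "resno", "resid",
            "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(!nzchar(atoms$element))) stop("empty element symbol")
  if (!is.null(box)) {
    stopifnot(length(box) == 3L)
    if (any(!is.finite(box)) || any(box <= 0)) {
      stop("box components must be positive")
    }
  }
  fr <- structure(list(atoms = atoms, frame_index = as.integer(frame_index),
                       box = box),
                  class = "system_frame")
  if (validate) validate_frame(fr)
  fr
}

#' @export
print.system_frame <- function(x, ...) {
  cat(sprintf("<system_frame> %d chains, %d atoms%s\n",
              length(chain_ids(x)), nrow(x$atoms),
              if (is.null(x$box)) "" else
                sprintf(", box %.2f x %.2f x %.2f nm",
                        x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

# Sequence / topology validation shared by the reader and the builders.
validate_frame <- function(frame, strict_h = FALSE) {
  ids <- chain_ids(frame)
  if (anyDuplicated(ids)) stop("duplicate chain identifiers")
  for (cid in ids) {
    at <- chain_atoms(frame, cid)
    codes <- chain_codes(at)
    seqname <- match_sequence(codes)
    if (is.na(seqname)) {
      stop("topology error: chain ", cid, " has residue sequence ",
           paste(codes, collapse = "-"),
           " which matches no registered pentapeptide")
    }
    for (i in seq_along(codes)) {
      n_h <- sum(at$resno == i & at$name == "H")
      has_cn <- any(at$resno == i & at$name == "CN")
      if (codes[i] == "MEG") {
        if (n_h > 0L) {
          stop("topology error: chain ", cid, " residue ", i,
               " (MEG) carries an amide hydrogen")
        }
        if (!has_cn) {
          stop("topology error: chain ", cid, " residue ", i,
               " (MEG) lacks the N-methyl carbon CN")
        }
      } else if (strict_h && i > 1L && n_h != 1L) {
        stop("missing-hydrogen error: chain ", cid, " residue ", i,
             " backbone N has no amide hydrogen")
      }
      if (strict_h && i == 1L &&
          !any(at$resno == 1L & at$name %in% c("H1", "H2", "H3"))) {
        stop("missing-hydrogen error: chain ", cid,
             " N-terminal nitrogen has no attached hydrogen")
      }
    }
  }
  invisible(frame)
}

#' Construct a trajectory
#'
#' An ordered list of frames sharing chain topology (same chain ids and
#' residue sequences in every frame).
#'
#' @param frames List of [system_frame()] objects.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  ref <- frames[[1L]]
  ref_ids <- chain_ids(ref)
  ref_seq <- lapply(ref_ids, function(cid)
    chain_codes(chain_atoms(ref, cid)))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!inherits(fr, "system_frame")) stop("frames must be system_frame")
    ids <- chain_ids(fr)
    if (!identical(ids, ref_ids)) {
      stop("frame ", k, " has different chain identifiers")
    }
    sq <- lapply(ids, function(cid) chain_codes(chain_atoms(fr, cid)))
    if (!identical(sq, ref_seq)) {
      stop("frame ", k, " has different residue sequences")
    }
  }
  structure(list(frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frame(s), %d chain(s)\n",
              length(x$frames), length(chain_ids(x$frames[[1L]]))))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

as_trajectory <- function(x) {
  if (inherits(x, "trajectory")) return(x)
  if (inherits(x, "system_frame")) return(trajectory(list(x)))
  stop("expected a system_frame or trajectory")
}

## ---------------------------------------------------------------- PDB I/O

#' Read a (multi-model) PDB structure file
#'
#' Parses the fixed-width PDB 3.3 layout. Models delimited by
#' MODEL/ENDMDL become trajectory frames; a file without MODEL records is
#' a single frame. Coordinates are converted from angstrom to nm, chains
#' are validated against the registered pentapeptide sequences, and
#' N-methyl-glutamate is recognised by residue name (`MEG` plus the
#' aliases in `config$meg_aliases`).
#'
#' @param path Path to a PDB-dialect text file.
#' @param strict_h Require an amide hydrogen on every non-MEG backbone
#'   nitrogen (and at least one H on the N-terminal nitrogen); when
#'   `FALSE`, missing amide hydrogens are reconstructed from the local
#'   N, CA, C(-1) geometry.
#' @param config An [interaction_config()] (for residue-name aliases).
#' @return A [trajectory()].
#' @export
read_structure <- function(path, strict_h = TRUE,
                           config = interaction_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  box <- NULL
  frames <- list()
  cur <- NULL   # list of atom-row lists
  in_model <- FALSE
  seen_model <- FALSE

  flush_frame <- function(cur, idx) {
    if (!length(cur)) stop("format error: empty model in ", path)
    atoms <- do.call(rbind, lapply(cur, as.data.frame,
                                   stringsAsFactors = FALSE))
    build_frame_from_records(atoms, idx, box, strict_h, config)
  }

  num <- function(s, ln, what) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) {
      stop("format error at line ", ln, ": unreadable ", what,
           " field '", trimws(s), "'")
    }
    v
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- substr(line, 1L, 6L)
    if (startsWith(rec, "CRYST1")) {
      box <- c(num(substr(line, 7, 15), ln, "box a"),
               num(substr(line, 16, 24), ln, "box b"),
               num(substr(line, 25, 33), ln, "box c")) / 10
    } else if (startsWith(rec, "MODEL")) {
      if (in_model) stop("format error at line ", ln, ": nested MODEL")
      in_model <- TRUE
      seen_model <- TRUE
      cur <- list()
    } else if (startsWith(rec, "ENDMDL")) {
      if (!in_model) stop("format error at line ", ln, ": stray ENDMDL")
      frames[[length(frames) + 1L]] <- flush_frame(cur, length(frames))
      cur <- NULL
      in_model <- FALSE
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (is.null(cur)) cur <- list()
      if (nchar(line) < 54L) {
        stop("format error at line ", ln, ": truncated coordinate record")
      }
      resid <- toupper(trimws(substr(line, 18, 20)))
      if (resid %in% config$meg_aliases) resid <- "MEG"
      name <- trimws(substr(line, 13, 16))
      el <- trimws(substr(line, 77, 78))
      if (!nzchar(el)) el <- element_from_name(name)
      cur[[length(cur) + 1L]] <- list(
        serial = as.integer(num(substr(line, 7, 11), ln, "serial")),
        name = name,
        element = el,
        chain = substr(line, 22, 22),
        file_resno = as.integer(num(substr(line, 23, 26), ln,
                                    "residue number")),
        resid = resid,
        x = num(substr(line, 31, 38), ln, "x") / 10,
        y = num(substr(line, 39, 46), ln, "y") / 10,
        z = num(substr(line, 47, 54), ln, "z") / 10)
    }
  }
  if (in_model) stop("format error: MODEL without ENDMDL in ", path)
  if (!seen_model) {
    if (is.null(cur) || !length(cur)) {
      stop("format error: no coordinate records in ", path)
    }
    frames[[1L]] <- flush_frame(cur, 0L)
  }
  if (!length(frames)) stop("format error: no models in ", path)
  trajectory(frames)
}

# normalise residue numbering to 1..n per chain, validate, reconstruct
# missing amide H when strict_h is FALSE
build_frame_from_records <- function(atoms, frame_index, box, strict_h,
                                     config) {
  atoms$resno <- NA_integer_
  for (cid in unique(atoms$chain)) {
    sel <- atoms$chain == cid
    rn <- atoms$file_resno[sel]
    atoms$resno[sel] <- as.integer(match(rn, unique(rn)))
  }
  atoms$file_resno <- NULL
  atoms <- atoms[, c("serial", "name", "element", "chain", "resno",
                     "resid", "x", "y", "z")]
  fr <- system_frame(atoms, frame_index = frame_index, box = box,
                     validate = FALSE)
  if (!strict_h) fr <- reconstruct_amide_h(fr)
  validate_frame(fr, strict_h = TRUE)
  fr
}

# Rebuild missing backbone amide hydrogens (residues 2..5, non-MEG) from
# the C(i-1), N(i), CA(i) geometry: H in the amide plane, anti to C(i-1)
# bisecting externally.
reconstruct_amide_h <- function(frame) {
  at <- frame$atoms
  for (cid in chain_ids(frame)) {
    ca <- chain_atoms(frame, cid)
    codes <- chain_codes(ca)
    for (i in seq_along(codes)) {
      if (i == 1L || codes[i] == "MEG") next
      if (any(ca$resno == i & ca$name == "H")) next
      g <- function(r, nm) {
        row <- ca[ca$resno == r & ca$name == nm, ]
        if (nrow(row) != 1L) {
          stop("topology error: chain ", cid, " residue ", r,
               " lacks backbone atom ", nm)
        }
        as.numeric(row[1L, c("x", "y", "z")])
      }
      n <- g(i, "N"); caa <- g(i, "CA"); cprev <- g(i - 1L, "C")
      u <- -(vec_unit(caa - n) + vec_unit(cprev - n))
      h <- n + 0.101 * vec_unit(u)
      at <- rbind(at, data.frame(
        serial = max(at$serial) + 1L, name = "H", element = "H",
        chain = cid, resno = i, resid = codes[i],
        x = h[1L], y = h[2L], z = h[3L], stringsAsFactors = FALSE))
    }
  }
  ord <- order(match(at$chain, chain_ids(frame)), at$resno)
  at <- at[ord, , drop = FALSE]
  rownames(at) <- NULL
  system_frame(at, frame$frame_index, frame$box, validate = FALSE)
}

#' Write a trajectory to a (multi-model) PDB file
#'
#' Fixed-width PDB 3.3 columns, coordinates in angstrom, MODEL/ENDMDL
#' records for multi-frame trajectories, TER after each chain. Output is
#' deterministic for a fixed input.
#'
#' @param traj A [trajectory()] or single [system_frame()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(traj, path) {
  traj <- as_trajectory(traj)
  if (!length(traj$frames)) stop("empty trajectory")
  con <- file(path, open = "wt")
  on.exit(close(con))
  multi <- length(traj$frames) > 1L
  box <- traj$frames[[1L]]$box
  if (!is.null(box)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90), con)
  }
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    serial <- 0L
    for (cid in chain_ids(fr)) {
      at <- chain_atoms(fr, cid)
      for (j in seq_len(nrow(at))) {
        serial <- serial + 1L
        nm <- at$name[j]
        nmf <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
        writeLines(sprintf(
          "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nmf, at$resid[j], cid, at$resno[j],
          at$x[j] * 10, at$y[j] * 10, at$z[j] * 10, 1, 0,
          at$element[j]), con)
      }
      serial <- serial + 1L
      writeLines(sprintf("TER   %5d %3s %3s %1s%4d",
                         serial, "", at$resid[nrow(at)], cid,
                         at$resno[nrow(at)]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ------------------------------------------------- dihedrals & conformation

backbone_xyz <- function(atoms, resno, name) {
  row <- atoms[atoms$resno == resno & atoms$name == name, ]
  if (nrow(row) != 1L) {
    stop("topology error: residue ", resno, " lacks backbone atom ", name)
  }
  as.numeric(row[1L, c("x", "y", "z")])
}

#' Backbone phi/psi dihedrals of one chain
#'
#' @param frame A [system_frame()].
#' @param chain Chain identifier; defaults to the only chain present.
#' @return Data frame with columns `resno`, `phi`, `psi` (degrees in
#'   `(-180, 180]`); `phi` is `NA` for residue 1 and `psi` is `NA` for
#'   the last residue.
#' @export
backbone_dihedrals <- function(frame, chain = NULL) {
  if (is.null(chain)) {
    ids <- chain_ids(frame)
    if (length(ids) != 1L) stop("specify `chain` for a multi-chain frame")
    chain <- ids
  }
  at <- chain_atoms(frame, chain)
  n_res <- max(at$resno)
  phi <- psi <- rep(NA_real_, n_res)
  g <- function(r, nm) backbone_xyz(at, r, nm)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      phi[i] <- dihedral_angle(g(i - 1L, "C"), g(i, "N"),
                               g(i, "CA"), g(i, "C"))
    }
    if (i < n_res) {
      psi[i] <- dihedral_angle(g(i, "N"), g(i, "CA"),
                               g(i, "C"), g(i + 1L, "N"))
    }
  }
  data.frame(resno = seq_len(n_res), phi = phi, psi = psi)
}

#' Ramachandran region boundaries
#'
#' Default regions used to label residue conformations: a beta-strand
#' region and a turn/helical region, mutually exclusive. Both are
#' configurable; these defaults are the package's own choice of
#' conventional Ramachandran boundaries.
#'
#' @param beta_phi,turn_phi Numeric `c(min, max)` phi bounds (degrees).
#' @param beta_psi_ranges List of `c(min, max)` psi intervals for the
#'   beta region (the default wraps across +/-180).
#' @param turn_psi Numeric `c(min, max)` psi bounds for the turn region.
#' @return List with class `"conformation_regions"`.
#' @export
conformation_regions <- function(beta_phi = c(-180, -90),
                                 beta_psi_ranges = list(c(90, 180),
                                                        c(-180, -170)),
                                 turn_phi = c(-120, -30),
                                 turn_psi = c(-80, 30)) {
  structure(list(beta_phi = beta_phi, beta_psi_ranges = beta_psi_ranges,
                 turn_phi = turn_phi, turn_psi = turn_psi),
            class = "conformation_regions")
}

in_range <- function(x, r) x >= r[1L] & x <= r[2L]

#' Assign a conformation label to (phi, psi)
#'
#' Labels are `"BETA"` if the point lies in the configured beta-strand
#' region, `"TURN_REGION"` in the turn/helical region, `"OTHER"`
#' elsewhere and `"UNDEFINED"` when either angle is `NA` (chain
#' termini). Vectorised over `phi`/`psi`.
#'
#' @param phi,psi Dihedrals in degrees.
#' @param regions A [conformation_regions()] object.
#' @return Character vector of labels.
#' @export
assign_conformation <- function(phi, psi,
                                regions = conformation_regions()) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  out <- rep("OTHER", n)
  undef <- is.na(phi) | is.na(psi)
  beta_psi <- Reduce(`|`, lapply(regions$beta_psi_ranges,
                                 function(r) in_range(psi, r)),
                     accumulate = FALSE)
  beta <- !undef & in_range(phi, regions$beta_phi) & beta_psi
  turn <- !undef & in_range(phi, regions$turn_phi) &
    in_range(psi, regions$turn_psi) & !beta
  out[beta] <- "BETA"
  out[turn] <- "TURN_REGION"
  out[undef] <- "UNDEFINED"
  out
}

# Per-residue labels for every chain of a frame, with terminal residues
# (UNDEFINED: one dihedral missing) inheriting the adjacent interior
# residue's label, so that an ideal strand is beta along its full length.
# This matches the chain-level reading of "chains adopting beta-strand
# conformations" used in the pattern classification.
frame_conformations <- function(frame, regions = conformation_regions()) {
  out <- list()
  for (cid in chain_ids(frame)) {
    dh <- backbone_dihedrals(frame, cid)
    lab <- assign_conformation(dh$phi, dh$psi, regions)
    n <- length(lab)
    if (n >= 2L && lab[1L] == "UNDEFINED") lab[1L] <- lab[2L]
    if (n >= 2L && lab[n] == "UNDEFINED") lab[n] <- lab[n - 1L]
    out[[cid]] <- lab
  }
  out
}
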
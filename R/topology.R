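# Residue chemistry: admissible sequences, donor/acceptor chemistry tables,
# and protonation-state introspection from the atoms actually present.
#
# Only polar hydrogens are modelled. The N-methyl-glutamate residue (code
# MEG) carries a CN methyl carbon on the backbone nitrogen instead of an
# amide hydrogen; its side chain is identical to Glu.

.pep_env <- new.env(parent = emptyenv())
.pep_env$sequences <- list(
  CREKA  = c("CYS", "ARG", "GLU", "LYS", "ALA"),
  CRENKA = c("CYS", "ARG", "MEG", "LYS", "ALA")
)

#' Register an admissible peptide sequence
#'
#' The package validates every chain against a registry of admissible
#' 5-residue sequences; CREKA and CRENKA (the N-methylated variant, with
#' residue code MEG at position 3) are pre-registered.
#'
#' @param name Sequence label, e.g. `"CREKA"`.
#' @param codes Character vector of three-letter residue codes.
#' @return Invisibly, the registry.
#' @export
register_peptide_sequence <- function(name, codes) {
  stopifnot(is.character(name), length(name) == 1L, is.character(codes))
  .pep_env$sequences[[name]] <- toupper(codes)
  invisible(.pep_env$sequences)
}

known_sequences <- function() .pep_env$sequences

sequence_codes <- function(sequence) {
  seqs <- known_sequences()
  if (!sequence %in% names(seqs)) {
    stop("unknown sequence '", sequence, "'; registered: ",
         paste(names(seqs), collapse = ", "))
  }
  seqs[[sequence]]
}

# match a vector of residue codes against the registry; NA if none matches
match_sequence <- function(codes) {
  seqs <- known_sequences()
  for (nm in names(seqs)) {
    if (length(codes) == length(seqs[[nm]]) && all(codes == seqs[[nm]])) {
      return(nm)
    }
  }
  NA_character_
}

#' Interaction chemistry configuration
#'
#' Explicit donor/acceptor chemistry table used by [enumerate_donors()],
#' [enumerate_acceptors()] and [detect_hbonds()]. Defaults follow the
#' N-H donor / O acceptor criterion: the cysteine thiol is neither donor
#' nor acceptor, and the O-H of a protonated carboxylic acid is not a
#' donor while its oxygens remain acceptors.
#'
#' @param include_cys_thiol Logical; treat Cys S-H as donor and S as
#'   acceptor. Default `FALSE`.
#' @param charged_carboxylates_only Logical; if `TRUE`, the oxygens of a
#'   protonated (neutral) carboxylic acid are not counted as acceptors.
#'   Default `FALSE`.
#' @param meg_aliases Residue names accepted for N-methyl-glutamate when
#'   reading structure files; stored canonically as `"MEG"`.
#' @return A list with class `"interaction_config"`.
#' @export
interaction_config <- function(include_cys_thiol = FALSE,
                               charged_carboxylates_only = FALSE,
                               meg_aliases = c("MEG", "NGL")) {
  structure(list(include_cys_thiol = include_cys_thiol,
                 charged_carboxylates_only = charged_carboxylates_only,
                 meg_aliases = toupper(meg_aliases)),
            class = "interaction_config")
}

# side-chain heavy-atom names per residue (excluding backbone N, CA, C, O)
SIDECHAIN_ATOMS <- list(
  CYS = c("CB", "SG", "HG"),
  ARG = c("CB", "CG", "CD", "NE", "HE", "CZ",
          "NH1", "HH11", "HH12", "NH2", "HH21", "HH22"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2", "HE2"),
  MEG = c("CB", "CG", "CD", "OE1", "OE2", "HE2", "CN"),
  LYS = c("CB", "CG", "CD", "CE", "NZ", "HZ1", "HZ2", "HZ3"),
  ALA = c("CB")
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "H", "H1", "H2", "H3", "OXT", "HXT")

# Atoms of one chain, ordered by (resno, insertion order).
chain_atoms <- function(frame, chain_id) {
  frame$atoms[frame$atoms$chain == chain_id, , drop = FALSE]
}

chain_ids <- function(frame) unique(frame$atoms$chain)

# residue codes of one chain in residue order
chain_codes <- function(atoms) {
  idx <- !duplicated(atoms$resno)
  atoms$resid[idx][order(atoms$resno[idx])]
}

# TRUE if the Glu/MEG side carboxylate of (chain, resno) is protonated
carboxylate_protonated <- function(atoms, resno) {
  any(atoms$resno == resno & atoms$name == "HE2")
}

# Donor table: one row per (heavy, H) pair.
# group column identifies the functional unit, used both to exclude
# H-bonds within one amide unit and to classify bonds; the amide unit k
# couples C=O of residue k with N-H of residue k+1.
donor_pairs <- function(atoms, chain_id, config = interaction_config()) {
  out <- list()
  add <- function(resno, resid, heavy, h, group, mainchain) {
    hi <- which(atoms$resno == resno & atoms$name == heavy)
    xi <- which(atoms$resno == resno & atoms$name == h)
    if (length(hi) != 1L || length(xi) != 1L) return(NULL)
    list(chain = chain_id, resno = resno, resid = resid,
         heavy = heavy, h = h,
         heavy_serial = atoms$serial[hi], h_serial = atoms$serial[xi],
         group = group, mainchain = mainchain)
  }
  codes <- chain_codes(atoms)
  for (i in seq_along(codes)) {
    code <- codes[i]
    if (i == 1L) {
      # N-terminal ammonium: up to three H on the backbone N
      for (h in c("H1", "H2", "H3")) {
        out[[length(out) + 1L]] <-
          add(i, code, "N", h, paste0(chain_id, ":nterm"), FALSE)
      }
    } else if (code != "MEG") {
      out[[length(out) + 1L]] <-
        add(i, code, "N", "H", paste0(chain_id, ":amide:", i - 1L), TRUE)
    }
    if (code == "ARG") {
      for (p in list(c("NE", "HE"), c("NH1", "HH11"), c("NH1", "HH12"),
                     c("NH2", "HH21"), c("NH2", "HH22"))) {
        out[[length(out) + 1L]] <-
          add(i, code, p[1L], p[2L], paste0(chain_id, ":arg:", i), FALSE)
      }
    }
    if (code == "LYS") {
      for (h in c("HZ1", "HZ2", "HZ3")) {
        out[[length(out) + 1L]] <-
          add(i, code, "NZ", h, paste0(chain_id, ":lys:", i), FALSE)
      }
    }
    if (code == "CYS" && isTRUE(config$include_cys_thiol)) {
      out[[length(out) + 1L]] <-
        add(i, code, "SG", "HG", paste0(chain_id, ":cys:", i), FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) {
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), heavy = character(),
                      h = character(), heavy_serial = integer(),
                      h_serial = integer(), group = character(),
                      mainchain = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
}

# Acceptor table: one row per oxygen (or thiol sulfur when enabled).
acceptor_atoms <- function(atoms, chain_id, config = interaction_config()) {
  out <- list()
  add <- function(resno, resid, name, group, mainchain) {
    xi <- which(atoms$resno == resno & atoms$name == name)
    if (length(xi) != 1L) return(NULL)
    list(chain = chain_id, resno = resno, resid = resid, name = name,
         serial = atoms$serial[xi], group = group, mainchain = mainchain)
  }
  codes <- chain_codes(atoms)
  n_res <- length(codes)
  for (i in seq_along(codes)) {
    code <- codes[i]
    if (i < n_res) {
      out[[length(out) + 1L]] <-
        add(i, code, "O", paste0(chain_id, ":amide:", i), TRUE)
    } else {
      # C-terminal carboxylate: both oxygens, terminal (non-amide) group
      for (nm in c("O", "OXT")) {
        out[[length(out) + 1L]] <-
          add(i, code, nm, paste0(chain_id, ":cterm"), FALSE)
      }
    }
    if (code %in% c("GLU", "MEG")) {
      skip <- isTRUE(config$charged_carboxylates_only) &&
        carboxylate_protonated(atoms, i)
      if (!skip) {
        for (nm in c("OE1", "OE2")) {
          out[[length(out) + 1L]] <-
            add(i, code, nm, paste0(chain_id, ":glu:", i), FALSE)
        }
      }
    }
    if (code == "CYS" && isTRUE(config$include_cys_thiol)) {
      out[[length(out) + 1L]] <-
        add(i, code, "SG", paste0(chain_id, ":cys:", i), FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) {
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), name = character(),
                      serial = integer(), group = character(),
                      mainchain = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
}

# element symbol inferred from a PDB atom name (peptide atoms only)
element_from_name <- function(name) {
  first <- substr(gsub("[0-9]", "", name), 1L, 1L)
  ifelse(first %in% c("C", "N", "O", "S", "H"), first, first)
}
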
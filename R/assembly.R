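# Aggregate detection, seven-way hydrogen-bond pattern classification,
# strand-pair orientation, and aggregate-size-stratified statistics.

#' The seven hydrogen-bond pattern categories
#'
#' Intramolecular: `BETA_TURN` (backbone bond donated by residue i+3 to
#' the carbonyl of residue i), `GAMMA_TURN` (i+2 to i),
#' `OTHER_INTRA_MAIN` (other main-chain amide pairs), `INTRA_SIDE` (a
#' side-chain or terminal group involved). Intermolecular: `BETA_SHEET`
#' (main-chain amide pairs with both residues in beta-strand
#' conformation), `MAIN_MAIN` (main-chain amide pairs without defined
#' beta conformation), `INTER_SIDE` (a side-chain or terminal group
#' involved).
#'
#' @export
HBOND_CATEGORIES <- c("BETA_TURN", "GAMMA_TURN", "OTHER_INTRA_MAIN",
                      "INTRA_SIDE", "BETA_SHEET", "MAIN_MAIN",
                      "INTER_SIDE")

#' Partition the chains of a frame into aggregates
#'
#' Two chains are in contact when they share at least one
#' intermolecular hydrogen bond or salt bridge, or any intermolecular
#' heavy-atom pair closer than `contact_cut`. Aggregates are the
#' connected components of the resulting chain-contact graph; a chain
#' in no contact forms an aggregate of size 1 (a free chain, not part
#' of any assembly).
#'
#' @param frame A [system_frame()].
#' @param contact_cut Heavy-atom contact cutoff, nm (default 0.45).
#' @param use_hbonds,use_salt_bridges Include bond-mediated links.
#' @param hbonds,salt_bridges Optional precomputed bond sets (to avoid
#'   recomputation inside [pattern_statistics()]).
#' @param config An [interaction_config()].
#' @return List of aggregates, each a `list(chain_ids, size)`, sorted
#'   by decreasing size; the chain-to-aggregate index is attached as
#'   attribute `"membership"` (named integer vector).
#' @export
find_aggregates <- function(frame, contact_cut = 0.45,
                            use_hbonds = TRUE, use_salt_bridges = TRUE,
                            hbonds = NULL, salt_bridges = NULL,
                            config = interaction_config()) {
  ids <- chain_ids(frame)
  edges <- matrix(character(0), ncol = 2L)
  # heavy-atom proximity
  heavy <- frame$atoms[frame$atoms$element != "H", , drop = FALSE]
  if (length(ids) > 1L) {
    xyz <- as.matrix(heavy[, c("x", "y", "z")])
    for (a in seq_along(ids)[-length(ids)]) {
      xa <- xyz[heavy$chain == ids[a], , drop = FALSE]
      for (b in (a + 1L):length(ids)) {
        xb <- xyz[heavy$chain == ids[b], , drop = FALSE]
        d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
          outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
        if (min(d2) < contact_cut^2) {
          edges <- rbind(edges, c(ids[a], ids[b]))
        }
      }
    }
  }
  if (use_hbonds) {
    if (is.null(hbonds)) hbonds <- detect_hbonds(frame, config = config)
    inter <- hbonds[!hbonds$intra, , drop = FALSE]
    if (nrow(inter)) {
      edges <- rbind(edges,
                     cbind(inter$donor_chain, inter$acceptor_chain))
    }
  }
  if (use_salt_bridges) {
    if (is.null(salt_bridges)) {
      salt_bridges <- detect_salt_bridges(frame, config = config)
    }
    sb <- salt_bridges[!salt_bridges$same_chain, , drop = FALSE]
    if (nrow(sb)) {
      edges <- rbind(edges, cbind(sb$cation_chain, sb$anion_chain))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  membership <- setNames(as.integer(comp$membership), ids)
  aggs <- lapply(seq_len(comp$no), function(k) {
    members <- ids[membership == k]
    list(chain_ids = members, size = length(members))
  })
  sizes <- vapply(aggs, `[[`, integer(1L), "size")
  ord <- order(-sizes, vapply(aggs, function(a) a$chain_ids[1L],
                              character(1L)))
  aggs <- aggs[ord]
  attr(aggs, "membership") <- membership
  class(aggs) <- "aggregate_set"
  aggs
}

#' @export
print.aggregate_set <- function(x, ...) {
  sizes <- vapply(x, `[[`, integer(1L), "size")
  cat(sprintf("<aggregate_set> %d aggregate(s); sizes: %s\n",
              length(x), paste(sizes, collapse = " ")))
  invisible(x)
}

# sizes of the aggregate each chain belongs to, named by chain
aggregate_size_by_chain <- function(aggs) {
  out <- integer(0)
  for (a in aggs) {
    out[a$chain_ids] <- a$size
  }
  out
}

#' Classify a hydrogen bond into one of the seven pattern categories
#'
#' Decision rules: an intramolecular bond with a side-chain or terminal
#' partner is `INTRA_SIDE`; an intramolecular main-chain bond whose
#' donor residue sits `i+3` (resp. `i+2`) after the acceptor residue is
#' `BETA_TURN` (resp. `GAMMA_TURN`), otherwise `OTHER_INTRA_MAIN`. An
#' intermolecular bond with a side-chain or terminal partner is
#' `INTER_SIDE`; an intermolecular main-chain bond is `BETA_SHEET` when
#' both partner residues are labelled `BETA`, else `MAIN_MAIN`.
#'
#' @param hb One row of an `"hbond_set"` (or a list with the same
#'   fields).
#' @param conformations Named list (by chain) of per-residue
#'   conformation labels, as from `frame_conformations()`.
#' @param same_aggregate Are donor and acceptor chains in the same
#'   aggregate? (Always true for intramolecular bonds; a contradiction
#'   raises a consistency error.)
#' @return One of [HBOND_CATEGORIES].
#' @export
classify_hbond <- function(hb, conformations, same_aggregate = TRUE) {
  intra <- hb$donor_chain == hb$acceptor_chain
  if (intra && !same_aggregate) {
    stop("consistency error: intramolecular bond with donor and ",
         "acceptor in different aggregates")
  }
  side <- hb$donor_is_sidechain || hb$acceptor_is_sidechain
  if (intra) {
    if (side) return("INTRA_SIDE")
    diff <- hb$donor_resno - hb$acceptor_resno
    if (diff == 3L) return("BETA_TURN")
    if (diff == 2L) return("GAMMA_TURN")
    return("OTHER_INTRA_MAIN")
  }
  if (side) return("INTER_SIDE")
  don_lab <- conformations[[hb$donor_chain]][hb$donor_resno]
  acc_lab <- conformations[[hb$acceptor_chain]][hb$acceptor_resno]
  if (identical(don_lab, "BETA") && identical(acc_lab, "BETA")) {
    return("BETA_SHEET")
  }
  "MAIN_MAIN"
}

# vectorised classification of a whole bond set
classify_hbond_set <- function(hbonds, conformations) {
  vapply(seq_len(nrow(hbonds)), function(i)
    classify_hbond(hbonds[i, , drop = FALSE], conformations),
    character(1L))
}

#' Orientation of a hydrogen-bonded strand pair
#'
#' `PARALLEL` when the Calpha(1) to Calpha(5) end-to-end vectors of the
#' two chains have a positive dot product, else `ANTIPARALLEL`. When a
#' bond set is supplied, the pair must share at least one
#' inter-main-chain hydrogen bond (orientation is only defined for
#' bonded strand pairs).
#'
#' @param frame A [system_frame()].
#' @param chain_i,chain_j Chain identifiers.
#' @param hbonds Optional `"hbond_set"` used to enforce the
#'   shared-bond precondition.
#' @return `"PARALLEL"` or `"ANTIPARALLEL"`.
#' @export
strand_orientation <- function(frame, chain_i, chain_j, hbonds = NULL) {
  if (!is.null(hbonds)) {
    mm <- hbonds[!hbonds$intra & !hbonds$donor_is_sidechain &
                   !hbonds$acceptor_is_sidechain, , drop = FALSE]
    linked <- (mm$donor_chain == chain_i & mm$acceptor_chain == chain_j) |
      (mm$donor_chain == chain_j & mm$acceptor_chain == chain_i)
    if (!any(linked)) {
      stop("usage error: chains ", chain_i, " and ", chain_j,
           " share no inter-main-chain hydrogen bond")
    }
  }
  ei <- chain_end_to_end(frame, chain_i)
  ej <- chain_end_to_end(frame, chain_j)
  if (sum(ei * ej) > 0) "PARALLEL" else "ANTIPARALLEL"
}

chain_end_to_end <- function(frame, chain) {
  at <- chain_atoms(frame, chain)
  backbone_xyz(at, max(at$resno), "CA") - backbone_xyz(at, 1L, "CA")
}

# orientation summary for every bonded strand pair of a frame
sheet_orientations <- function(frame, hbonds = NULL,
                               config = interaction_config()) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(frame, config = config)
  mm <- hbonds[!hbonds$intra & !hbonds$donor_is_sidechain &
                 !hbonds$acceptor_is_sidechain, , drop = FALSE]
  if (!nrow(mm)) {
    return(data.frame(chain_i = character(), chain_j = character(),
                      n_bonds = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(mm$donor_chain, mm$acceptor_chain)
  b <- pmax(mm$donor_chain, mm$acceptor_chain)
  key <- paste(a, b)
  pairs <- !duplicated(key)
  out <- data.frame(chain_i = a[pairs], chain_j = b[pairs],
                    n_bonds = as.integer(table(key)[key[pairs]]),
                    stringsAsFactors = FALSE)
  out$orientation <- vapply(seq_len(nrow(out)), function(k)
    strand_orientation(frame, out$chain_i[k], out$chain_j[k]),
    character(1L))
  out[order(out$chain_i, out$chain_j), , drop = FALSE]
}

#' Aggregate-size-stratified hydrogen-bond pattern statistics
#'
#' For each frame: detect hydrogen bonds and salt bridges, partition
#' chains into aggregates, classify every bond into the seven pattern
#' categories, and attribute it to the aggregate size of its donor
#' chain. Counts are pooled over frames (or taken from the last frame
#' only) and converted to percentages per aggregate-size bin.
#'
#' @param traj A [trajectory()] (or single frame).
#' @param d_cut,ang_cut Hydrogen-bond criteria (nm, degrees).
#' @param contact_cut Aggregate contact cutoff, nm.
#' @param regions A [conformation_regions()] object.
#' @param config An [interaction_config()].
#' @param mode `"pooled"` (counts accumulated over all frames, the
#'   default) or `"last"` (final snapshot only).
#' @return An object of class `"pattern_table"`: list with integer
#'   matrix `counts` (7 categories x observed sizes), matrix `percent`
#'   (columns summing to 100 where populated) and `n_frames`.
#' @export
pattern_statistics <- function(traj, d_cut = 0.30, ang_cut = 120,
                               contact_cut = 0.45,
                               regions = conformation_regions(),
                               config = interaction_config(),
                               mode = c("pooled", "last")) {
  traj <- as_trajectory(traj)
  mode <- match.arg(mode)
  frames <- if (mode == "last") {
    traj$frames[length(traj$frames)]
  } else {
    traj$frames
  }
  max_size <- length(chain_ids(traj$frames[[1L]]))
  counts <- matrix(0L, nrow = length(HBOND_CATEGORIES), ncol = max_size,
                   dimnames = list(HBOND_CATEGORIES, seq_len(max_size)))
  for (fr in frames) {
    hb <- detect_hbonds(fr, d_cut, ang_cut, config)
    if (!nrow(hb)) next
    sb <- detect_salt_bridges(fr, config = config)
    aggs <- find_aggregates(fr, contact_cut, hbonds = hb,
                            salt_bridges = sb, config = config)
    size_of <- aggregate_size_by_chain(aggs)
    conf <- frame_conformations(fr, regions)
    cats <- classify_hbond_set(hb, conf)
    for (k in seq_along(cats)) {
      s <- size_of[[hb$donor_chain[k]]]
      counts[cats[k], s] <- counts[cats[k], s] + 1L
    }
  }
  structure(list(counts = counts, percent = counts_to_percent(counts),
                 n_frames = length(frames)),
            class = "pattern_table")
}

counts_to_percent <- function(counts) {
  tot <- colSums(counts)
  percent <- sweep(counts, 2L, pmax(tot, 1L), `/`) * 100
  percent[, tot == 0L] <- 0
  percent
}

#' @export
print.pattern_table <- function(x, digits = 2, ...) {
  cat(sprintf("<pattern_table> %d frame(s), %d bond(s)\n",
              x$n_frames, sum(x$counts)))
  pop <- colSums(x$counts) > 0
  if (any(pop)) {
    print(round(x$percent[, pop, drop = FALSE], digits))
  } else {
    cat("(no hydrogen bonds)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pattern_table <- function(x, ...) {
  df <- as.data.frame(t(x$percent))
  df <- cbind(aggregate_size = as.integer(rownames(df)),
              n_bonds = as.integer(colSums(x$counts)), df)
  rownames(df) <- NULL
  df
}

#' Export a pattern table as TSV
#'
#' Rows are aggregate sizes, columns the seven categories, cells the
#' percentage of bonds (2 decimals) in that size bin.
#'
#' @param pt A `"pattern_table"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_pattern_tsv <- function(pt, path) {
  df <- as.data.frame(pt)
  for (cat in HBOND_CATEGORIES) df[[cat]] <- sprintf("%.2f", df[[cat]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
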
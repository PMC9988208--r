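# Aggregate detection, bond classification, strand orientation, and
# size-stratified pattern statistics.

test_that("aggregates are the connected components of the contact graph", {
  box <- build_minimum_bias_box(seed = 7)
  aggs <- find_aggregates(box)
  expect_length(aggs, 15L)
  expect_true(all(vapply(aggs, `[[`, integer(1L), "size") == 1L))

  # sheet pair plus one far chain: sizes {2, 1}
  sheet <- build_sheet_pair("ANTIPARALLEL", "CREKA")
  far <- build_chain("CREKA", chain_id = "C")
  atC <- far$atoms
  atC[, c("x", "y", "z")] <- atC[, c("x", "y", "z")] + 5
  atC$serial <- atC$serial + nrow(sheet$atoms)
  fr <- system_frame(rbind(sheet$atoms, atC))
  sizes <- sort(vapply(find_aggregates(fr), `[[`, integer(1L), "size"))
  expect_equal(sizes, c(1L, 2L))

  # contact is transitive through connected components: A-B and B-C in
  # contact, A-C not, gives one aggregate of three chains
  base <- build_chain("CREKA", chain_id = "A")
  stack <- lapply(1:3, function(k) {
    at <- base$atoms
    at$chain <- LETTERS[k]
    at$serial <- at$serial + (k - 1L) * nrow(at)
    at[, "z"] <- at[, "z"] + (k - 1L) * 0.30
    at
  })
  fr3 <- system_frame(do.call(rbind, stack))
  aggs3 <- find_aggregates(fr3)
  expect_length(aggs3, 1L)
  expect_equal(aggs3[[1L]]$size, 3L)
})

test_that("the partition matches an independent component oracle", {
  for (s in 1:5) {
    fr <- random_contact_frame(n_chains = 6L, seed = s + 100L)
    aggs <- find_aggregates(fr)
    membership <- attr(aggs, "membership")
    ids <- names(membership)
    # every chain in exactly one aggregate
    all_members <- unlist(lapply(aggs, `[[`, "chain_ids"))
    expect_setequal(all_members, ids)
    expect_equal(length(all_members), length(ids))
    # rebuild the edge list with the same criterion, components by BFS
    hb <- detect_hbonds(fr)
    sb <- detect_salt_bridges(fr)
    heavy <- fr$atoms[fr$atoms$element != "H", ]
    edges <- matrix(character(0), ncol = 2L)
    for (a in seq_along(ids)[-length(ids)]) {
      for (b in (a + 1L):length(ids)) {
        xa <- as.matrix(heavy[heavy$chain == ids[a], c("x", "y", "z")])
        xb <- as.matrix(heavy[heavy$chain == ids[b], c("x", "y", "z")])
        dmin <- sqrt(min(outer(rowSums(xa^2), rep(1, nrow(xb))) +
                           outer(rep(1, nrow(xa)), rowSums(xb^2)) -
                           2 * xa %*% t(xb)))
        bonded <- any(!hb$intra &
                        ((hb$donor_chain == ids[a] &
                            hb$acceptor_chain == ids[b]) |
                           (hb$donor_chain == ids[b] &
                              hb$acceptor_chain == ids[a]))) ||
          any(!sb$same_chain &
                ((sb$cation_chain == ids[a] & sb$anion_chain == ids[b]) |
                   (sb$cation_chain == ids[b] & sb$anion_chain == ids[a])))
        if (dmin < 0.45 || bonded) edges <- rbind(edges, c(ids[a], ids[b]))
      }
    }
    oracle <- bfs_components(ids, edges)
    # same partition up to component relabelling
    expect_equal(length(unique(oracle)), length(aggs))
    for (grp in split(ids, oracle)) {
      expect_length(unique(membership[grp]), 1L)
    }
  }
})

test_that("each synthetic fixture classifies to its intended category", {
  classify_all <- function(fr) {
    hb <- detect_hbonds(fr)
    conf <- pepassembly:::frame_conformations(fr)
    data.frame(hb, category = pepassembly:::classify_hbond_set(hb, conf),
               stringsAsFactors = FALSE)
  }

  bt <- classify_all(build_turn_chain("BETA_TURN"))
  expect_true("BETA_TURN" %in% bt$category)
  gt <- classify_all(build_turn_chain("GAMMA_TURN"))
  expect_true("GAMMA_TURN" %in% gt$category)

  for (ori in c("ANTIPARALLEL", "PARALLEL")) {
    sh <- classify_all(build_sheet_pair(ori, "CREKA"))
    inter_mm <- sh[!sh$intra & !sh$donor_is_sidechain &
                     !sh$acceptor_is_sidechain, ]
    expect_gte(nrow(inter_mm), 2L)
    expect_true(all(inter_mm$category == "BETA_SHEET"))
  }

  mm <- classify_all(synth_preset("mm-pair-creka"))
  inter_mm <- mm[!mm$intra & !mm$donor_is_sidechain &
                   !mm$acceptor_is_sidechain, ]
  expect_gte(nrow(inter_mm), 1L)
  expect_true(all(inter_mm$category == "MAIN_MAIN"))
  expect_false("BETA_SHEET" %in% mm$category)

  isd <- classify_all(build_intra_side_chain("CREKA"))
  expect_true("INTRA_SIDE" %in% isd$category)

  dim <- classify_all(build_salt_bridge_dimer("CREKA"))
  expect_true("INTER_SIDE" %in% dim$category)
  expect_false("BETA_SHEET" %in% dim$category)

  # an arginine-to-glutamate intermolecular side bond is INTER_SIDE
  arg_glu <- dim[dim$donor_resid == "ARG" & dim$donor_is_sidechain &
                   !dim$intra, ]
  if (nrow(arg_glu)) {
    expect_true(all(arg_glu$category == "INTER_SIDE"))
  }

  # intramolecular bond in a different aggregate is contradictory
  expect_error(
    classify_hbond(list(donor_chain = "A", acceptor_chain = "A",
                        donor_is_sidechain = FALSE,
                        acceptor_is_sidechain = FALSE,
                        donor_resno = 4L, acceptor_resno = 1L),
                   list(), same_aggregate = FALSE),
    "consistency")
})

test_that("strand orientation matches construction and is symmetric", {
  ap <- build_sheet_pair("ANTIPARALLEL", "CREKA")
  hb <- detect_hbonds(ap)
  expect_equal(strand_orientation(ap, "A", "B", hb), "ANTIPARALLEL")
  expect_equal(strand_orientation(ap, "B", "A", hb), "ANTIPARALLEL")
  pa <- build_sheet_pair("PARALLEL", "CREKA")
  expect_equal(strand_orientation(pa, "A", "B"), "PARALLEL")
  expect_equal(strand_orientation(pa, "B", "A"), "PARALLEL")

  # unbonded chains have no defined orientation
  box <- build_minimum_bias_box(n_chains = 3L, box = c(8, 8, 8), seed = 1)
  ids <- unique(box$atoms$chain)
  expect_error(strand_orientation(box, ids[1L], ids[2L],
                                  detect_hbonds(box)),
               "usage error")
})

test_that("pattern statistics stratify, normalise and conserve counts", {
  # an isolated ideal beta-turn chain: all bonds in the size-1 bin
  pt <- pattern_statistics(build_turn_chain("BETA_TURN"))
  expect_equal(pt$percent["BETA_TURN", "1"], 100)
  expect_equal(sum(pt$counts), sum(pt$counts["BETA_TURN", ]))

  # two-strand sheet: size-2 bin holds only beta-sheet plus constructed
  # side contacts, never undefined main-main
  pt2 <- pattern_statistics(build_sheet_pair("ANTIPARALLEL", "CREKA"))
  expect_gt(pt2$percent["BETA_SHEET", "2"], 0)
  expect_equal(pt2$percent["MAIN_MAIN", "2"], 0)
  expect_equal(sum(pt2$percent[, "2"]), 100, tolerance = 1e-6)

  # normalisation and count conservation on random frames
  for (s in 1:8) {
    fr <- random_contact_frame(n_chains = 5L, seed = s + 300L)
    hb <- detect_hbonds(fr)
    pt <- pattern_statistics(fr)
    expect_equal(sum(pt$counts), nrow(hb))
    pop <- colSums(pt$counts) > 0
    if (any(pop)) {
      expect_equal(unname(colSums(pt$percent[, pop, drop = FALSE])),
                   rep(100, sum(pop)), tolerance = 1e-6)
    }
  }

  # pooling over frames accumulates counts
  tr <- trajectory(list(build_turn_chain("BETA_TURN"),
                        build_turn_chain("BETA_TURN")))
  ptp <- pattern_statistics(tr, mode = "pooled")
  ptl <- pattern_statistics(tr, mode = "last")
  expect_equal(sum(ptp$counts), 2L * sum(ptl$counts))
})

test_that("beta-sheet content decays along a coordinate-noise ladder", {
  base <- build_sheet_pair("ANTIPARALLEL", "CREKA")
  sigmas <- c(0, 0.01, 0.02, 0.03, 0.05)
  mean_sheet <- vapply(sigmas, function(sg) {
    counts <- vapply(1:20, function(s) {
      fr <- perturb_frame(base, sg, seed = 1000L + s)
      hb <- detect_hbonds(fr)
      conf <- pepassembly:::frame_conformations(fr)
      if (!nrow(hb)) return(0L)
      sum(pepassembly:::classify_hbond_set(hb, conf) == "BETA_SHEET")
    }, integer(1L))
    mean(counts)
  }, numeric(1L))
  # monotone decay up to small sampling slack; strong loss at the top
  expect_true(all(diff(mean_sheet) <= 0.25))
  expect_lt(mean_sheet[length(sigmas)], mean_sheet[1L])
})
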
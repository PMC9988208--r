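# Donor/acceptor enumeration and hydrogen-bond / salt-bridge detection.

test_that("donor enumeration follows the N-H chemistry table", {
  fr <- build_chain("CREKA")
  don <- enumerate_donors(fr)
  expect_equal(sum(don$mainchain), 4L)                  # residues 2-5
  expect_equal(sum(don$group == "A:nterm"), 3L)         # ammonium
  expect_equal(sum(don$resid == "ARG" & !don$mainchain), 5L)
  expect_equal(sum(don$resid == "LYS" & !don$mainchain), 3L)
  expect_equal(nrow(don), 15L)
  expect_false(any(don$heavy == "SG"))                  # thiol off

  # the methylated backbone nitrogen cannot donate
  frn <- build_chain("CRENKA")
  donn <- enumerate_donors(frn)
  expect_equal(sum(donn$mainchain), 3L)
  expect_false(any(donn$resid == "MEG" & donn$heavy == "N"))

  # thiol donor is opt-in
  cfg <- interaction_config(include_cys_thiol = TRUE)
  expect_true(any(enumerate_donors(fr, cfg)$heavy == "SG"))
})

test_that("acceptor enumeration counts backbone and carboxylate oxygens", {
  fr <- build_chain("CREKA")
  acc <- enumerate_acceptors(fr)
  # 4 amide carbonyls + 2 C-terminal + 2 Glu side-chain oxygens
  expect_equal(nrow(acc), 8L)
  expect_equal(sum(acc$mainchain), 4L)
  expect_equal(sum(acc$name %in% c("OE1", "OE2")), 2L)

  # protonated acid still accepts by default, not in charged-only mode
  frp <- build_chain("CREKA", glu_protonated = TRUE)
  expect_equal(nrow(enumerate_acceptors(frp)), 8L)
  cfg <- interaction_config(charged_carboxylates_only = TRUE)
  expect_equal(nrow(enumerate_acceptors(frp, cfg)), 6L)
  expect_equal(nrow(enumerate_acceptors(fr, cfg)), 8L)

  empty <- system_frame(data.frame(
    serial = integer(), name = character(), element = character(),
    chain = character(), resno = integer(), resid = character(),
    x = numeric(), y = numeric(), z = numeric()))
  expect_equal(nrow(enumerate_acceptors(empty)), 0L)
  expect_equal(nrow(detect_hbonds(empty)), 0L)
})

# place chain B so that its residue-1 carbonyl O sits at distance d and
# angle ang (vertex at H) from the backbone amide H of residue 3 of A
place_acceptor_at <- function(d, ang) {
  frA <- build_chain("CREKA", chain_id = "A")
  frB <- build_chain("CREKA", chain_id = "B")
  atA <- frA$atoms
  h <- as.numeric(atA[atA$resno == 3 & atA$name == "H",
                      c("x", "y", "z")])
  n <- as.numeric(atA[atA$resno == 3 & atA$name == "N",
                      c("x", "y", "z")])
  u <- (h - n) / sqrt(sum((h - n)^2))    # N->H direction
  w <- c(-u[2], u[1], 0)
  w <- w / sqrt(sum(w^2))
  # angle at H between N and acceptor
  dir <- cos(pi * ang / 180) * (-u) + sin(pi * ang / 180) * w
  target <- h + d * dir
  atB <- frB$atoms
  o1 <- as.numeric(atB[atB$resno == 1 & atB$name == "O",
                       c("x", "y", "z")])
  atB[, c("x", "y", "z")] <-
    sweep(as.matrix(atB[, c("x", "y", "z")]), 2L, o1 - target, `-`)
  atB$serial <- atB$serial + nrow(atA)
  system_frame(rbind(atA, atB))
}

test_that("distance and angle criteria are strict inequalities", {
  has_pair <- function(fr) {
    hb <- detect_hbonds(fr)
    any(hb$donor_chain == "A" & hb$donor_resno == 3 & hb$hydrogen == "H" &
          hb$acceptor_chain == "B" & hb$acceptor_resno == 1 &
          hb$acceptor_name == "O")
  }
  expect_true(has_pair(place_acceptor_at(0.20, 180)))   # comfortably in
  expect_false(has_pair(place_acceptor_at(0.30, 180)))  # d == cutoff: out
  expect_true(has_pair(place_acceptor_at(0.2999, 180)))
  expect_false(has_pair(place_acceptor_at(0.25, 120)))  # ang == cutoff
  expect_true(has_pair(place_acceptor_at(0.25, 121)))
  expect_error(detect_hbonds(build_chain(), d_cut = 0), "parameter")
  expect_error(detect_hbonds(build_chain(), ang_cut = -5), "parameter")
})

test_that("grid detection equals exhaustive evaluation", {
  for (s in 1:10) {
    fr <- random_contact_frame(n_chains = 5L, seed = s)
    g <- detect_hbonds(fr, method = "grid")
    e <- detect_hbonds(fr, method = "exhaustive")
    expect_identical(hbond_keys(g), hbond_keys(e))
    expect_equal(g$d_HO, e$d_HO, tolerance = 1e-12)
    expect_equal(g$angle_DHA, e$angle_DHA, tolerance = 1e-12)
  }
})

test_that("bond sets are monotone in the cutoffs and rigid-motion invariant", {
  fr <- random_contact_frame(n_chains = 6L, seed = 42)
  tight <- detect_hbonds(fr, d_cut = 0.30, ang_cut = 120)
  loose <- detect_hbonds(fr, d_cut = 0.35, ang_cut = 100)
  expect_true(all(hbond_keys(tight) %in% hbond_keys(loose)))

  for (s in 1:4) {
    moved <- rigid_move(fr, seed = s)
    hb2 <- detect_hbonds(moved)
    expect_identical(hbond_keys(hb2), hbond_keys(tight))
    expect_equal(hb2$d_HO, tight$d_HO, tolerance = 1e-9)
  }
})

test_that("the methylated nitrogen never appears as a donor", {
  for (s in 1:6) {
    fr <- random_contact_frame(n_chains = 4L, seed = s,
                               sequence = "CRENKA", noise_sigma = 0.02)
    hb <- detect_hbonds(fr)
    expect_false(any(hb$donor_resid == "MEG" & hb$donor_heavy == "N"))
  }
})

test_that("salt bridges obey the cutoff and deduplicate per residue pair", {
  fr <- build_salt_bridge_dimer("CREKA")
  sb <- detect_salt_bridges(fr)
  expect_gte(nrow(sb), 1L)
  expect_true(all(sb$d < 0.40))

  # pulling the chains apart removes every bridge
  at <- fr$atoms
  at[at$chain == "B", c("x", "y", "z")] <-
    at[at$chain == "B", c("x", "y", "z")] + 5
  far <- system_frame(at)
  expect_equal(nrow(detect_salt_bridges(far)), 0L)

  # intramolecular Lys Nz near the C-terminal carboxylate: one record,
  # minimum distance kept, flagged same-chain
  fr1 <- build_chain("CREKA")
  at1 <- fr1$atoms
  oxt <- as.numeric(at1[at1$resno == 5 & at1$name == "OXT",
                        c("x", "y", "z")])
  o5 <- as.numeric(at1[at1$resno == 5 & at1$name == "O",
                       c("x", "y", "z")])
  dir <- (oxt - o5) / sqrt(sum((oxt - o5)^2))
  at1[at1$name == "NZ", c("x", "y", "z")] <- rbind(oxt + 0.25 * dir)
  fr1 <- system_frame(at1)
  sb1 <- detect_salt_bridges(fr1)
  rec <- sb1[sb1$cation_atom == "NZ" & sb1$anion_resno == 5, ]
  expect_equal(nrow(rec), 1L)
  expect_true(rec$same_chain)
  expect_equal(rec$d, 0.25, tolerance = 1e-6)
  expect_equal(rec$anion_atom, "OXT")
})
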
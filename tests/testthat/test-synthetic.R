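# Synthetic builders: determinism, chemistry, sheet hydrogen-bond
# inventories, minimum-bias placement and turn fragility under noise.

test_that("builders are deterministic for a fixed seed", {
  a <- build_chain("CREKA", noise_sigma = 0.02, seed = 5)
  b <- build_chain("CREKA", noise_sigma = 0.02, seed = 5)
  expect_identical(a$atoms, b$atoms)
  expect_false(identical(
    a$atoms,
    build_chain("CREKA", noise_sigma = 0.02, seed = 6)$atoms))

  b1 <- build_minimum_bias_box(seed = 9)
  b2 <- build_minimum_bias_box(seed = 9)
  expect_identical(b1$atoms, b2$atoms)

  d1 <- dla_grow(400, seed = 3)
  d2 <- dla_grow(400, seed = 3)
  expect_identical(d1$sites, d2$sites)
})

test_that("generated chemistry passes validation for both sequences", {
  for (sq in c("CREKA", "CRENKA")) {
    fr <- build_chain(sq, noise_sigma = 0.01, seed = 2)
    expect_silent(pepassembly:::validate_frame(fr, strict_h = TRUE))
  }
  frn <- build_chain("CRENKA")
  at <- frn$atoms
  expect_false(any(at$resno == 3L & at$name == "H"))
  expect_true(any(at$resno == 3L & at$name == "CN"))
  # protonated carboxylic acid carries its hydrogen
  frp <- build_chain("CREKA", glu_protonated = TRUE)
  expect_true(any(frp$atoms$name == "HE2"))
})

test_that("sheet pairs carry the designed hydrogen-bond ladders", {
  n_mm <- function(fr) nrow(inter_mainchain(detect_hbonds(fr)))
  ap_creka <- n_mm(build_sheet_pair("ANTIPARALLEL", "CREKA"))
  ap_crenka <- n_mm(build_sheet_pair("ANTIPARALLEL", "CRENKA"))
  expect_gte(ap_creka, 2L)
  expect_lte(ap_crenka, 2L)
  expect_lt(ap_crenka, ap_creka)   # methylation hampers the ladder

  pa_creka <- n_mm(build_sheet_pair("PARALLEL", "CREKA"))
  pa_crenka <- n_mm(build_sheet_pair("PARALLEL", "CRENKA"))
  expect_gte(pa_creka, 2L)
  expect_lt(pa_crenka, pa_creka)

  expect_error(build_sheet_pair("ANTIPARALLEL", separation = 0.2),
               "parameter error")
  expect_error(build_sheet_pair("ANTIPARALLEL", separation = 0.9),
               "parameter error")
})

test_that("minimum-bias placement honours spacing for many seeds", {
  for (s in 1:40) {
    box <- build_minimum_bias_box(seed = s)
    cogs <- chain_cogs(box)
    d <- as.matrix(dist(cogs))
    diag(d) <- Inf
    expect_gte(min(d), 1.8)
    # all atoms inside the box
    xyz <- as.matrix(box$atoms[, c("x", "y", "z")])
    expect_true(all(xyz >= 0 & xyz <= rep(c(9.5, 8.5, 9.0),
                                          each = nrow(xyz))))
  }
  one <- build_minimum_bias_box(n_chains = 1L, seed = 1)
  expect_length(find_aggregates(one), 1L)
  expect_error(build_minimum_bias_box(n_chains = 40L, box = c(3, 3, 3),
                                      seed = 1),
               "feasibility")
})

test_that("turn hydrogen bonds are usually destroyed by 0.1 nm noise", {
  base <- build_turn_chain("BETA_TURN", "CREKA")
  kept <- vapply(1:100, function(s) {
    fr <- perturb_frame(base, 0.10, seed = s)
    hb <- detect_hbonds(fr)
    any(!hb$donor_is_sidechain & !hb$acceptor_is_sidechain &
          hb$donor_resno == 4L & hb$acceptor_resno == 1L)
  }, logical(1L))
  expect_lt(mean(kept), 0.5)
})

test_that("the salt-bridge dimer is bridged but not sheet-bonded", {
  fr <- build_salt_bridge_dimer("CREKA")
  expect_gte(nrow(detect_salt_bridges(fr)), 1L)
  hb <- detect_hbonds(fr)
  expect_equal(nrow(inter_mainchain(hb)), 0L)
  aggs <- find_aggregates(fr)
  expect_length(aggs, 1L)
  expect_equal(aggs[[1L]]$size, 2L)
})
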
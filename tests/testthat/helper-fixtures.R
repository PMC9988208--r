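# Shared fixtures and independent oracles for the test suite.

# Chains thrown into a small box with random rotation/translation and no
# clearance constraint, so inter-chain contacts and bonds arise freely.
random_contact_frame <- function(n_chains = 6L, box = c(3.2, 3.2, 3.2),
                                 seed = 1L, sequence = "CREKA",
                                 noise_sigma = 0.01) {
  template <- build_chain(sequence, chain_id = "A")
  withr::with_seed(seed, {
    dfs <- lapply(seq_len(n_chains), function(k) {
      at <- template$atoms
      xyz <- as.matrix(at[, c("x", "y", "z")])
      xyz <- sweep(xyz, 2L, colMeans(xyz))
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
      rot <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z),
                      2 * (x * z + w * y), 2 * (x * y + w * z),
                      1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                      2 * (x * z - w * y), 2 * (y * z + w * x),
                      1 - 2 * (x^2 + y^2)), 3L, 3L, byrow = TRUE)
      xyz <- xyz %*% t(rot)
      xyz <- sweep(xyz, 2L, runif(3L) * box, `+`)
      if (noise_sigma > 0) {
        xyz <- xyz + matrix(rnorm(length(xyz), sd = noise_sigma),
                            ncol = 3L)
      }
      at[, c("x", "y", "z")] <- xyz
      at$chain <- LETTERS[k]
      at$serial <- at$serial + (k - 1L) * nrow(at)
      at
    })
    system_frame(do.call(rbind, dfs))
  })
}

# independent connected-components oracle (breadth-first search)
bfs_components <- function(ids, edges) {
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  adj <- setNames(rep(list(character(0)), length(ids)), ids)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  cur <- 0L
  for (root in ids) {
    if (!is.na(comp[[root]])) next
    cur <- cur + 1L
    queue <- root
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cur
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# inter-chain main-chain-amide bonds of an hbond_set
inter_mainchain <- function(hb) {
  hb[!hb$intra & !hb$donor_is_sidechain & !hb$acceptor_is_sidechain, ,
     drop = FALSE]
}

# canonical string key per bond, for set comparisons
hbond_keys <- function(hb) {
  paste(hb$donor_chain, hb$donor_resno, hb$hydrogen,
        hb$acceptor_chain, hb$acceptor_resno, hb$acceptor_name)
}

chain_cogs <- function(frame) {
  ids <- unique(frame$atoms$chain)
  t(vapply(ids, function(c)
    colMeans(as.matrix(frame$atoms[frame$atoms$chain == c,
                                   c("x", "y", "z")])),
    numeric(3L)))
}

mean_nn_distance <- function(frame) {
  d <- as.matrix(dist(chain_cogs(frame)))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

# rigid-motion helper: rotate + translate every atom of a frame
rigid_move <- function(frame, seed = 1L) {
  withr::with_seed(seed, {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rot <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z),
                    2 * (x * z + w * y), 2 * (x * y + w * z),
                    1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                    2 * (x * z - w * y), 2 * (y * z + w * x),
                    1 - 2 * (x^2 + y^2)), 3L, 3L, byrow = TRUE)
    shift <- runif(3L, -3, 3)
    xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
    frame$atoms[, c("x", "y", "z")] <-
      sweep(xyz %*% t(rot), 2L, shift, `+`)
    frame
  })
}

make_square_cluster <- function(side = 64L) {
  s <- as.matrix(expand.grid(x = seq_len(side) - 1L,
                             y = seq_len(side) - 1L))
  structure(list(sites = s, stage = rep("PRENUCLEATED", nrow(s))),
            class = "lattice_cluster")
}

make_line_cluster <- function(len = 512L) {
  s <- cbind(x = 0:(len - 1L), y = rep(0L, len))
  structure(list(sites = s, stage = rep("PRENUCLEATED", len)),
            class = "lattice_cluster")
}
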
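# Diffusion-limited aggregation, surface coalescence and the
# box-counting dimension estimator.

test_that("DLA growth is connected, deterministic and branched", {
  one <- dla_grow(1, seed = 1)
  expect_equal(nrow(one$sites), 1L)
  expect_true(cluster_connected(one))

  cl <- dla_grow(1500, seed = 4)
  expect_equal(nrow(cl$sites), 1500L)
  expect_true(cluster_connected(cl))
  expect_true(all(cl$stage == "PRENUCLEATED"))
  expect_identical(dla_grow(1500, seed = 4)$sites, cl$sites)

  # a branched fractal: dimension strictly between line and plane
  fd <- fractal_dimension(cl)
  expect_gt(fd$dimension, 1.2)
  expect_lt(fd$dimension, 1.9)

  expect_error(dla_grow(0), "n_particles")
  expect_error(dla_grow(10, stickiness = 0), "stickiness")
})

test_that("box counting is exact on analytic limits", {
  sq <- make_square_cluster(64L)
  fd_sq <- fractal_dimension(sq)
  expect_equal(fd_sq$dimension, 2.0, tolerance = 0.1)
  ln <- make_line_cluster(512L)
  fd_ln <- fractal_dimension(ln)
  expect_equal(fd_ln$dimension, 1.0, tolerance = 0.1)
  expect_gte(length(fd_sq$scales), 4L)

  expect_error(fractal_dimension(make_line_cluster(50L)), "precision")
  expect_error(fractal_dimension(make_square_cluster(10L)), "precision")
})

test_that("mass-radius dimension agrees with the analytic limits", {
  sq <- make_square_cluster(128L)
  # centre the square on its middle so radii sample the interior
  sq$sites <- sq$sites - 64L
  expect_equal(mass_radius_dimension(sq, center = c(0, 0))$dimension,
               2.0, tolerance = 0.15)
  cl <- dla_grow(1500, seed = 4)
  md <- mass_radius_dimension(cl)
  expect_gt(md$dimension, 1.3)
  expect_lt(md$dimension, 2.0)
})

test_that("coalescence fills concave sites without roughening", {
  cl <- dla_grow(1200, seed = 8)
  expect_identical(coalesce_fill(cl, 0L), cl)

  filled <- coalesce_fill(cl, 600L, seed = 2)
  expect_equal(nrow(filled$sites), 1800L)
  expect_equal(sum(filled$stage == "FILL"), 600L)
  expect_true(cluster_connected(filled))
  expect_identical(coalesce_fill(cl, 600L, seed = 2)$sites,
                   filled$sites)

  pa0 <- perimeter_area(cl)
  pa1 <- perimeter_area(filled)
  expect_lte(pa1[["perimeter"]] / pa1[["area"]],
             pa0[["perimeter"]] / pa0[["area"]])

  # every deposited site touches the prior cluster
  prior <- paste(cl$sites[, 1L], cl$sites[, 2L])
  all_sites <- filled$sites
  occ <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(all_sites))) {
    key <- paste(all_sites[k, 1L], all_sites[k, 2L])
    if (filled$stage[k] == "FILL") {
      nb <- c(paste(all_sites[k, 1L] + 1L, all_sites[k, 2L]),
              paste(all_sites[k, 1L] - 1L, all_sites[k, 2L]),
              paste(all_sites[k, 1L], all_sites[k, 2L] + 1L),
              paste(all_sites[k, 1L], all_sites[k, 2L] - 1L))
      expect_true(any(vapply(nb, exists, logical(1L), envir = occ)))
    }
    assign(key, TRUE, envir = occ)
  }

  # the fill stage never increases perimeter/area along the way
  steps <- c(100L, 300L, 600L)
  ratios <- vapply(steps, function(n) {
    pa <- perimeter_area(coalesce_fill(cl, n, seed = 2))
    pa[["perimeter"]] / pa[["area"]]
  }, numeric(1L))
  expect_true(all(diff(c(pa0[["perimeter"]] / pa0[["area"]],
                         ratios)) <= 1e-12))
})
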
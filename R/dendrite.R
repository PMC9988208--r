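# Lattice model of the two-step dendrite-formation mechanism:
# (1) diffusion-limited aggregation pre-nucleates a fractal cluster that
# defines the dendritic geometry; (2) further molecules deposit onto the
# cluster surface, preferentially into concave sites, coalescing the
# structure into a continuous dendrite. This is an illustrative,
# desk-scale embodiment of a qualitative mechanism: lattice particles do
# not map onto individual peptide molecules or concentrations.

new_lattice_cluster <- function(sites, stage) {
  stopifnot(is.matrix(sites), ncol(sites) == 2L,
            length(stage) == nrow(sites))
  structure(list(sites = sites, stage = stage),
            class = "lattice_cluster")
}

#' @export
print.lattice_cluster <- function(x, ...) {
  cat(sprintf("<lattice_cluster> %d site(s) (%d pre-nucleated, %d fill)\n",
              nrow(x$sites), sum(x$stage == "PRENUCLEATED"),
              sum(x$stage == "FILL")))
  invisible(x)
}

#' @export
plot.lattice_cluster <- function(x, ...) {
  cols <- ifelse(x$stage == "FILL", "firebrick", "grey25")
  graphics::plot(x$sites[, 1L], x$sites[, 2L], pch = 15,
                 cex = 0.3, col = cols, asp = 1,
                 xlab = "x (lattice units)", ylab = "y (lattice units)",
                 ...)
  invisible(x)
}

#' Grow a diffusion-limited aggregation cluster
#'
#' Classic on-lattice DLA: random walkers launched from a circle
#' outside the cluster stick, with the given probability, to any site
#' adjacent (4-neighbourhood) to the cluster; walkers beyond the kill
#' radius (3 x launch radius) are re-launched. Deterministic per seed.
#'
#' @param n_particles Number of particles (>= 1), including the seed.
#' @param stickiness Sticking probability in (0, 1].
#' @param seed Integer seed.
#' @return A `"lattice_cluster"` with all sites tagged
#'   `"PRENUCLEATED"`.
#' @export
dla_grow <- function(n_particles, stickiness = 1.0, seed = NULL) {
  run <- function() dla_grow_cpp(as.integer(n_particles), stickiness)
  sites <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(sites) <- c("x", "y")
  new_lattice_cluster(sites, rep("PRENUCLEATED", nrow(sites)))
}

# occupancy matrix + origin offset for a cluster (with optional margin)
cluster_grid <- function(cluster, margin = 1L) {
  s <- cluster$sites
  xr <- range(s[, 1L]); yr <- range(s[, 2L])
  ox <- xr[1L] - margin - 1L
  oy <- yr[1L] - margin - 1L
  W <- xr[2L] - xr[1L] + 2L * margin + 2L
  H <- yr[2L] - yr[1L] + 2L * margin + 2L
  occ <- matrix(FALSE, nrow = W, ncol = H)
  occ[cbind(s[, 1L] - ox, s[, 2L] - oy)] <- TRUE
  list(occ = occ, ox = ox, oy = oy)
}

#' Perimeter and area of a lattice cluster
#'
#' Area is the number of occupied sites; perimeter the number of
#' exposed unit edges (4-neighbourhood).
#'
#' @param cluster A `"lattice_cluster"`.
#' @return Named numeric vector `c(perimeter, area)`.
#' @export
perimeter_area <- function(cluster) {
  g <- cluster_grid(cluster)
  occ <- g$occ
  W <- nrow(occ); H <- ncol(occ)
  nb <- matrix(0L, W, H)
  nb[-W, ] <- nb[-W, ] + occ[-1L, ]
  nb[-1L, ] <- nb[-1L, ] + occ[-W, ]
  nb[, -H] <- nb[, -H] + occ[, -1L]
  nb[, -1L] <- nb[, -1L] + occ[, -H]
  c(perimeter = sum(4L - nb[occ]), area = sum(occ))
}

#' Is a lattice cluster 4-connected?
#'
#' @param cluster A `"lattice_cluster"`.
#' @return Logical.
#' @export
cluster_connected <- function(cluster) {
  g <- cluster_grid(cluster)
  occ <- g$occ
  n <- sum(occ)
  if (n <= 1L) return(TRUE)
  start <- which(occ, arr.ind = TRUE)[1L, ]
  seen <- matrix(FALSE, nrow(occ), ncol(occ))
  stack <- matrix(start, ncol = 2L)
  seen[start[1L], start[2L]] <- TRUE
  count <- 0L
  while (nrow(stack)) {
    cur <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    count <- count + 1L
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nx <- cur[1L] + d[1L]; ny <- cur[2L] + d[2L]
      if (occ[nx, ny] && !seen[nx, ny]) {
        seen[nx, ny] <- TRUE
        stack <- rbind(stack, c(nx, ny))
      }
    }
  }
  count == n
}

#' Coalesce a cluster by surface deposition
#'
#' Deposits `n_fill` particles one at a time onto empty perimeter
#' sites, preferring concave sites (>= 2 occupied 4-neighbours; when
#' none exists, any site with an occupied neighbour). New sites are
#' tagged `"FILL"`. Connectivity is preserved and, because concave
#' deposition never adds more exposed edge than it removes, the
#' perimeter-to-area ratio does not increase.
#'
#' @param cluster A `"lattice_cluster"`.
#' @param n_fill Number of particles to deposit (>= 0).
#' @param seed Integer seed.
#' @return The enlarged `"lattice_cluster"`.
#' @export
coalesce_fill <- function(cluster, n_fill, seed = NULL) {
  stopifnot(n_fill >= 0)
  if (n_fill == 0L) return(cluster)
  run <- function() coalesce_fill_run(cluster, n_fill)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

coalesce_fill_run <- function(cluster, n_fill) {
  margin <- as.integer(ceiling(sqrt(n_fill))) + 2L
  g <- cluster_grid(cluster, margin = margin)
  occ <- g$occ
  W <- nrow(occ); H <- ncol(occ)
  idx <- function(x, y) (y - 1L) * W + x
  nc <- matrix(0L, W, H)   # occupied-neighbour count
  add_nc <- function(x, y) {
    nc[x + 1L, y] <<- nc[x + 1L, y] + 1L
    nc[x - 1L, y] <<- nc[x - 1L, y] + 1L
    nc[x, y + 1L] <<- nc[x, y + 1L] + 1L
    nc[x, y - 1L] <<- nc[x, y - 1L] + 1L
  }
  sxy <- which(occ, arr.ind = TRUE)
  for (k in seq_len(nrow(sxy))) add_nc(sxy[k, 1L], sxy[k, 2L])
  # candidate stack of concave sites (may hold stale entries)
  cand <- which(!occ & nc >= 2L)
  new_sites <- matrix(0L, n_fill, 2L)
  for (p in seq_len(n_fill)) {
    pick <- NA_integer_
    while (length(cand)) {
      k <- if (length(cand) == 1L) 1L else sample.int(length(cand), 1L)
      ci <- cand[k]
      cand <- cand[-k]
      if (!occ[ci] && nc[ci] >= 2L) { pick <- ci; break }
    }
    if (is.na(pick)) {
      # no concave site (thin cluster): any empty perimeter site
      per <- which(!occ & nc >= 1L)
      if (!length(per)) stop("no deposition site available")
      pick <- if (length(per) == 1L) per else
        per[sample.int(length(per), 1L)]
    }
    x <- ((pick - 1L) %% W) + 1L
    y <- ((pick - 1L) %/% W) + 1L
    if (x <= 1L || x >= W || y <= 1L || y >= H) {
      stop("fill margin exhausted")
    }
    occ[x, y] <- TRUE
    add_nc(x, y)
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nx <- x + d[1L]; ny <- y + d[2L]
      if (!occ[nx, ny] && nc[nx, ny] >= 2L) {
        cand <- c(cand, idx(nx, ny))
      }
    }
    new_sites[p, ] <- c(x + g$ox, y + g$oy)
  }
  new_lattice_cluster(rbind(cluster$sites, new_sites),
                      c(cluster$stage, rep("FILL", n_fill)))
}

#' Box-counting fractal dimension of a lattice cluster
#'
#' Least-squares slope of log(occupied-box count) against log(1/box
#' size) over dyadic box sizes from 2 up to a quarter of the cluster
#' extent (at least 4 scales required). A filled square estimates 2, a
#' straight line 1, and classic DLA clusters about 1.7.
#'
#' @param cluster A `"lattice_cluster"` with >= 100 sites.
#' @return List of class `"fractal_fit"`: `dimension`, `stderr`,
#'   `scales`, `counts`.
#' @export
fractal_dimension <- function(cluster) {
  s <- cluster$sites
  if (nrow(s) < 100L) {
    stop("precision error: need >= 100 occupied sites")
  }
  ext <- max(diff(range(s[, 1L])), diff(range(s[, 2L]))) + 1L
  scales <- 2^(1:30)
  scales <- scales[scales <= ext / 4]
  if (length(scales) < 4L) {
    stop("precision error: cluster extent ", ext,
         " too small for 4 dyadic scales")
  }
  counts <- vapply(scales, function(sc) {
    bx <- floor(s[, 1L] / sc)
    by <- floor(s[, 2L] / sc)
    length(unique(bx + 1i * by))
  }, numeric(1L))
  fit <- lm(log(counts) ~ log(1 / scales))
  structure(list(dimension = unname(coef(fit)[2L]),
                 stderr = suppressWarnings(summary(fit))$coefficients[2L, 2L],
                 scales = scales, counts = counts),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> D = %.3f +/- %.3f over %d scales\n",
              x$dimension, x$stderr, length(x$scales)))
  invisible(x)
}

#' Mass-radius fractal dimension
#'
#' Complementary estimator: slope of log cluster mass within radius r
#' of the growth centre against log r, over dyadic radii from 4 up to
#' half the maximum site radius. Less sensitive than box counting to
#' the one-site branch width of desk-scale DLA clusters.
#'
#' @param cluster A `"lattice_cluster"` with >= 100 sites.
#' @param center Numeric 2-vector; defaults to the first (seed) site.
#' @return List of class `"fractal_fit"`.
#' @export
mass_radius_dimension <- function(cluster, center = NULL) {
  s <- cluster$sites
  if (nrow(s) < 100L) {
    stop("precision error: need >= 100 occupied sites")
  }
  if (is.null(center)) center <- s[1L, ]
  r <- sqrt((s[, 1L] - center[1L])^2 + (s[, 2L] - center[2L])^2)
  radii <- 2^(2:30)
  radii <- radii[radii <= max(r) / 2]
  if (length(radii) < 3L) {
    stop("precision error: cluster too small for 3 dyadic radii")
  }
  mass <- vapply(radii, function(x) sum(r <= x), numeric(1L))
  fit <- lm(log(mass) ~ log(radii))
  structure(list(dimension = unname(coef(fit)[2L]),
                 stderr = suppressWarnings(summary(fit))$coefficients[2L, 2L],
                 scales = radii, counts = mass),
            class = "fractal_fit")
}

#' Export a lattice cluster as CSV
#'
#' @param cluster A `"lattice_cluster"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_cluster_csv <- function(cluster, path) {
  df <- data.frame(x = cluster$sites[, 1L], y = cluster$sites[, 2L],
                   stage = cluster$stage)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
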
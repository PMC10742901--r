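# Independent oracles and fixture builders shared across the test files.
# Oracles deliberately avoid the code paths they check.

# erf through the normal CDF (the implementation uses pracma::erf)
erf_oracle <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# random labelled tree on n vertices: attach each vertex to an earlier one
random_tree <- function(n) {
  if (n == 1) return(matrix(integer(), 0, 2))
  cbind(vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L), 2:n)
}

# longest simple path (in vertices) by exhaustive DFS over all paths
brute_backbone <- function(bonds, n) {
  if (n == 1) return(1L)
  adj <- lapply(seq_len(n), function(v) {
    c(bonds[bonds[, 1] == v, 2], bonds[bonds[, 2] == v, 1])
  })
  best <- 0L
  walk <- function(v, visited) {
    best <<- max(best, length(visited))
    for (u in adj[[v]]) {
      if (!u %in% visited) walk(u, c(visited, u))
    }
  }
  for (v in seq_len(n)) walk(v, v)
  best
}

# tree diameter via all-pairs shortest paths in igraph (independent algorithm)
igraph_backbone <- function(bonds, n) {
  if (n == 1) return(1L)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  max(igraph::distances(g)) + 1L
}

# box of straight chains laid out on a y/z raster (identity orientations,
# 0.5 nm bond length); sizes in beads, one polymer per entry
chain_box <- function(sizes, edge = 30, spacing = 2) {
  rows <- list()
  bonds <- NULL
  bead <- 0L
  per_row <- floor((edge - 2) / spacing)
  for (p in seq_along(sizes)) {
    k <- sizes[p]
    iy <- (p - 1) %% per_row
    iz <- (p - 1) %/% per_row
    ids <- bead + seq_len(k)
    rows[[p]] <- tibble::tibble(
      x = 1 + 0.5 * (seq_len(k) - 1), y = 1 + spacing * iy,
      z = 1 + spacing * iz, polymer_id = p)
    if (k > 1) bonds <- rbind(bonds, cbind(ids[-k], ids[-1]))
    bead <- bead + k
  }
  mc_box(dplyr::bind_rows(rows), bonds, edge = edge)
}

# box holding arbitrary tree topologies at collision-free positions
tree_box <- function(trees, edge = 50) {
  # trees: list of bond matrices (local 1-based ids); sizes inferred
  rows <- list()
  bonds <- NULL
  bead <- 0L
  for (p in seq_along(trees)) {
    b <- trees[[p]]
    k <- if (nrow(b)) max(b) else 1L
    ids <- bead + seq_len(k)
    rows[[p]] <- tibble::tibble(
      x = 1 + 0.6 * (seq_len(k) - 1), y = 1 + 2 * ((p - 1) %% 20),
      z = 1 + 2 * ((p - 1) %/% 20), polymer_id = p)
    if (nrow(b)) bonds <- rbind(bonds, cbind(ids[b[, 1]], ids[b[, 2]]))
    bead <- bead + k
  }
  mc_box(dplyr::bind_rows(rows), bonds, edge = edge)
}

# --- cuboid oracles --------------------------------------------------------

random_cuboid <- function(center_range = 2, edge_range = c(0.3, 1.2)) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  cuboid(stats::runif(3, -center_range, center_range),
         stats::runif(3, edge_range[1] / 2, edge_range[2] / 2),
         polymc:::quat_from_axis_angle(axis, stats::runif(1, 0, pi)))
}

# closed-form projection of world points (rows) onto an oriented cuboid
project_on_cuboid <- function(pts, cub) {
  R <- polymc:::quat_to_matrix(cub$quat)
  local <- sweep(pts, 2, cub$center) %*% R   # = t(R) applied to each point
  for (k in 1:3) {
    local[, k] <- pmin(pmax(local[, k], -cub$half_extents[k]),
                       cub$half_extents[k])
  }
  local %*% t(R) + rep(cub$center, each = nrow(pts))
}

# grid sample of all six faces (edges and corners included)
sample_cuboid_surface <- function(cub, g = 40) {
  h <- cub$half_extents
  s <- seq(-1, 1, length.out = g)
  grid <- as.matrix(expand.grid(s, s))
  faces <- list()
  for (ax in 1:3) {
    for (sg in c(-1, 1)) {
      pts <- matrix(0, nrow(grid), 3)
      others <- setdiff(1:3, ax)
      pts[, ax] <- sg * h[ax]
      pts[, others[1]] <- grid[, 1] * h[others[1]]
      pts[, others[2]] <- grid[, 2] * h[others[2]]
      faces[[length(faces) + 1L]] <- pts
    }
  }
  local <- do.call(rbind, faces)
  R <- polymc:::quat_to_matrix(cub$quat)
  local %*% t(R) + rep(cub$center, each = nrow(local))
}

# dense-sampling distance oracle: sampled surface of each body projected
# in closed form onto the other, minimum over both directions
sampling_distance_oracle <- function(a, b, g = 40) {
  sa <- sample_cuboid_surface(a, g)
  sb <- sample_cuboid_surface(b, g)
  da <- sqrt(rowSums((sa - project_on_cuboid(sa, b))^2))
  db <- sqrt(rowSums((sb - project_on_cuboid(sb, a))^2))
  min(da, db)
}

# exact separating-axis intersection test for two oriented cuboids
sat_intersects <- function(a, b) {
  Ra <- polymc:::quat_to_matrix(a$quat)
  Rb <- polymc:::quat_to_matrix(b$quat)
  d <- b$center - a$center
  axes <- cbind(Ra, Rb)
  for (i in 1:3) {
    for (j in 1:3) {
      cr <- c(Ra[2, i] * Rb[3, j] - Ra[3, i] * Rb[2, j],
              Ra[3, i] * Rb[1, j] - Ra[1, i] * Rb[3, j],
              Ra[1, i] * Rb[2, j] - Ra[2, i] * Rb[1, j])
      if (sum(cr^2) > 1e-12) axes <- cbind(axes, cr / sqrt(sum(cr^2)))
    }
  }
  for (k in seq_len(ncol(axes))) {
    u <- axes[, k]
    ra <- sum(abs(crossprod(u, Ra)) * a$half_extents)
    rb <- sum(abs(crossprod(u, Rb)) * b$half_extents)
    if (abs(sum(u * d)) > ra + rb + 1e-12) return(FALSE)
  }
  TRUE
}

# small test configuration (quiet about the sub-40 nm warning)
test_config <- function(...) {
  suppressWarnings(sim_config(...))
}
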
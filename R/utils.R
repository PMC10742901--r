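unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-300) abort("cannot normalise a zero vector", class = "polymc_degenerate")
  v / n
}

# uniform random direction on the unit sphere
random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n2 <- sum(v * v)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# random unit vector perpendicular to unit vector v
perp_unit <- function(v) {
  repeat {
    e <- rnorm(3)
    e <- e - sum(e * v) * v
    n2 <- sum(e * e)
    if (n2 > 1e-12) return(e / sqrt(n2))
  }
}

#' Hash of the physical state of a simulation box
#'
#' Digest of bead positions, orientations, sizes, polymer membership and
#' bonds.  Two boxes with identical hashes are physically identical; the
#' step counter and bookkeeping counters are deliberately excluded, so a
#' reverted Monte Carlo step leaves the hash unchanged.
#'
#' @param box A simulation box (see [init_box()]).
#' @return A character scalar.
#' @export
state_hash <- function(box) {
  stopifnot(inherits(box, "mc_box"))
  rlang::hash(list(box$pos, box$quat, box$half, box$polymer_id, box$bonds))
}

# beads incident to bead i in a 2-column bond matrix
incident_beads <- function(bonds, i) {
  if (nrow(bonds) == 0L) return(integer())
  c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
}

# index of the bond row joining i and j (either order), or NA
bond_row <- function(bonds, i, j) {
  hit <- which((bonds[, 1] == i & bonds[, 2] == j) |
                 (bonds[, 1] == j & bonds[, 2] == i))
  if (length(hit)) hit[[1L]] else NA_integer_
}

# connected component containing `start` in an edge list (vector ids)
component_from <- function(bonds, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- integer()
    for (b in frontier) nxt <- c(nxt, incident_beads(bonds, b))
    nxt <- setdiff(unique(nxt), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}
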
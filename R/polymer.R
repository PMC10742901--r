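#' Polymer bond-graph object
#'
#' A polymer is a connected acyclic bond graph (a tree) over bead ids;
#' free monomers are single-bead polymers with no bonds, so conservation
#' and parameter lookup are uniform across species.
#'
#' @param bead_ids Integer vector of bead ids (unique).
#' @param bonds Two-column matrix/data frame of unordered bead-id pairs,
#'   or `NULL` for a single bead.  Must form a spanning tree of
#'   `bead_ids`.
#' @param id Integer polymer identifier.
#' @return An object of class `polymer`.
#' @examples
#' p <- polymer(1:4, cbind(1:3, 2:4)) # linear 4-chain
#' polymer_length(p)
#' backbone_length(p)
#' @export
polymer <- function(bead_ids, bonds = NULL, id = 1L) {
  bead_ids <- as.integer(bead_ids)
  if (anyDuplicated(bead_ids)) abort("duplicate bead ids", class = "polymc_domain")
  if (is.null(bonds)) {
    bonds <- matrix(integer(), 0, 2)
  } else {
    bonds <- as.matrix(bonds)
    storage.mode(bonds) <- "integer"
  }
  p <- structure(list(id = as.integer(id), bead_ids = bead_ids, bonds = bonds),
                 class = "polymer")
  err <- check_tree(bead_ids, bonds)
  if (!is.null(err)) abort(err, class = "polymc_domain")
  p
}

# NULL if (bead_ids, bonds) is a tree, else a message
check_tree <- function(bead_ids, bonds) {
  k <- length(bead_ids)
  if (nrow(bonds) != k - 1L) {
    return(sprintf("bond graph is not a tree: %d beads need %d bonds, got %d",
                   k, k - 1L, nrow(bonds)))
  }
  if (nrow(bonds) > 0 && !all(c(bonds) %in% bead_ids)) {
    return("bond endpoints outside the polymer's bead set")
  }
  if (length(component_from(bonds, bead_ids[1L])) != k &&
      k > 1L) {
    return("bond graph is disconnected")
  }
  NULL
}

#' Total polymer length in monomers
#'
#' @param p A [polymer()].
#' @return Integer bead count.
#' @export
polymer_length <- function(p) {
  stopifnot(inherits(p, "polymer"))
  length(p$bead_ids)
}

#' Backbone length of a polymer
#'
#' The number of monomers on the longest simple path through the bond
#' tree (the tree diameter counted in vertices), the standard backbone
#' proxy for acyclic coarse-grained polymers.  Equals
#' [polymer_length()] exactly when the polymer is an unbranched chain.
#'
#' @param p A [polymer()].
#' @return Integer path length in monomers (1 for a free monomer).
#' @examples
#' backbone_length(polymer(1:5, cbind(1:4, 2:5))) # 5
#' @export
backbone_length <- function(p) {
  stopifnot(inherits(p, "polymer"))
  backbone_from_bonds(p$bead_ids, p$bonds)
}

# tree diameter in vertices by double breadth-first search
backbone_from_bonds <- function(bead_ids, bonds) {
  k <- length(bead_ids)
  if (k <= 2L) return(k)
  idx <- seq_len(k)
  names(idx) <- as.character(bead_ids)
  a <- idx[as.character(bonds[, 1])]
  b <- idx[as.character(bonds[, 2])]
  adj <- vector("list", k)
  for (r in seq_along(a)) {
    adj[[a[r]]] <- c(adj[[a[r]]], b[r])
    adj[[b[r]]] <- c(adj[[b[r]]], a[r])
  }
  far <- bfs_farthest(adj, 1L)
  bfs_farthest(adj, far$node)$dist + 1L
}

bfs_farthest <- function(adj, start) {
  k <- length(adj)
  dist <- rep.int(-1L, k)
  dist[start] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (dist[u] < 0L) {
          dist[u] <- dist[v] + 1L
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  node <- which.max(dist)
  list(node = node, dist = dist[node])
}

#' @export
print.polymer <- function(x, ...) {
  cat(sprintf("<polymer #%d> %d beads, %d bonds, backbone %d\n",
              x$id, length(x$bead_ids), nrow(x$bonds), backbone_length(x)))
  invisible(x)
}

#' @export
format.polymer <- function(x, ...) {
  sprintf("polymer #%d (%d beads)", x$id, length(x$bead_ids))
}
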
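new_mc_box <- function(pos, quat, half, polymer_id, bonds, edge,
                       step_count = 0L, next_polymer_id = NULL,
                       counters = NULL) {
  counters <- counters %||% c(accepted = 0L, reverted = 0L, combination = 0L,
                              breakdown = 0L, none = 0L)
  structure(list(
    pos = pos, quat = quat, half = half,
    polymer_id = as.integer(polymer_id),
    bonds = bonds, edge = as.numeric(edge),
    step_count = as.integer(step_count),
    next_polymer_id = as.integer(next_polymer_id %||%
                                   (max(polymer_id, 0L) + 1L)),
    counters = counters
  ), class = "mc_box")
}

#' Assemble a simulation box from a bead table
#'
#' Builds an `mc_box` from per-bead records; mostly useful for tests and
#' for reconstructing states from trajectory tables.  [init_box()] is the
#' normal entry point.
#'
#' @param beads Data frame with columns `x`, `y`, `z`, `polymer_id`, and
#'   optionally `qw`, `qx`, `qy`, `qz` (identity orientation assumed when
#'   absent).
#' @param bonds Two-column matrix or data frame of bonded bead row
#'   indices (may be empty).
#' @param edge Box edge lengths, nm (scalar or length 3).
#' @param half_extents Bead cuboid half-extents, nm: length 3, or an
#'   n x 3 matrix.
#' @return An object of class `mc_box`.
#' @export
mc_box <- function(beads, bonds = NULL, edge,
                   half_extents = default_half_extents()) {
  stopifnot(is.data.frame(beads), all(c("x", "y", "z", "polymer_id") %in% names(beads)))
  n <- nrow(beads)
  pos <- cbind(beads$x, beads$y, beads$z)
  if (all(c("qw", "qx", "qy", "qz") %in% names(beads))) {
    quat <- cbind(beads$qw, beads$qx, beads$qy, beads$qz)
  } else {
    quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  }
  half <- if (is.matrix(half_extents)) half_extents else
    matrix(rep(half_extents, each = n), n, 3)
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "integer"
  dimnames(bonds) <- NULL
  if (length(edge) == 1) edge <- rep(edge, 3)
  new_mc_box(pos, quat, half, beads$polymer_id, bonds, edge)
}

#' @export
as_tibble.mc_box <- function(x, ...) {
  b <- x # the x/y/z columns would shadow the argument inside tibble()
  tibble(bead = seq_len(nrow(b$pos)),
         polymer_id = b$polymer_id,
         x = b$pos[, 1], y = b$pos[, 2], z = b$pos[, 3],
         qw = b$quat[, 1], qx = b$quat[, 2], qy = b$quat[, 3],
         qz = b$quat[, 4])
}

#' Bonds of a simulation box as a tibble
#'
#' @param box An `mc_box`.
#' @return A tibble with columns `from`, `to` (bead row indices).
#' @export
box_bonds <- function(box) {
  stopifnot(inherits(box, "mc_box"))
  tibble(from = box$bonds[, 1], to = box$bonds[, 2])
}

#' Extract one polymer from a box
#'
#' @param box An `mc_box`.
#' @param pid Polymer id.
#' @return A [polymer()].
#' @export
get_polymer <- function(box, pid) {
  stopifnot(inherits(box, "mc_box"))
  members <- which(box$polymer_id == pid)
  if (!length(members)) abort(sprintf("no polymer with id %d", pid),
                              class = "polymc_domain")
  sub <- box$bonds[box$polymer_id[box$bonds[, 1]] == pid, , drop = FALSE]
  polymer(members, if (nrow(sub)) sub else NULL, id = pid)
}

#' Per-polymer topology statistics
#'
#' Length (bead count) and backbone length of every polymer currently in
#' the box, free monomers included as length-1 polymers.
#'
#' @param box An `mc_box`.
#' @return A tibble with columns `polymer_id`, `length`, `backbone`.
#' @export
polymer_stats <- function(box) {
  stopifnot(inherits(box, "mc_box"))
  pid <- box$polymer_id
  sizes <- table(pid)
  ids <- as.integer(names(sizes))
  bond_pid <- if (nrow(box$bonds)) pid[box$bonds[, 1]] else integer()
  backbone <- integer(length(ids))
  for (k in seq_along(ids)) {
    len <- sizes[[k]]
    if (len <= 2L) {
      backbone[k] <- len
    } else {
      members <- which(pid == ids[k])
      sub <- box$bonds[bond_pid == ids[k], , drop = FALSE]
      backbone[k] <- backbone_from_bonds(members, sub)
    }
  }
  tibble(polymer_id = ids, length = as.integer(sizes), backbone = backbone)
}

#' Check all structural invariants of a simulation box
#'
#' Verifies that every bead cuboid lies inside the box, that no
#' non-bonded bead pair overlaps (GJK distance below the contact
#' tolerance), that every bond joins beads of one polymer, that each
#' polymer's bond graph is a tree, and that orientations are unit
#' quaternions with positive half-extents.
#'
#' @param box An `mc_box`.
#' @param contact_tol Contact tolerance for the collision predicate, nm.
#' @return A tibble of violations with columns `rule`, `ids`,
#'   `message`; zero rows when the box is valid.
#' @export
validate_box <- function(box, contact_tol = 1e-9) {
  stopifnot(inherits(box, "mc_box"))
  bad <- list()
  n <- nrow(box$pos)
  qn <- abs(sqrt(rowSums(box$quat^2)) - 1) > 1e-9
  if (any(qn)) {
    bad[[length(bad) + 1L]] <- tibble(rule = "orientation",
                                      ids = paste(which(qn), collapse = ","),
                                      message = "non-unit quaternion")
  }
  hneg <- rowSums(box$half <= 0) > 0
  if (any(hneg)) {
    bad[[length(bad) + 1L]] <- tibble(rule = "half_extents",
                                      ids = paste(which(hneg), collapse = ","),
                                      message = "non-positive half-extents")
  }
  chk <- cpp_validate_collisions(box$pos, box$quat, box$half, box$bonds,
                                 box$edge, contact_tol)
  if (length(chk$oob)) {
    bad[[length(bad) + 1L]] <- tibble(rule = "bounds",
                                      ids = paste(chk$oob, collapse = ","),
                                      message = "bead outside the box")
  }
  if (nrow(chk$pairs)) {
    bad[[length(bad) + 1L]] <- tibble(
      rule = "collision",
      ids = apply(chk$pairs, 1, paste, collapse = "-"),
      message = "non-bonded beads overlap")
  }
  if (nrow(box$bonds)) {
    span <- box$polymer_id[box$bonds[, 1]] != box$polymer_id[box$bonds[, 2]]
    if (any(span)) {
      bad[[length(bad) + 1L]] <- tibble(
        rule = "bond_span",
        ids = apply(box$bonds[span, , drop = FALSE], 1, paste, collapse = "-"),
        message = "bond joins beads of different polymers")
    }
  }
  pid <- box$polymer_id
  bond_pid <- if (nrow(box$bonds)) pid[box$bonds[, 1]] else integer()
  for (id in unique(pid)) {
    members <- which(pid == id)
    sub <- box$bonds[bond_pid == id, , drop = FALSE]
    err <- check_tree(members, sub)
    if (!is.null(err)) {
      bad[[length(bad) + 1L]] <- tibble(rule = "tree",
                                        ids = as.character(id), message = err)
    }
  }
  if (length(bad)) bind_rows(bad) else
    tibble(rule = character(), ids = character(), message = character())
}

#' @export
print.mc_box <- function(x, ...) {
  sizes <- table(x$polymer_id)
  cat(sprintf(
    "<mc_box> %.3g x %.3g x %.3g nm, %d beads in %d polymers (largest %d), step %d\n",
    x$edge[1], x$edge[2], x$edge[3], nrow(x$pos), length(sizes),
    max(as.integer(sizes)), x$step_count))
  invisible(x)
}
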
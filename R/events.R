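#' Combination event: join two polymers at an activated bead
#'
#' Implements the combination scenarios of the chemical-events model.
#' The activated bead `activation` (hit by the radical) bonds to
#' `partner`, a bead of another polymer found within the capture radius:
#'
#' * `extend` -- the activation bead is terminal (degree <= 1); its whole
#'   polymer joins the partner's polymer and the chain grows (this also
#'   covers a terminal bead attaching as a single branch of a larger
#'   structure).
#' * `branch` -- the activation bead is internal; its polymer attaches
#'   through it, splitting into two branches at the activation point.
#' * `swap` -- one bond incident to the activation bead is cut and only
#'   the detached portion containing the activation bead joins the
#'   partner's polymer; the remainder stays behind as a separate polymer.
#'
#' With `scenario = "auto"` (the engine's choice) a terminal activation
#' bead always extends, and an internal one branches or swaps with equal
#' probability.  The moved component is rigidly translated so the new
#' bond has length `bond_length`, and rotated so the bond angle at each
#' junction that gains three consecutive beads is `bond_angle` (azimuth
#' random).  Joining beads of one polymer would create a cycle; the event
#' is then rejected and the box returned unchanged with attribute
#' `rejected = "cycle"`.
#'
#' @param box An `mc_box`.
#' @param activation,partner Bead row indices; must belong to different
#'   polymers.
#' @param scenario Scenario override, or `"auto"` for topology-driven
#'   dispatch.
#' @param cut For `swap`: the neighbour of `activation` whose bond is
#'   cut; a uniformly random incident bond when `NULL`.
#' @param bond_length New bond length, nm.
#' @param bond_angle Junction bond angle, degrees (tetrahedral carbon
#'   default 109.5).
#' @return The updated `mc_box`, with attribute `scenario` naming the
#'   dispatched case.
#' @export
combine_polymers <- function(box, activation, partner,
                             scenario = c("auto", "extend", "branch", "swap"),
                             cut = NULL, bond_length = 0.5,
                             bond_angle = 109.5) {
  scenario <- match.arg(scenario)
  pa <- box$polymer_id[activation]
  pb <- box$polymer_id[partner]
  if (pa == pb) {
    attr(box, "rejected") <- "cycle"
    return(box)
  }
  nbrs_a <- incident_beads(box$bonds, activation)
  deg_a <- length(nbrs_a)
  if (scenario == "auto") {
    scenario <- if (deg_a <= 1L) "extend"
    else if (runif(1) < 0.5) "branch" else "swap"
  }
  if (scenario == "swap" && deg_a == 0L) {
    abort("swap requires a bond incident to the activation bead",
          class = "polymc_domain")
  }
  bonds <- box$bonds
  pid <- box$polymer_id
  rem_nbrs <- nbrs_a
  if (scenario == "swap") {
    cut <- cut %||% nbrs_a[[sample.int(deg_a, 1L)]]
    if (!cut %in% nbrs_a) {
      abort("`cut` must be a neighbour of the activation bead",
            class = "polymc_domain")
    }
    bonds <- bonds[-bond_row(bonds, activation, cut), , drop = FALSE]
    sub <- bonds[pid[bonds[, 1]] == pa, , drop = FALSE]
    move_ids <- component_from(sub, activation)
    rem_nbrs <- setdiff(nbrs_a, cut)
  } else {
    move_ids <- which(pid == pa)
  }
  pid[move_ids] <- pb
  bonds <- rbind(bonds, c(activation, partner))

  # geometry: place the moved component at bond distance from the partner,
  # honouring the bond angle at both junctions where defined
  theta <- bond_angle * pi / 180
  pos <- box$pos
  quat <- box$quat
  b_ctr <- pos[partner, ]
  nbrs_b <- incident_beads(box$bonds, partner)
  if (length(nbrs_b)) {
    ref <- unit3(pos[nbrs_b[[sample.int(length(nbrs_b), 1L)]], ] - b_ctr)
    u <- cos(theta) * ref + sin(theta) * perp_unit(ref)
  } else {
    u <- random_unit_vector()
  }
  target_a <- b_ctr + bond_length * u
  shift <- target_a - pos[activation, ]
  pos[move_ids, ] <- pos[move_ids, , drop = FALSE] +
    rep(shift, each = length(move_ids))
  if (length(rem_nbrs)) {
    na1 <- rem_nbrs[[sample.int(length(rem_nbrs), 1L)]]
    w <- unit3(pos[na1, ] - target_a)
    wp <- cos(theta) * (-u) + sin(theta) * perp_unit(u)
    rot <- rotation_between(w, wp)
    if (rot$angle > 1e-12) {
      R <- rotation_about(rot$axis, rot$angle)
      rel <- t(R %*% (t(pos[move_ids, , drop = FALSE]) - target_a))
      pos[move_ids, ] <- rel + rep(target_a, each = length(move_ids))
      q <- quat_from_axis_angle(rot$axis, rot$angle)
      quat[move_ids, ] <- quat_rows_rotate(q, quat[move_ids, , drop = FALSE])
    }
  }
  box$pos <- pos
  box$quat <- quat
  box$polymer_id <- pid
  box$bonds <- bonds
  attr(box, "scenario") <- scenario
  box
}

#' Breakdown event: cut a polymer at a bond
#'
#' Removes the bond between `from` and `to`, splitting the polymer into
#' exactly two trees.  The component containing `to` is detached and
#' receives a fresh polymer id; the component containing `from` keeps the
#' original id.  Bead coordinates are unchanged -- separation, if any,
#' happens through subsequent rigid-body moves.
#'
#' @param box An `mc_box`.
#' @param from,to Bead row indices of an existing bond.
#' @return The updated `mc_box`, with attribute `detached` holding the
#'   new polymer id.
#' @export
breakdown_polymer <- function(box, from, to) {
  r <- bond_row(box$bonds, from, to)
  if (is.na(r)) {
    abort(sprintf("no bond between beads %d and %d", from, to),
          class = "polymc_domain")
  }
  pa <- box$polymer_id[from]
  bonds <- box$bonds[-r, , drop = FALSE]
  sub <- bonds[box$polymer_id[bonds[, 1]] == pa, , drop = FALSE]
  detached <- component_from(sub, to)
  new_id <- box$next_polymer_id
  box$polymer_id[detached] <- new_id
  box$next_polymer_id <- new_id + 1L
  box$bonds <- bonds
  attr(box, "detached") <- new_id
  box
}
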
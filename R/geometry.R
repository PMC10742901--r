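# --- quaternion helpers (w, x, y, z; Hamilton convention) ------------------

quat_from_axis_angle <- function(axis, angle) {
  axis <- unit3(axis)
  c(cos(angle / 2), sin(angle / 2) * axis)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

# left-compose one rotation quaternion q with every row of Q (n x 4)
quat_rows_rotate <- function(q, Q) {
  W <- Q[, 1]; X <- Q[, 2]; Y <- Q[, 3]; Z <- Q[, 4]
  out <- cbind(
    q[1] * W - q[2] * X - q[3] * Y - q[4] * Z,
    q[1] * X + q[2] * W + q[3] * Z - q[4] * Y,
    q[1] * Y - q[2] * Z + q[3] * W + q[4] * X,
    q[1] * Z + q[2] * Y - q[3] * X + q[4] * W
  )
  out / sqrt(rowSums(out^2)) # renormalise against drift
}

# rotation matrix from quaternion composition path kept in one place
rotation_about <- function(axis, angle) quat_to_matrix(quat_from_axis_angle(axis, angle))

# shortest rotation taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v * v))
  d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(list(axis = c(1, 0, 0), angle = 0))
    return(list(axis = perp_unit(a), angle = pi)) # antiparallel
  }
  list(axis = v / s, angle = atan2(s, d))
}

check_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != 3) ||
      max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    abort("orientation must be a proper rotation (orthonormal, det +1)",
          class = "polymc_domain")
  }
  invisible(R)
}

# --- convex shapes ---------------------------------------------------------

#' Oriented cuboid bead shape
#'
#' Constructs the convex shape of one coarse-grained bead: a cuboid with a
#' centre, strictly positive half-extents and a proper rotation
#' orientation.
#'
#' @param center Numeric length-3 centre, nm.
#' @param half_extents Numeric length-3 half edge lengths, nm (all `> 0`).
#' @param orientation A 3x3 proper rotation matrix, or a length-4 unit
#'   quaternion `(w, x, y, z)`.  Identity by default.
#' @return An object of class `cuboid`.
#' @examples
#' cuboid(c(0, 0, 0), c(0.5, 0.5, 0.5))
#' @export
cuboid <- function(center = c(0, 0, 0), half_extents = c(0.5, 0.5, 0.5),
                   orientation = NULL) {
  stopifnot(length(center) == 3, length(half_extents) == 3)
  if (any(!is.finite(half_extents)) || any(half_extents <= 0)) {
    abort("half_extents must be strictly positive", class = "polymc_degenerate")
  }
  if (is.null(orientation)) {
    q <- c(1, 0, 0, 0)
  } else if (is.matrix(orientation)) {
    check_rotation(orientation)
    q <- quat_from_matrix(orientation)
  } else {
    stopifnot(length(orientation) == 4)
    q <- orientation / sqrt(sum(orientation^2))
  }
  structure(list(center = as.numeric(center),
                 half_extents = as.numeric(half_extents), quat = q),
            class = "cuboid")
}

quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' World-frame corner vertices of a cuboid
#'
#' @param x A [cuboid()].
#' @return An 8 x 3 numeric matrix of corner coordinates, nm.
#' @export
cuboid_vertices <- function(x) {
  stopifnot(inherits(x, "cuboid"))
  R <- quat_to_matrix(x$quat)
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  corners <- signs * rep(x$half_extents, each = 8)
  t(R %*% t(corners)) + rep(x$center, each = 8)
}

as_vertex_matrix <- function(x, arg = "shape") {
  if (inherits(x, "cuboid")) return(cuboid_vertices(x))
  if (is.matrix(x) && ncol(x) == 3 && nrow(x) >= 4) {
    ctr <- sweep(x, 2, colMeans(x))
    sv <- svd(ctr, nu = 0, nv = 0)$d
    if (sv[3] < 1e-12 * max(sv[1], 1)) {
      abort(paste0("`", arg, "` is degenerate (zero volume)"),
            class = "polymc_degenerate")
    }
    return(x)
  }
  abort(paste0("`", arg, "` must be a cuboid or an n x 3 vertex matrix"),
        class = "polymc_domain")
}

#' Shortest distance between two convex bodies (GJK)
#'
#' Gilbert-Johnson-Keerthi distance between the convex hulls of two
#' shapes, used as the collision feasibility predicate for bead cuboids.
#' The implementation iterates support mappings over the Minkowski
#' difference with a simplex closest-point reduction; it terminates at
#' `tol` (default 1e-10 nm) or after `maxit` iterations.
#'
#' @param a,b A [cuboid()] or an n x 3 matrix of vertices (n >= 4,
#'   spanning a 3-D volume).
#' @param tol Convergence tolerance, nm.
#' @param maxit Maximum GJK iterations.
#' @return Non-negative distance in nm; exactly 0 when the hulls
#'   intersect or touch.
#' @examples
#' a <- cuboid(c(0, 0, 0), c(0.5, 0.5, 0.5))
#' b <- cuboid(c(2, 0, 0), c(0.5, 0.5, 0.5))
#' gjk_distance(a, b) # 1
#' @export
gjk_distance <- function(a, b, tol = 1e-10, maxit = 64L) {
  A <- as_vertex_matrix(a, "a")
  B <- as_vertex_matrix(b, "b")
  cpp_gjk_vertices(A, B, tol, as.integer(maxit))
}

# --- rigid-body moves ------------------------------------------------------

beads_centers <- function(beads) {
  if (is.matrix(beads)) {
    stopifnot(ncol(beads) == 3)
    return(beads)
  }
  if (is.data.frame(beads)) {
    stopifnot(all(c("x", "y", "z") %in% names(beads)))
    return(cbind(beads$x, beads$y, beads$z))
  }
  abort("`beads` must be a data frame with x/y/z or an n x 3 matrix",
        class = "polymc_domain")
}

#' Scalar moment of inertia of a bead cluster
#'
#' `sum(m_i r_i^2)` with `r_i` the distance of each bead centre from the
#' cluster centre of mass.  Beads carry unit monomer masses by default,
#' so the unit is monomer nm^2.  This scalar drives the size scaling of
#' rigid-body move proposals: bulky structures rotate less.
#'
#' @param beads Bead centres: a data frame with `x`, `y`, `z` columns or
#'   an n x 3 matrix.
#' @param masses Optional per-bead masses (default all 1).
#' @return Non-negative scalar.
#' @examples
#' moment_of_inertia(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)) # 0.5
#' @export
moment_of_inertia <- function(beads, masses = NULL) {
  ctr <- beads_centers(beads)
  m <- masses %||% rep(1, nrow(ctr))
  stopifnot(length(m) == nrow(ctr))
  com <- colSums(ctr * m) / sum(m)
  sum(m * rowSums(sweep(ctr, 2, com)^2))
}

#' Propose a random rigid-body move
#'
#' Draws a rotation about a uniformly random axis through the centre of
#' mass and a translation in a uniformly random direction.  The rotation
#' angle is Uniform(0, theta_max) with `theta_max = pi / (1 + I / I_0)`
#' (I the scalar [moment_of_inertia()]), and the translation magnitude is
#' Uniform(0, d_max) with
#' `d_max = min(6 L_edge, d_0 / sqrt(1 + N / N_0))`, `L_edge` the longest
#' cuboid edge among the moved beads and `N` the bead count -- so a move
#' never exceeds six times the longest edge, and large structures both
#' rotate and translate less.
#'
#' @inheritParams moment_of_inertia
#' @param half_extents Cuboid half-extents of the moved beads: length-3
#'   vector or n x 3 matrix (default: the package's standard bead size).
#' @param theta_I0 Inertia scale `I_0` for the rotation cap,
#'   monomer nm^2.
#' @param d_0 Translation scale, nm.
#' @param N_0 Bead-count scale for the translation cap.
#' @return A `rigid_move`: list with `axis`, `angle`, `translation`,
#'   `pivot` (centre of mass) and the caps used.
#' @examples
#' set.seed(1)
#' propose_move(matrix(rnorm(9), 3, 3))
#' @export
propose_move <- function(beads, half_extents = NULL, theta_I0 = 10,
                         d_0 = 2, N_0 = 10) {
  ctr <- beads_centers(beads)
  half <- half_extents %||% default_half_extents()
  structure(propose_core(ctr, 2 * max(half), theta_I0, d_0, N_0),
            class = "rigid_move")
}

# shared proposal core (also the engine fast path); unit bead masses
propose_core <- function(ctr, l_edge, theta_I0, d_0, N_0) {
  n <- nrow(ctr)
  com <- c(sum(ctr[, 1]), sum(ctr[, 2]), sum(ctr[, 3])) / n
  inertia <- sum((ctr[, 1] - com[1])^2 + (ctr[, 2] - com[2])^2 +
                   (ctr[, 3] - com[3])^2)
  theta_max <- pi / (1 + inertia / theta_I0)
  d_max <- min(6 * l_edge, d_0 / sqrt(1 + n / N_0))
  axis <- random_unit_vector()
  angle <- runif(1, 0, theta_max)
  direction <- random_unit_vector()
  magnitude <- runif(1, 0, d_max)
  list(axis = axis, angle = angle, translation = direction * magnitude,
       pivot = com, theta_max = theta_max, d_max = d_max)
}

# rotate points (rows) about pivot then translate
move_points <- function(pts, axis, angle, pivot, translation) {
  R <- rotation_about(axis, angle)
  k <- nrow(pts)
  shift <- rep(pivot, each = k)
  (pts - shift) %*% t(R) + shift + rep(translation, each = k)
}

#' Apply a rigid-body move to beads
#'
#' Rotates bead centres about the move's pivot, composes bead
#' orientations with the move rotation, then translates.  Intra-cluster
#' distances are preserved (rigidity).
#'
#' @param beads A data frame with columns `x`, `y`, `z` and optionally
#'   quaternion columns `qw`, `qx`, `qy`, `qz`, or an n x 3 matrix of
#'   centres.
#' @param move A `rigid_move` from [propose_move()], or any list with
#'   `axis`, `angle`, `translation` and `pivot`.
#' @return Beads of the same shape as the input, moved.
#' @export
apply_move <- function(beads, move) {
  ctr <- beads_centers(beads)
  moved <- move_points(ctr, move$axis, move$angle, move$pivot,
                       move$translation)
  if (is.matrix(beads)) return(moved)
  out <- beads
  out$x <- moved[, 1]; out$y <- moved[, 2]; out$z <- moved[, 3]
  if (all(c("qw", "qx", "qy", "qz") %in% names(beads))) {
    q <- quat_from_axis_angle(move$axis, move$angle)
    Q <- quat_rows_rotate(q, cbind(beads$qw, beads$qx, beads$qy, beads$qz))
    out$qw <- Q[, 1]; out$qx <- Q[, 2]; out$qy <- Q[, 3]; out$qz <- Q[, 4]
  }
  out
}

default_half_extents <- function() c(0.30, 0.225, 0.20)

#' @export
print.rigid_move <- function(x, ...) {
  cat(sprintf("<rigid_move> angle %.3f rad about (%.2f, %.2f, %.2f), |t| = %.3f nm\n",
              x$angle, x$axis[1], x$axis[2], x$axis[3],
              sqrt(sum(x$translation^2))))
  invisible(x)
}
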
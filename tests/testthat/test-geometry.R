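random_unit_vector_test <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

test_that("GJK reproduces analytic cuboid distances", {
  u <- cuboid(c(0, 0, 0), c(0.5, 0.5, 0.5))
  expect_equal(gjk_distance(u, cuboid(c(2, 0, 0), c(0.5, 0.5, 0.5))), 1)
  expect_equal(gjk_distance(u, cuboid(c(0.5, 0.2, 0), c(0.5, 0.5, 0.5))), 0)
  expect_equal(gjk_distance(u, u), 0)
  # exactly touching faces count as contact
  expect_equal(gjk_distance(u, cuboid(c(1, 0, 0), c(0.5, 0.5, 0.5))), 0)
  # unit cube vs 45-degree rotated unit cube, centres 2 apart on x:
  # nearest feature is the rotated cube's edge at x = 2 - sqrt(2)/2
  r45 <- polymc:::quat_from_axis_angle(c(0, 0, 1), pi / 4)
  d <- gjk_distance(u, cuboid(c(2, 0, 0), c(0.5, 0.5, 0.5), r45))
  expect_equal(d, 1.5 - sqrt(2) / 2, tolerance = 1e-9)
  # degenerate (flat) vertex sets are rejected
  flat <- cbind(expand.grid(c(0, 1), c(0, 1)), 0)
  expect_error(gjk_distance(as.matrix(flat), cuboid_vertices(u)),
               class = "polymc_degenerate")
  expect_error(cuboid(c(0, 0, 0), c(0.5, 0, 0.5)),
               class = "polymc_degenerate")
})

test_that("GJK distance is symmetric and rigid-motion equivariant", {
  set.seed(5)
  for (rep in 1:40) {
    a <- random_cuboid()
    b <- random_cuboid()
    d <- gjk_distance(a, b)
    expect_gte(d, 0)
    expect_equal(gjk_distance(b, a), d, tolerance = 1e-9)
    # common translation
    t3 <- runif(3, -5, 5)
    at <- cuboid(a$center + t3, a$half_extents, a$quat)
    bt <- cuboid(b$center + t3, b$half_extents, b$quat)
    expect_equal(gjk_distance(at, bt), d, tolerance = 1e-8)
    # common rotation about the origin
    q <- polymc:::quat_from_axis_angle(random_unit_vector_test(),
                                       runif(1, 0, pi))
    R <- polymc:::quat_to_matrix(q)
    ar <- cuboid(c(R %*% a$center), a$half_extents, polymc:::quat_mul(q, a$quat))
    br <- cuboid(c(R %*% b$center), b$half_extents, polymc:::quat_mul(q, b$quat))
    expect_equal(gjk_distance(ar, br), d, tolerance = 1e-8)
    # shrinking both shapes about their centres cannot decrease distance
    as_ <- cuboid(a$center, a$half_extents * 0.5, a$quat)
    bs_ <- cuboid(b$center, b$half_extents * 0.5, b$quat)
    expect_gte(gjk_distance(as_, bs_), d - 1e-9)
  }
})

test_that("GJK matches the dense-sampling oracle and the SAT classifier", {
  set.seed(7)
  for (rep in 1:40) {
    a <- random_cuboid(center_range = 1.2)
    b <- random_cuboid(center_range = 1.2)
    d <- gjk_distance(a, b)
    hit <- sat_intersects(a, b)
    expect_identical(d == 0, hit)
    if (!hit) {
      expect_lt(abs(d - sampling_distance_oracle(a, b, g = 40)), 1e-2)
    }
  }
})

test_that("moment of inertia matches direct summation", {
  expect_equal(moment_of_inertia(matrix(c(3, 1, 2), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(moment_of_inertia(two), 0.5)
  set.seed(9)
  pts <- matrix(rnorm(30), 10, 3)
  com <- colMeans(pts)
  direct <- 0
  for (i in 1:10) direct <- direct + sum((pts[i, ] - com)^2)
  expect_equal(moment_of_inertia(pts), direct, tolerance = 1e-12)
  # invariant under a rigid move of the whole set
  set.seed(10)
  mv <- propose_move(pts)
  expect_equal(moment_of_inertia(apply_move(pts, mv)),
               moment_of_inertia(pts), tolerance = 1e-9)
})

test_that("move proposals respect their caps and replay deterministically", {
  set.seed(21)
  for (rep in 1:500) {
    k <- sample(1:20, 1)
    pts <- matrix(runif(3 * k, 0, 5), k, 3)
    mv <- propose_move(pts)
    expect_lte(sqrt(sum(mv$translation^2)),
               6 * 2 * max(polymc:::default_half_extents()) + 1e-12)
    expect_lte(sqrt(sum(mv$translation^2)), mv$d_max + 1e-12)
    expect_lte(mv$angle, mv$theta_max)
    expect_gte(mv$angle, 0)
  }
  pts <- matrix(runif(9), 3, 3)
  set.seed(33); m1 <- propose_move(pts)
  set.seed(33); m2 <- propose_move(pts)
  expect_identical(m1, m2)
})

test_that("proposal axes are uniform on the sphere", {
  set.seed(77)
  z <- replicate(4000, propose_move(matrix(0, 1, 3))$axis[3])
  # for a uniform sphere direction the z component is Uniform(-1, 1)
  counts <- table(cut(z, breaks = seq(-1, 1, length.out = 11)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("applying a move is rigid and composes orientations", {
  pts <- matrix(runif(15), 5, 3)
  idm <- list(axis = c(1, 0, 0), angle = 0, translation = c(0, 0, 0),
              pivot = c(0, 0, 0))
  expect_equal(apply_move(pts, idm), pts)
  tr <- list(axis = c(1, 0, 0), angle = 0, translation = c(1, 0, 0),
             pivot = c(0.3, 0.1, 0))
  expect_equal(apply_move(pts, tr), pts + rep(c(1, 0, 0), each = 5))
  set.seed(12)
  beads <- tibble::tibble(x = runif(6), y = runif(6), z = runif(6),
                          qw = 1, qx = 0, qy = 0, qz = 0)
  mv <- propose_move(beads)
  out <- apply_move(beads, mv)
  d0 <- dist(cbind(beads$x, beads$y, beads$z))
  d1 <- dist(cbind(out$x, out$y, out$z))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  expect_equal(rowSums(cbind(out$qw, out$qx, out$qy, out$qz)^2), rep(1, 6),
               tolerance = 1e-9)
})
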
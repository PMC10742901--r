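test_that("box construction and bead-table round trip", {
  box <- chain_box(c(3, 1))
  tb <- tibble::as_tibble(box)
  expect_equal(nrow(tb), 4)
  expect_named(tb, c("bead", "polymer_id", "x", "y", "z",
                     "qw", "qx", "qy", "qz"))
  rebuilt <- mc_box(tb, as.matrix(box_bonds(box)), edge = box$edge)
  expect_identical(state_hash(rebuilt), state_hash(box))
})

test_that("initialisation fills the box with the configured species mix", {
  cfg <- test_config(box_edge = 12, n_molecules = 80, seed = 1)
  set.seed(4)
  box <- init_box(cfg)
  sizes <- table(polymer_stats(box)$length)
  # 80 molecules: equal thirds with the remainder to monomers
  expect_equal(as.integer(sizes[c("1", "2", "3")]), c(28L, 26L, 26L))
  expect_equal(length(unique(box$polymer_id)), 80)
  expect_equal(nrow(box$pos), 28 + 2 * 26 + 3 * 26)
  # fresh boxes validate clean
  expect_equal(nrow(validate_box(box)), 0)
  # dimer bond lengths and trimer internal angles are exact
  ps <- polymer_stats(box)
  tri <- ps$polymer_id[ps$length == 3][1]
  members <- which(box$polymer_id == tri)
  mid <- members[2]
  v1 <- box$pos[members[1], ] - box$pos[mid, ]
  v2 <- box$pos[members[3], ] - box$pos[mid, ]
  expect_equal(sqrt(sum(v1^2)), 0.5, tolerance = 1e-9)
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, 109.5, tolerance = 1e-6)
})

test_that("the default configuration describes the reference box", {
  cfg <- sim_config()
  expect_equal(cfg$box_edge, rep(50, 3))
  expect_equal(cfg$n_molecules, 5875L)
  counts <- polymc:::molecule_counts(cfg)
  expect_equal(sum(counts), 5875)
  expect_true(max(counts) - min(counts) <= 1) # equal thirds, remainder to monomers
  expect_equal(cfg$capture_radius, 1.2) # twice the longest bead edge
})

test_that("impossible packings fail with a density report", {
  cfg <- test_config(box_edge = 2, n_molecules = 500, seed = 1,
                     max_place_attempts = 25)
  set.seed(1)
  expect_error(init_box(cfg), "packing failed")
})

test_that("box validation flags each broken invariant", {
  cfg <- test_config(box_edge = 10, n_molecules = 30, seed = 1)
  set.seed(2)
  box <- init_box(cfg)
  expect_equal(nrow(validate_box(box)), 0)

  oob <- box
  oob$pos[1, 1] <- -5
  v <- validate_box(oob)
  expect_true("bounds" %in% v$rule)

  # park a bead on top of a bead of another polymer
  other <- which(box$polymer_id != box$polymer_id[1])[1]
  clash <- box
  clash$pos[other, ] <- clash$pos[1, ] + 1e-4
  v <- validate_box(clash)
  expect_true("collision" %in% v$rule)

  # a bond reaching across two polymers breaks both span and tree rules
  span <- box
  span$bonds <- rbind(span$bonds, c(1L, other))
  v <- validate_box(span)
  expect_true("bond_span" %in% v$rule)
})

test_that("the state hash tracks physics, not bookkeeping", {
  box <- chain_box(c(4, 2))
  h0 <- state_hash(box)
  stepped <- box
  stepped$step_count <- 99L
  stepped$counters[["accepted"]] <- 5L
  expect_identical(state_hash(stepped), h0)
  moved <- box
  moved$pos[1, 1] <- moved$pos[1, 1] + 1e-12
  expect_false(identical(state_hash(moved), h0))
})

test_that("small-box configurations warn about the regime", {
  expect_warning(sim_config(box_edge = 35, n_molecules = 10),
                 class = "polymc_box_size")
  expect_warning(sim_config(box_edge = 12, n_molecules = 10),
                 class = "polymc_box_size")
  expect_no_warning(sim_config(box_edge = 50))
})
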
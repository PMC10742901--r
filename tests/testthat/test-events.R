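test_that("a monomer extends a chain at a terminal bead", {
  box <- chain_box(c(5, 1))
  out <- combine_polymers(box, activation = 6, partner = 5)
  expect_equal(attr(out, "scenario"), "extend")
  ps <- polymer_stats(out)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$length, 6L)
  expect_equal(ps$backbone, 6L) # still a simple chain
  # new bond has the configured length
  expect_equal(sqrt(sum((out$pos[6, ] - out$pos[5, ])^2)), 0.5,
               tolerance = 1e-9)
})

test_that("attachment at an internal bead creates a degree-3 junction", {
  box <- chain_box(c(5, 1))
  out <- combine_polymers(box, activation = 6, partner = 3)
  ps <- polymer_stats(out)
  expect_equal(ps$length, 6L)
  deg <- tabulate(c(out$bonds), nbins = 6)
  expect_equal(deg[3], 3L)
  expect_equal(ps$backbone, 5L) # branch does not lengthen the backbone
  # bond angle at the partner junction is tetrahedral against one of the
  # two pre-existing bonds (the reference neighbour is drawn at random)
  angle_to <- function(nb) {
    u1 <- out$pos[nb, ] - out$pos[3, ]
    u2 <- out$pos[6, ] - out$pos[3, ]
    acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))) * 180 / pi
  }
  expect_true(abs(angle_to(2) - 109.5) < 1e-6 ||
                abs(angle_to(4) - 109.5) < 1e-6)
})

test_that("segment swap moves the cut portion onto the other polymer", {
  # 4-chain (beads 1..4) swaps at bead 2 onto a 3-chain (beads 5..7):
  # cutting bond 2-3 leaves {3,4} behind and merges {1,2} -> sizes 2 and 5
  box <- chain_box(c(4, 3))
  set.seed(1)
  out <- combine_polymers(box, activation = 2, partner = 5,
                          scenario = "swap", cut = 3)
  ps <- polymer_stats(out)
  expect_equal(sum(ps$length), 7L) # conservation
  expect_setequal(ps$length, c(2L, 5L))
  expect_equal(sort(which(out$polymer_id == out$polymer_id[5])), c(1:2, 5:7))
})

test_that("combining beads of one polymer is rejected (no cycles)", {
  box <- chain_box(c(4))
  out <- combine_polymers(box, 1, 4)
  expect_equal(attr(out, "rejected"), "cycle")
  expect_identical(state_hash(out), state_hash(box))
})

test_that("breakdown splits into the two graph components", {
  box <- chain_box(c(6))
  out <- breakdown_polymer(box, 3, 4)
  expect_equal(sort(polymer_stats(out)$length), c(3L, 3L))
  expect_identical(out$pos, box$pos) # coordinates untouched
  # the detached side gets the fresh id
  expect_equal(unique(out$polymer_id[4:6]), attr(out, "detached"))
  expect_error(breakdown_polymer(box, 1, 6), class = "polymc_domain")

  # random trees: component split matches an independent graph library
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    bonds <- random_tree(n)
    tb <- tree_box(list(bonds))
    r <- sample(nrow(bonds), 1)
    res <- breakdown_polymer(tb, bonds[r, 1], bonds[r, 2])
    g <- igraph::graph_from_edgelist(bonds[-r, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    expect_equal(length(unique(res$polymer_id)), 2)
    split_pkg <- unname(split(seq_len(n), res$polymer_id))
    split_ora <- unname(split(seq_len(n), comp))
    expect_setequal(split_pkg, split_ora)
  }
})

test_that("combine then breakdown at the new bond restores both sizes", {
  set.seed(15)
  for (rep in 1:30) {
    ka <- sample(1:6, 1); kb <- sample(1:6, 1)
    box <- chain_box(c(ka, kb))
    act <- sample(ka, 1)
    par <- ka + sample(kb, 1)
    deg <- length(polymc:::incident_beads(box$bonds, act))
    scenario <- if (deg <= 1) "extend" else "branch"
    merged <- combine_polymers(box, act, par, scenario = scenario)
    expect_equal(nrow(merged$bonds), ka + kb - 1L)
    back <- breakdown_polymer(merged, act, par)
    expect_setequal(polymer_stats(back)$length, c(ka, kb))
    # the swap variant conserves beads even though it reshuffles them
    if (deg >= 1) {
      swapped <- combine_polymers(box, act, par, scenario = "swap")
      expect_equal(sum(polymer_stats(swapped)$length), ka + kb)
    }
  }
})

test_that("randomised event sequences conserve beads and tree-ness", {
  set.seed(16)
  box <- chain_box(c(rep(3, 10), rep(2, 10), rep(1, 10)), edge = 40)
  n_beads <- nrow(box$pos)
  for (it in 1:2000) {
    pids <- unique(box$polymer_id)
    sizes <- table(box$polymer_id)
    if (length(pids) >= 2 && runif(1) < 0.6) {
      pa <- sample(pids, 1)
      pb <- sample(setdiff(pids, pa), 1)
      act <- sample(which(box$polymer_id == pa), 1)
      par <- sample(which(box$polymer_id == pb), 1)
      box <- combine_polymers(box, act, par)
    } else if (nrow(box$bonds) > 0) {
      r <- sample(nrow(box$bonds), 1)
      box <- breakdown_polymer(box, box$bonds[r, 1], box$bonds[r, 2])
    }
    expect_equal(nrow(box$pos), n_beads)
    expect_equal(nrow(box$bonds),
                 n_beads - length(unique(box$polymer_id)))
  }
  # full structural audit at the end
  pid <- box$polymer_id
  for (id in unique(pid)) {
    members <- which(pid == id)
    sub <- box$bonds[pid[box$bonds[, 1]] == id, , drop = FALSE]
    expect_null(polymc:::check_tree(members, sub))
  }
})
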
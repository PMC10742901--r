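test_that("growth statistics average only polymerised material", {
  only_mono <- chain_box(rep(1, 5))
  g <- growth_stats(only_mono)
  expect_true(is.na(g$mean_backbone) && is.na(g$mean_length))
  expect_equal(g$n_free_monomers, 5L)
  expect_equal(g$n_polymers, 0L)

  mixed <- chain_box(c(6, 1, 1, 1, 1))
  g <- growth_stats(mixed)
  expect_equal(g$mean_backbone, 6)
  expect_equal(g$mean_length, 6)
  expect_equal(g$n_free_monomers, 4L)

  # a 4-chain plus a branched 8-bead tree of backbone 6
  branched <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                    c(3, 7), c(4, 8))
  box <- tree_box(list(cbind(1:3, 2:4), branched))
  ps <- polymer_stats(box)
  expect_setequal(ps$backbone, c(4L, 6L))
  g <- growth_stats(box)
  expect_equal(g$mean_backbone, 5.0)
  expect_equal(g$mean_length, 6.0)
})

test_that("jaccard similarity counts shared occupied voxels", {
  frame_at <- function(cells) {
    tibble::tibble(x = cells[, 1] + 0.5, y = cells[, 2] + 0.5,
                   z = cells[, 3] + 0.5, polymer_id = 1)
  }
  a <- occupancy_set(frame_at(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0))),
                     box_edge = 5, min_size = 2)
  b <- occupancy_set(frame_at(rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))),
                     box_edge = 5, min_size = 2)
  expect_equal(jaccard_index(a, b), 0.5) # 2 shared / 4 in the union
  expect_equal(jaccard_index(a, a), 1)
  c_ <- occupancy_set(frame_at(rbind(c(3, 3, 3), c(4, 4, 4))),
                      box_edge = 5, min_size = 2)
  expect_equal(jaccard_index(a, c_), 0)
  # two empty patterns are identical by definition
  empty <- occupancy_set(tibble::tibble(x = 1, y = 1, z = 1, polymer_id = 1),
                         box_edge = 5, min_size = 2)
  expect_equal(jaccard_index(empty, empty), 1)
  # mismatched grids are not comparable
  fine <- occupancy_set(frame_at(rbind(c(0, 0, 0))), box_edge = 5,
                        voxel_edge = 0.5, min_size = 2)
  expect_error(jaccard_index(a, fine), class = "polymc_domain")
})

test_that("free monomers do not contribute to occupancy", {
  beads <- tibble::tibble(
    x = c(1.5, 1.9, 8.5), y = c(1.5, 1.5, 8.5), z = c(1.5, 1.5, 8.5),
    polymer_id = c(1, 1, 2)) # dimer + free monomer
  occ <- occupancy_set(beads, box_edge = 10, min_size = 2)
  expect_equal(length(occ$items), 1) # only the dimer voxel
})

test_that("ensemble similarity is a symmetric unit-diagonal matrix", {
  set.seed(20)
  boxes <- lapply(1:5, function(i) {
    chain_box(sample(1:4, 8, replace = TRUE), edge = 30)
  })
  sim <- ensemble_similarity(boxes, voxel_edge = 1)
  expect_equal(dim(sim$matrix), c(5, 5))
  expect_equal(diag(sim$matrix), rep(1, 5))
  expect_equal(sim$matrix, t(sim$matrix))
  expect_equal(nrow(sim$series), 25) # n^2 comparisons, self included
  expect_true(all(sim$series$jaccard >= 0 & sim$series$jaccard <= 1))
  # identical boxes are all-ones
  same <- ensemble_similarity(boxes[c(1, 1, 1)], voxel_edge = 1)
  expect_equal(same$matrix, matrix(1, 3, 3))
})

test_that("subcube counts partition the box and conserve beads", {
  cfg <- test_config(box_edge = 20, n_molecules = 60, seed = 6)
  set.seed(6)
  box <- init_box(cfg)
  counts <- subcube_counts(box, cube_edge = 10)
  expect_equal(nrow(counts), 8) # 2^3 cells for a 20 nm box
  expect_equal(sum(counts$count), nrow(box$pos))
  expect_error(subcube_counts(box, cube_edge = 3), class = "polymc_domain")

  # invariance under bead reordering
  tb <- tibble::as_tibble(box)
  shuffled <- tb[sample(nrow(tb)), ]
  c2 <- subcube_counts(shuffled[, c("x", "y", "z", "polymer_id")],
                       cube_edge = 10, box_edge = 20)
  expect_equal(c2$count, counts$count)

  # identical boxes deviate by zero; shifted ones do not
  expect_equal(subcube_deviation(list(box, box), cube_edge = 10), 0)
  pairs <- subcube_deviation(list(box, box, box), cube_edge = 10,
                             summarise = FALSE)
  expect_equal(nrow(pairs), 3)
})

test_that("tidy, glance and autoplot cover the result types", {
  cfg <- test_config(box_edge = 10, n_molecules = 30, steps = 300,
                     seed = 12, snapshot_interval = 100)
  run <- run_box(cfg)
  expect_s3_class(tidy(run), "tbl_df")
  expect_equal(glance(run)$steps, 300L)
  expect_s3_class(autoplot(run), "ggplot")
  ens <- run_ensemble(cfg, 2)
  expect_s3_class(tidy(ens), "tbl_df")
  expect_equal(glance(ens)$n_boxes, 2)
  expect_s3_class(autoplot(ens), "ggplot")
  sim <- ensemble_similarity(ens, step = 300)
  expect_equal(nrow(tidy(sim)), 4)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_subcube_counts(subcube_counts(run$final, 5)),
                  "ggplot")
})
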
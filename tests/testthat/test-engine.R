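test_that("identical seeds reproduce a run bit-exactly", {
  cfg <- test_config(box_edge = 10, n_molecules = 40, steps = 1500,
                     seed = 7, snapshot_interval = 500)
  r1 <- run_box(cfg, keep_frames = FALSE)
  r2 <- run_box(cfg, keep_frames = FALSE)
  expect_identical(state_hash(r1$final), state_hash(r2$final))
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$counters, r2$counters)
})

test_that("a zero-step run is just the initial frame", {
  cfg <- test_config(box_edge = 10, n_molecules = 30, steps = 0, seed = 3)
  r <- run_box(cfg)
  expect_equal(nrow(r$stats), 1)
  expect_equal(names(r$frames), "0")
  expect_equal(r$final$step_count, 0L)
})

test_that("forced infeasibility reverts the physical state exactly", {
  cfg <- test_config(box_edge = 10, n_molecules = 40, seed = 5, steps = 0)
  set.seed(5)
  box <- init_box(cfg)
  h0 <- state_hash(box)
  for (i in 1:50) {
    box <- mc_step(box, cfg, force_infeasible = TRUE)
    expect_identical(state_hash(box), h0)
  }
  expect_equal(box$step_count, 50L)
  expect_equal(box$counters[["reverted"]], 50L)
})

test_that("steps conserve beads and keep the box valid", {
  cfg <- test_config(box_edge = 10, n_molecules = 40, steps = 1500,
                     seed = 11, snapshot_interval = 300)
  r <- run_box(cfg)
  expect_equal(nrow(r$final$pos), nrow(r$frames[["0"]]$pos))
  for (f in r$frames) {
    expect_equal(nrow(validate_box(f)), 0)
  }
  # polymer lengths always sum to the bead total
  for (f in r$frames) {
    expect_equal(sum(polymer_stats(f)$length), nrow(f$pos))
  }
})

test_that("a lone molecule can never react", {
  beads <- tibble::tibble(x = 5, y = 5, z = 5, polymer_id = 1)
  box <- mc_box(beads, NULL, edge = 10)
  cfg <- test_config(box_edge = 10, n_molecules = 1, steps = 0, seed = 2)
  set.seed(9)
  for (i in 1:30) box <- mc_step(box, cfg)
  expect_equal(nrow(box$bonds), 0)
  expect_equal(unique(box$polymer_id), 1L)
  expect_equal(box$step_count, 30L)
})

test_that("growth occurs in a reacting box", {
  cfg <- test_config(box_edge = 12, n_molecules = 80, steps = 20000,
                     seed = 1, snapshot_interval = 5000)
  r <- run_box(cfg, keep_frames = FALSE)
  g <- glance(r)
  expect_gt(g$mean_length, 2)
  expect_gt(g$combinations, 0)
  expect_lte(g$mean_backbone, g$mean_length)
})

test_that("ensembles replicate independently from distinct seeds", {
  cfg <- test_config(box_edge = 10, n_molecules = 30, steps = 300,
                     seed = 100, snapshot_interval = 100)
  ens <- run_ensemble(cfg, n_boxes = 3)
  expect_equal(length(ens$runs), 3)
  hashes <- vapply(ens$runs, function(r) state_hash(r$final), "")
  expect_equal(length(unique(hashes)), 3)
  expect_setequal(unique(ens$stats$box_id), 1:3)
  # one replicate is exactly a plain run at seed base + 1
  cfg1 <- cfg
  cfg1$seed <- cfg$seed + 1L
  solo <- run_box(cfg1)
  expect_identical(state_hash(solo$final), state_hash(ens$runs[[1]]$final))
})

test_that("run output writes stats and a reloadable trajectory", {
  dir <- withr::local_tempdir()
  cfg <- test_config(box_edge = 10, n_molecules = 25, steps = 400,
                     seed = 8, snapshot_interval = 200)
  r <- run_box(cfg, out = dir)
  expect_true(file.exists(file.path(dir, "stats.csv")))
  traj <- read_xyz(file.path(dir, "trajectory.xyz"))
  expect_equal(max(traj$frame), length(r$frames))
  last <- traj[traj$frame == max(traj$frame), ]
  expect_identical(cbind(last$x, last$y, last$z), unname(r$final$pos))
})
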
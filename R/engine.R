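#' Simulation configuration
#'
#' Collects every tunable parameter of the chemical-events Monte Carlo
#' engine.  Defaults reproduce the reference conditions: a 50 nm cubic
#' box holding 5875 molecules (equal thirds monomers, dimers and trimers
#' by molecule count, remainder to monomers) of cuboid beads, tetrahedral
#' 109.5 degree bond angles, and one candidate radical event per step.
#'
#' Boxes of edge >= 40 nm are the validated regime; edges in [30, 40) nm
#' trigger a warning because box-size effects are no longer negligible
#' there, and smaller boxes (unit-test scale) warn that results are not
#' chemically meaningful.
#'
#' @param box_edge Box edge length, nm (scalar cube or length 3).
#' @param n_molecules Total molecule count at initialisation.
#' @param steps Monte Carlo steps to run.
#' @param seed Integer seed for R's Mersenne-Twister RNG; fixes every
#'   random draw of the run.
#' @param snapshot_interval Steps between recorded statistics/frames.
#' @param bead_half_extents Cuboid half edge lengths of one bead, nm.
#' @param bond_length Bond length between bonded bead centres, nm.
#' @param bond_angle Bond angle at chain junctions, degrees.
#' @param capture_radius Radical/partner capture distance, nm; default
#'   twice the longest bead edge.
#' @param U_mean Mean of the exponential deposited-energy draw
#'   (dimensionless); the main calibration knob of the event model.
#' @param p_radical Probability that a step's energy check produces a
#'   radical at all (dose-rate dependence is folded into the fitted
#'   event parameters, so the default is 1).
#' @param theta_I0,d_0,N_0 Rigid-move scaling constants (see
#'   [propose_move()]).
#' @param contact_tol GJK contact tolerance for the collision predicate, nm.
#' @param composition Relative molecule-count weights for
#'   monomer/dimer/trimer at initialisation.
#' @param max_place_attempts Rejection-sampling attempts per molecule
#'   before initialisation fails.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(box_edge = 50, steps = 1000)
#' @export
sim_config <- function(box_edge = 50, n_molecules = 5875, steps = 10000,
                       seed = 1L, snapshot_interval = 1000,
                       bead_half_extents = c(0.30, 0.225, 0.20),
                       bond_length = 0.5, bond_angle = 109.5,
                       capture_radius = NULL, U_mean = 1, p_radical = 1,
                       theta_I0 = 10, d_0 = 2, N_0 = 10,
                       contact_tol = 1e-9,
                       composition = c(monomer = 1, dimer = 1, trimer = 1),
                       max_place_attempts = 2000) {
  if (length(box_edge) == 1) box_edge <- rep(box_edge, 3)
  stopifnot(length(box_edge) == 3, all(box_edge > 0),
            n_molecules >= 1, steps >= 0,
            length(bead_half_extents) == 3, all(bead_half_extents > 0),
            bond_length > 0, U_mean > 0,
            p_radical >= 0, p_radical <= 1)
  if (min(box_edge) < 30) {
    warn(paste0("box edge below 30 nm: unit-test scale only, results are ",
                "not chemically meaningful"),
         class = "polymc_box_size")
  } else if (min(box_edge) < 40) {
    warn(paste0("box edge below the 40 nm validated minimum: box-size ",
                "effects are not negligible in this regime"),
         class = "polymc_box_size")
  }
  capture_radius <- capture_radius %||% (2 * 2 * max(bead_half_extents))
  structure(list(
    box_edge = as.numeric(box_edge), n_molecules = as.integer(n_molecules),
    steps = as.integer(steps), seed = as.integer(seed),
    snapshot_interval = as.integer(snapshot_interval),
    bead_half_extents = as.numeric(bead_half_extents),
    bond_length = bond_length, bond_angle = bond_angle,
    capture_radius = capture_radius, U_mean = U_mean, p_radical = p_radical,
    theta_I0 = theta_I0, d_0 = d_0, N_0 = N_0, contact_tol = contact_tol,
    composition = composition,
    max_place_attempts = as.integer(max_place_attempts)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> box %.3g x %.3g x %.3g nm, %d molecules, %d steps, seed %d\n",
    x$box_edge[1], x$box_edge[2], x$box_edge[3], x$n_molecules, x$steps,
    x$seed))
  invisible(x)
}

# molecule counts per species: proportional split, remainder to monomers
molecule_counts <- function(cfg) {
  w <- cfg$composition / sum(cfg$composition)
  counts <- floor(cfg$n_molecules * w)
  counts[["monomer"]] <- counts[["monomer"]] +
    (cfg$n_molecules - sum(counts))
  counts
}

#' Initialise a simulation box
#'
#' Fills the box with the configured number of molecules -- monomers,
#' dimers and trimers in roughly equal molecule counts by default -- by
#' rejection sampling of random positions and uniformly random
#' orientations until every placement is inside the box and collision
#' free (GJK against all previously placed beads).  Multimers are built
#' with the configured bond length and bond angle, beads oriented with
#' their long axis along the incident bond.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed; when `NULL` the current RNG state is used
#'   (note [run_box()] seeds itself from `cfg$seed`).
#' @return An `mc_box` with `cfg$n_molecules` polymers.
#' @export
init_box <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  counts <- molecule_counts(cfg)
  res <- cpp_pack_box(counts[["monomer"]], counts[["dimer"]],
                      counts[["trimer"]], cfg$box_edge,
                      cfg$bead_half_extents, cfg$bond_length, cfg$bond_angle,
                      cfg$contact_tol, cfg$max_place_attempts)
  bonds <- res$bonds
  storage.mode(bonds) <- "integer"
  new_mc_box(res$pos, res$quat, res$half, res$polymer_id, bonds,
             cfg$box_edge)
}

# precomputed per-run constants for the hot loop
step_pars <- function(cfg) {
  list(edge = cfg$box_edge, capture_radius = cfg$capture_radius,
       U_mean = cfg$U_mean, p_radical = cfg$p_radical,
       pv = param_vectors(), theta_I0 = cfg$theta_I0, d_0 = cfg$d_0,
       N_0 = cfg$N_0, l_edge = 2 * max(cfg$bead_half_extents),
       bond_length = cfg$bond_length,
       bond_angle = cfg$bond_angle, contact_tol = cfg$contact_tol,
       half3 = cfg$bead_half_extents)
}

# scalar outcome decision on the fast path: 1 combination, 2 breakdown, 0 none
decide_fast <- function(U, n, pv) {
  if (runif(1) < p_act_fast(U, n, pv)) return(1L)
  if (n >= 2L && runif(1) < p_brk_fast(U, n, pv)) return(2L)
  0L
}

step_impl <- function(box, pars, force_infeasible = FALSE, want_log = FALSE) {
  box0 <- box
  loc <- runif(3) * pars$edge
  event <- "none"
  u_dep <- NA_real_
  n_target <- NA_integer_
  scenario <- NA_character_
  if (pars$p_radical < 1 && runif(1) >= pars$p_radical) {
    target <- 0L
  } else {
    target <- cpp_nearest_bead(box$pos, loc, pars$capture_radius,
                               box$polymer_id, -1L)
  }
  move_ids <- NULL
  if (target > 0L) {
    u_dep <- rexp(1, rate = 1 / pars$U_mean)
    pid_t <- box$polymer_id[target]
    n_target <- sum(box$polymer_id == pid_t)
    outcome <- decide_fast(u_dep, n_target, pars$pv)
    if (outcome == 1L) {
      partner <- cpp_nearest_bead(box$pos, box$pos[target, ],
                                  pars$capture_radius, box$polymer_id, pid_t)
      if (partner > 0L) {
        box <- combine_polymers(box, target, partner,
                                bond_length = pars$bond_length,
                                bond_angle = pars$bond_angle)
        scenario <- attr(box, "scenario")
        attr(box, "scenario") <- NULL
        event <- "combination"
        move_ids <- which(box$polymer_id == box$polymer_id[partner])
      }
    } else if (outcome == 2L) {
      nbrs <- incident_beads(box$bonds, target)
      cut <- nbrs[[sample.int(length(nbrs), 1L)]]
      box <- breakdown_polymer(box, target, cut)
      attr(box, "detached") <- NULL
      event <- "breakdown"
      move_ids <- which(box$polymer_id == box$polymer_id[target])
    }
  }
  if (is.null(move_ids)) {
    pids <- unique(box$polymer_id)
    chosen <- pids[[sample.int(length(pids), 1L)]]
    move_ids <- which(box$polymer_id == chosen)
  }
  mv <- propose_core(box$pos[move_ids, , drop = FALSE], pars$l_edge,
                     pars$theta_I0, pars$d_0, pars$N_0)
  box <- apply_move_box(box, move_ids, mv)
  ok <- !force_infeasible && feasible_move(box, move_ids, pars)
  out <- if (ok) box else box0
  out$step_count <- box0$step_count + 1L
  key <- if (ok) "accepted" else "reverted"
  out$counters[[key]] <- out$counters[[key]] + 1L
  if (ok && event != "none") {
    out$counters[[event]] <- out$counters[[event]] + 1L
  }
  if (want_log) {
    attr(out, "event_row") <- list(step = out$step_count, event = event,
                                   scenario = scenario, U = u_dep,
                                   n_target = n_target, accepted = ok)
  }
  out
}

apply_move_box <- function(box, idx, mv) {
  box$pos[idx, ] <- move_points(box$pos[idx, , drop = FALSE], mv$axis,
                                mv$angle, mv$pivot, mv$translation)
  q <- quat_from_axis_angle(mv$axis, mv$angle)
  box$quat[idx, ] <- quat_rows_rotate(q, box$quat[idx, , drop = FALSE])
  box
}

feasible_move <- function(box, idx, pars) {
  cpp_feasible(box$pos, box$quat, box$half, idx, box$bonds, pars$edge,
               pars$contact_tol) == 0L
}

#' Advance a simulation box by one Monte Carlo step
#'
#' One iteration of the chemical-events cycle: a random location is
#' drawn; if a radical appears there and a bead lies within the capture
#' radius, the deposited energy decides between a combination event
#' (bonding to the nearest bead of another polymer), a breakdown event
#' (cutting a bond at the activation bead) or no reaction.  The affected
#' structure -- or, with no event, one uniformly chosen molecule -- then
#' receives a random rigid rotation-translation, and the whole step is
#' accepted only if the result is collision free and inside the box;
#' otherwise every change is reverted.  The step counter advances either
#' way.
#'
#' @param box An `mc_box`.
#' @param cfg A [sim_config()].
#' @param force_infeasible Internal testing hook: treat the feasibility
#'   check as failed so the step must revert.
#' @return The advanced `mc_box`.
#' @export
mc_step <- function(box, cfg, force_infeasible = FALSE) {
  stopifnot(inherits(box, "mc_box"), inherits(cfg, "sim_config"))
  step_impl(box, step_pars(cfg), force_infeasible = force_infeasible)
}

#' Run one simulation box
#'
#' Seeds the RNG from `cfg$seed`, initialises the box (unless one is
#' supplied) and advances it `cfg$steps` steps, recording growth
#' statistics (and, optionally, full frames) every
#' `cfg$snapshot_interval` steps.  Identical configurations produce
#' bit-identical runs.
#'
#' @param cfg A [sim_config()].
#' @param box Optional starting `mc_box`; by default a fresh box is
#'   packed from `cfg`.
#' @param keep_frames Keep a copy of the box at every snapshot (memory
#'   scales with `steps / snapshot_interval`).
#' @param log_events Collect a per-step event log tibble.
#' @param out Optional output directory; writes `stats.csv` and an
#'   extended-XYZ `trajectory.xyz` there.
#' @param progress Emit a progress line every million steps.
#' @return An object of class `mc_run`: list with `config`, `stats`
#'   (tibble of step, mean_backbone, mean_length, n_free_monomers,
#'   n_polymers), `frames` (named by step, if kept), `final` box,
#'   `counters` and optionally `events`.
#' @export
run_box <- function(cfg, box = NULL, keep_frames = TRUE, log_events = FALSE,
                    out = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  box <- box %||% init_box(cfg)
  pars <- step_pars(cfg)
  stats <- list(growth_stats(box))
  frames <- list()
  if (keep_frames) frames[[as.character(box$step_count)]] <- box
  events <- list()
  interval <- max(1L, cfg$snapshot_interval)
  n_start <- nrow(box$pos)
  for (s in seq_len(cfg$steps)) {
    box <- step_impl(box, pars, want_log = log_events)
    if (log_events) {
      row <- attr(box, "event_row")
      attr(box, "event_row") <- NULL
      if (row$event != "none") events[[length(events) + 1L]] <- row
    }
    if (s %% interval == 0L || s == cfg$steps) {
      stats[[length(stats) + 1L]] <- growth_stats(box)
      if (keep_frames) frames[[as.character(box$step_count)]] <- box
    }
    if (progress && s %% 1e6 == 0) {
      message(sprintf("step %d / %d", s, cfg$steps))
    }
  }
  stopifnot(nrow(box$pos) == n_start) # monomer conservation
  res <- structure(list(
    config = cfg,
    stats = bind_rows(stats[!duplicated(vapply(stats, function(d) d$step, 1))]),
    frames = if (keep_frames) frames else NULL,
    final = box,
    counters = box$counters,
    events = if (log_events) bind_rows(lapply(events, as_tibble)) else NULL
  ), class = "mc_run")
  if (!is.null(out)) write_run(res, out)
  res
}

write_run <- function(run, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$stats, file.path(out, "stats.csv"), row.names = FALSE)
  frames <- run$frames %||% list(final = run$final)
  first <- TRUE
  for (f in frames) {
    write_xyz(f, file.path(out, "trajectory.xyz"), append = !first)
    first <- FALSE
  }
  invisible(out)
}

#' Run an ensemble of replicate boxes
#'
#' Repeats [run_box()] on `n_boxes` independently initialised boxes;
#' replicate `i` uses seed `base_seed + i`, so every replicate is
#' reproducible on its own and the replicates differ from each other.
#'
#' @param cfg A [sim_config()] shared by all replicates.
#' @param n_boxes Number of replicate boxes.
#' @param base_seed Base seed (default `cfg$seed`).
#' @param box Optional shared starting `mc_box`: all replicates then
#'   evolve the same initial state under different random streams (their
#'   similarity starts at 1 and decays as the trajectories diverge).  By
#'   default each replicate packs its own initial box.
#' @param keep_frames,log_events Passed to [run_box()].
#' @param out Optional directory; per-box outputs go to `box_001/`, ...
#' @return An object of class `mc_ensemble`: list with `runs` (list of
#'   `mc_run`), `stats` (per-box statistics bound with a `box_id`
#'   column) and `base_seed`.
#' @export
run_ensemble <- function(cfg, n_boxes, base_seed = cfg$seed, box = NULL,
                         keep_frames = TRUE, log_events = FALSE, out = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n_boxes >= 1)
  runs <- purrr::map(seq_len(n_boxes), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(base_seed + i)
    run_box(cfg_i, box = box, keep_frames = keep_frames,
            log_events = log_events,
            out = if (!is.null(out)) {
              file.path(out, sprintf("box_%03d", i))
            } else NULL)
  })
  stats <- bind_rows(
    purrr::imap(runs, function(r, i) mutate(r$stats, box_id = i, .before = 1))
  )
  structure(list(runs = runs, stats = stats, base_seed = base_seed),
            class = "mc_ensemble")
}

#' @export
print.mc_run <- function(x, ...) {
  last <- x$stats[nrow(x$stats), ]
  cat(sprintf(
    paste0("<mc_run> %d steps (%d accepted, %d reverted); final mean ",
           "backbone %.2f, mean length %.2f, %d free monomers\n"),
    x$final$step_count, x$counters[["accepted"]], x$counters[["reverted"]],
    last$mean_backbone, last$mean_length, last$n_free_monomers))
  invisible(x)
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat(sprintf("<mc_ensemble> %d boxes x %d steps (base seed %d)\n",
              length(x$runs), x$runs[[1]]$config$steps, x$base_seed))
  invisible(x)
}
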
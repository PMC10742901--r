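# normalise a frame (mc_box or bead table) to a bead data frame + edge
frame_df <- function(frame, box_edge = NULL) {
  if (inherits(frame, "mc_box")) {
    return(list(df = tibble(x = frame$pos[, 1], y = frame$pos[, 2],
                            z = frame$pos[, 3],
                            polymer_id = frame$polymer_id),
                edge = frame$edge))
  }
  if (is.data.frame(frame)) {
    stopifnot(all(c("x", "y", "z", "polymer_id") %in% names(frame)))
    edge <- box_edge %||% attr(frame, "box_edge")
    if (is.null(edge)) {
      abort("supply `box_edge` for data-frame frames", class = "polymc_domain")
    }
    if (length(edge) == 1) edge <- rep(edge, 3)
    return(list(df = frame, edge = as.numeric(edge)))
  }
  abort("`frame` must be an mc_box or a bead data frame",
        class = "polymc_domain")
}

#' Growth statistics of one frame
#'
#' Mean backbone length and mean polymer length over all polymers of
#' size >= 2, plus the free (non-polymerised) monomer count and the
#' polymer count.  With no polymers of size >= 2 the means are reported
#' as `NA` (undefined) while the counts remain valid.
#'
#' @param frame An `mc_box`.
#' @return One-row tibble: `step`, `mean_backbone`, `mean_length`,
#'   `n_free_monomers`, `n_polymers`.
#' @export
growth_stats <- function(frame) {
  stopifnot(inherits(frame, "mc_box"))
  ps <- polymer_stats(frame)
  poly <- ps[ps$length >= 2L, ]
  tibble(step = frame$step_count,
         mean_backbone = if (nrow(poly)) mean(poly$backbone) else NA_real_,
         mean_length = if (nrow(poly)) mean(poly$length) else NA_real_,
         n_free_monomers = sum(ps$length == 1L),
         n_polymers = nrow(poly))
}

#' Voxel occupancy set of polymerised material
#'
#' Growth patterns of replicate boxes are compared through the set of
#' voxels that contain polymerised material.  The box is divided into
#' cubic voxels of edge `voxel_edge`; a voxel is occupied when it holds
#' at least one bead belonging to a polymer of size >= `min_size`.  The
#' alternative `"sizes"` strategy compares the multiset of polymer sizes
#' instead of spatial occupancy.
#'
#' @param frame An `mc_box`, or a bead data frame with columns `x`, `y`,
#'   `z`, `polymer_id` (then `box_edge` is required).
#' @param voxel_edge Voxel edge length, nm.
#' @param min_size Minimum polymer size counted as polymerised.
#' @param strategy `"voxel"` (spatial occupancy, default) or `"sizes"`
#'   (multiset of polymer sizes).
#' @param box_edge Box edge for data-frame input.
#' @param box_id Optional replicate label carried through to results.
#' @return An object of class `occupancy_set`.
#' @export
occupancy_set <- function(frame, voxel_edge = 1, min_size = 2,
                          strategy = c("voxel", "sizes"), box_edge = NULL,
                          box_id = NA_integer_) {
  strategy <- match.arg(strategy)
  fr <- frame_df(frame, box_edge)
  sizes <- table(fr$df$polymer_id)
  if (strategy == "sizes") {
    items <- sort(as.integer(sizes[sizes >= min_size]))
    return(structure(list(strategy = strategy, items = items,
                          voxel_edge = voxel_edge, dims = NULL,
                          box_id = box_id), class = "occupancy_set"))
  }
  dims <- ceiling(fr$edge / voxel_edge - 1e-9)
  keep <- fr$df$polymer_id %in% as.integer(names(sizes[sizes >= min_size]))
  df <- fr$df[keep, ]
  ix <- pmin(pmax(floor(df$x / voxel_edge), 0), dims[1] - 1)
  iy <- pmin(pmax(floor(df$y / voxel_edge), 0), dims[2] - 1)
  iz <- pmin(pmax(floor(df$z / voxel_edge), 0), dims[3] - 1)
  keys <- sort(unique(ix + dims[1] * (iy + dims[2] * iz)))
  structure(list(strategy = strategy, items = keys,
                 voxel_edge = voxel_edge, dims = dims, box_id = box_id),
            class = "occupancy_set")
}

#' @export
print.occupancy_set <- function(x, ...) {
  cat(sprintf("<occupancy_set> %s strategy, %d elements\n",
              x$strategy, length(x$items)))
  invisible(x)
}

#' Jaccard similarity of two occupancy sets
#'
#' `|A intersect B| / |A union B|`; two empty sets are defined as
#' identical (similarity 1).  For the `"sizes"` strategy the multiset
#' Jaccard (sum of per-element minimum counts over maximum counts) is
#' used.
#'
#' @param a,b [occupancy_set()]s built with identical grid parameters
#'   and strategy.
#' @return Similarity in `[0, 1]`.
#' @examples
#' box <- mc_box(tibble::tibble(x = 1, y = 1, z = 1, polymer_id = 1),
#'               edge = 10)
#' jaccard_index(occupancy_set(box, min_size = 1),
#'               occupancy_set(box, min_size = 1)) # 1
#' @export
jaccard_index <- function(a, b) {
  stopifnot(inherits(a, "occupancy_set"), inherits(b, "occupancy_set"))
  if (!identical(a$strategy, b$strategy) ||
      !isTRUE(all.equal(a$voxel_edge, b$voxel_edge)) ||
      !identical(a$dims, b$dims)) {
    abort("occupancy sets built on different grids are not comparable",
          class = "polymc_domain")
  }
  if (length(a$items) == 0 && length(b$items) == 0) return(1)
  if (a$strategy == "sizes") {
    ta <- table(a$items); tb <- table(b$items)
    keys <- union(names(ta), names(tb))
    ca <- setNames(rep(0, length(keys)), keys); ca[names(ta)] <- ta
    cb <- setNames(rep(0, length(keys)), keys); cb[names(tb)] <- tb
    return(sum(pmin(ca, cb)) / sum(pmax(ca, cb)))
  }
  inter <- length(intersect(a$items, b$items))
  inter / (length(a$items) + length(b$items) - inter)
}

#' Pairwise Jaccard similarity across an ensemble
#'
#' Compares the growth pattern of every box against every other box (and
#' itself) at one recorded step, yielding an n x n similarity matrix
#' with unit diagonal and a flattened series of all n^2 comparisons.
#'
#' @param x An `mc_ensemble` (frames must have been kept), a list of
#'   `mc_box`es, or a list of [occupancy_set()]s.
#' @param step Recorded step to compare (default: the last common one).
#'   Ignored for box/occupancy lists.
#' @param voxel_edge,min_size,strategy Passed to [occupancy_set()].
#' @return An object of class `similarity_matrix`: list with `matrix`,
#'   `series` (tibble `i`, `j`, `jaccard`, length n^2), `step`.
#' @export
ensemble_similarity <- function(x, step = NULL, voxel_edge = 1, min_size = 2,
                                strategy = "voxel") {
  occ <- NULL
  if (inherits(x, "mc_ensemble")) {
    frames <- purrr::map(x$runs, function(r) {
      if (is.null(r$frames)) {
        abort("ensemble was run with keep_frames = FALSE",
              class = "polymc_domain")
      }
      steps <- as.integer(names(r$frames))
      use <- if (is.null(step)) max(steps) else as.integer(step)
      if (!use %in% steps) {
        abort(sprintf("no frame recorded at step %d", use),
              class = "polymc_domain")
      }
      r$frames[[as.character(use)]]
    })
    step <- step %||% max(as.integer(names(x$runs[[1]]$frames)))
    occ <- purrr::imap(frames, function(f, i) {
      occupancy_set(f, voxel_edge, min_size, strategy, box_id = i)
    })
  } else if (is.list(x) && length(x) && inherits(x[[1]], "occupancy_set")) {
    occ <- x
  } else if (is.list(x) && length(x) && inherits(x[[1]], "mc_box")) {
    occ <- purrr::imap(x, function(f, i) {
      occupancy_set(f, voxel_edge, min_size, strategy, box_id = i)
    })
  } else {
    abort("`x` must be an mc_ensemble or a list of boxes/occupancy sets",
          class = "polymc_domain")
  }
  n <- length(occ)
  m <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) m[i, j] <- jaccard_index(occ[[i]], occ[[j]])
      else if (j < i) m[i, j] <- m[j, i]
    }
  }
  series <- tibble(i = rep(seq_len(n), each = n), j = rep(seq_len(n), n),
                   jaccard = as.vector(t(m)))
  structure(list(matrix = m, series = series, step = step %||% NA_integer_),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$series$jaccard[x$series$i != x$series$j]
  cat(sprintf(
    "<similarity_matrix> %d boxes, %d comparisons; off-diagonal mean %.3f\n",
    nrow(x$matrix), nrow(x$series),
    if (length(off)) mean(off) else NA_real_))
  invisible(x)
}

#' Subcube monomer counts
#'
#' Divides the box into cubic subcells of edge `cube_edge` (which must
#' divide the box edge) and counts the beads whose centres fall in each
#' cell; for the 50 nm default box with 10 nm subcubes this is the
#' 125-cell randomness grid.
#'
#' @inheritParams occupancy_set
#' @param cube_edge Subcube edge length, nm.
#' @return A tibble with columns `ix`, `iy`, `iz` (1-based cell indices)
#'   and `count`, covering every cell of the grid.
#' @export
subcube_counts <- function(frame, cube_edge = 10, box_edge = NULL) {
  fr <- frame_df(frame, box_edge)
  k <- fr$edge / cube_edge
  if (any(abs(k - round(k)) > 1e-9)) {
    abort("`cube_edge` must divide the box edge", class = "polymc_domain")
  }
  k <- as.integer(round(k))
  ix <- pmin(pmax(floor(fr$df$x / cube_edge), 0), k[1] - 1) + 1L
  iy <- pmin(pmax(floor(fr$df$y / cube_edge), 0), k[2] - 1) + 1L
  iz <- pmin(pmax(floor(fr$df$z / cube_edge), 0), k[3] - 1) + 1L
  grid <- expand.grid(ix = seq_len(k[1]), iy = seq_len(k[2]),
                      iz = seq_len(k[3]))
  key <- (ix - 1L) + k[1] * ((iy - 1L) + k[2] * (iz - 1L))
  counts <- tabulate(key + 1L, nbins = prod(k))
  out <- as_tibble(grid[order((grid$ix - 1) + k[1] *
                                ((grid$iy - 1) + k[2] * (grid$iz - 1))), ])
  out$count <- counts
  attr(out, "cube_edge") <- cube_edge
  attr(out, "dims") <- k
  out
}

#' Average subcube deviation across boxes
#'
#' Structural randomness measure: for every pair of boxes, the mean over
#' corresponding subcubes of the absolute difference in monomer counts;
#' identical structures give 0 and uncorrelated ones a value set by the
#' concentration.  The pairwise means are averaged into one number by
#' default.
#'
#' @param frames A list of `mc_box`es (or bead data frames with a
#'   `box_edge` attribute).
#' @param cube_edge Subcube edge length, nm.
#' @param summarise Return the overall mean (default) instead of the
#'   per-pair tibble.
#' @return A scalar, or a tibble `box_i`, `box_j`, `mean_abs_dev` when
#'   `summarise = FALSE`.
#' @export
subcube_deviation <- function(frames, cube_edge = 10, summarise = TRUE) {
  stopifnot(is.list(frames), length(frames) >= 2)
  counts <- purrr::map(frames, function(f) subcube_counts(f, cube_edge)$count)
  n <- length(counts)
  pairs <- utils::combn(n, 2)
  dev <- apply(pairs, 2, function(p) {
    mean(abs(counts[[p[1]]] - counts[[p[2]]]))
  })
  if (summarise) return(mean(dev))
  tibble(box_i = pairs[1, ], box_j = pairs[2, ], mean_abs_dev = dev)
}
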
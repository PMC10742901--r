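#' Write an extended-XYZ trajectory frame
#'
#' Serialises box state as one extended-XYZ frame: per bead the species
#' label, centre, orientation quaternion and polymer id, with the box
#' edges in the `Lattice` record and the step counter as `step=`.
#' Coordinates are written at full double precision, so a written frame
#' reloads losslessly with [read_xyz()].
#'
#' @param x An `mc_box`, or an `mc_run` (all kept frames are written).
#' @param path Output file path.
#' @param append Append to an existing trajectory instead of
#'   overwriting.
#' @param species Species label written for every bead.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, append = FALSE, species = "MAA") {
  if (inherits(x, "mc_run")) {
    frames <- x$frames %||% list(x$final)
    first <- !append
    for (f in frames) {
      write_xyz(f, path, append = !first, species = species)
      first <- FALSE
    }
    return(invisible(path))
  }
  stopifnot(inherits(x, "mc_box"))
  n <- nrow(x$pos)
  header <- sprintf(
    paste0("Lattice=\"%.17g 0 0 0 %.17g 0 0 0 %.17g\" ",
           "Properties=species:S:1:pos:R:3:quat:R:4:polymer:I:1 step=%d"),
    x$edge[1], x$edge[2], x$edge[3], x$step_count)
  rows <- sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g %.17g %d",
                  species, x$pos[, 1], x$pos[, 2], x$pos[, 3],
                  x$quat[, 1], x$quat[, 2], x$quat[, 3], x$quat[, 4],
                  x$polymer_id)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(n), header, rows), con)
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Parses frames written by [write_xyz()] back into a bead table.
#'
#' @param path Trajectory file path.
#' @return A tibble with columns `frame`, `step`, `species`, `x`, `y`,
#'   `z`, `qw`, `qx`, `qy`, `qz`, `polymer_id`; the box edges of the
#'   first frame are attached as attribute `box_edge`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  frame <- 0L
  edge <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(lines[i])
    header <- lines[i + 1L]
    frame <- frame + 1L
    step <- NA_integer_
    m <- regmatches(header, regexec("step=([0-9]+)", header))[[1]]
    if (length(m) == 2) step <- as.integer(m[2])
    lat <- regmatches(header, regexec("Lattice=\"([^\"]+)\"", header))[[1]]
    if (length(lat) == 2 && is.null(edge)) {
      v <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
      edge <- v[c(1, 5, 9)]
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    mat <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:9))),
                  ncol = 8, byrow = TRUE)
    out[[frame]] <- tibble(
      frame = frame, step = step,
      species = vapply(parts, `[`, "", 1L),
      x = mat[, 1], y = mat[, 2], z = mat[, 3],
      qw = mat[, 4], qx = mat[, 5], qy = mat[, 6], qz = mat[, 7],
      polymer_id = as.integer(mat[, 8]))
    i <- i + 2L + n
  }
  res <- bind_rows(out)
  attr(res, "box_edge") <- edge
  res
}
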
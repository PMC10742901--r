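#' Size-dependent event parameters
#'
#' The dimensionless coefficients `X`, `F` and `G` controlling the
#' activation and breakdown probability laws, one row per polymer size
#' class (1, 2, 3, 4, 5, 6-10, 11-15, >=16).  The values were fitted from
#' quantum-chemistry reaction energetics for methacrylic acid oligomers
#' under gamma irradiation at 20 cGy/min and are consumed here as given;
#' the table ships as a plain CSV in `inst/extdata/event_params.csv`.
#'
#' @return A tibble with columns `size_class`, `size_min`, `size_max`,
#'   `X`, `F`, `G`.
#' @examples
#' event_params()
#' @export
event_params <- function() {
  if (is.null(the$params)) {
    path <- system.file("extdata", "event_params.csv", package = "polymc",
                        mustWork = TRUE)
    df <- utils::read.csv(path)
    df$size_class <- ifelse(
      df$size_min == df$size_max, as.character(df$size_min),
      ifelse(is.infinite(df$size_max), paste0(">=", df$size_min),
             paste0(df$size_min, "-", df$size_max))
    )
    the$params <- as_tibble(df[, c("size_class", "size_min", "size_max",
                                   "X", "F", "G")])
  }
  the$params
}

# fast lookup vectors (row index by findInterval on size_min)
param_vectors <- function() {
  if (is.null(the$param_vec)) {
    p <- event_params()
    the$param_vec <- list(brks = p$size_min, X = p$X, F = p$F, G = p$G)
  }
  the$param_vec
}

#' Look up event parameters for a polymer size
#'
#' Maps a polymer size in monomers to its size class row of
#' [event_params()].  The lookup is total: every `n >= 1` falls in exactly
#' one class.
#'
#' @param n Integer vector of polymer sizes (monomer counts), all `>= 1`.
#' @return A tibble with one row per element of `n`: the matching
#'   parameter row preceded by an `n` column.
#' @examples
#' lookup_params(c(1, 8, 1000))
#' @export
lookup_params <- function(n) {
  check_size(n, 1)
  p <- event_params()
  row <- findInterval(n, p$size_min)
  out <- p[row, ]
  out <- mutate(out, n = as.integer(n), .before = 1L)
  out
}

check_size <- function(n, least) {
  if (!is.numeric(n) || length(n) == 0 || anyNA(n) ||
      any(n < least) || any(n != floor(n))) {
    abort(paste0("polymer size `n` must be an integer >= ", least),
          class = "polymc_domain")
  }
  invisible(n)
}

check_energy <- function(U) {
  if (!is.numeric(U) || anyNA(U) || any(U < 0)) {
    abort("deposited energy `U` must be non-negative", class = "polymc_domain")
  }
  invisible(U)
}

#' Activation (combination) probability
#'
#' Probability that a radical event of deposited energy `U` activates a
#' polymer of size `n` for a combination reaction:
#' `P_act(U) = X (1 - F) + X F erf(G U)`, with `(X, F, G)` taken from the
#' size class of `n`.  The value lies in `[X (1 - F), X]`, is
#' non-decreasing in `U`, and is identically 1 for monomers (`n = 1`,
#' where `X = 1` and `F = 0`): free monomers are the growth feedstock and
#' always activate.
#'
#' @param U Non-negative numeric vector, dimensionless deposited energy.
#' @param n Integer vector of polymer sizes, `>= 1`.  Recycled against `U`.
#' @return Numeric vector of probabilities.
#' @examples
#' p_act(0.5, 1)        # always 1 for monomers
#' p_act(c(0, 1, 10), 3)
#' @export
p_act <- function(U, n) {
  check_energy(U)
  check_size(n, 1)
  k <- max(length(U), length(n))
  U <- rep_len(U, k)
  n <- rep_len(n, k)
  pv <- param_vectors()
  row <- findInterval(n, pv$brks)
  X <- pv$X[row]; F <- pv$F[row]; G <- pv$G[row]
  X * (1 - F) + X * F * pracma::erf(G * U)
}

#' Breakdown (scission) probability
#'
#' Probability that a radical event of deposited energy `U` breaks a
#' polymer of size `n` at the event point:
#' `P_brk(U) = X (1 - F) + X F erf(G U^2)`.  A single monomer cannot
#' break, so `n >= 2` is required.
#'
#' @inheritParams p_act
#' @param n Integer vector of polymer sizes, `>= 2`.
#' @return Numeric vector of probabilities.
#' @examples
#' p_brk(c(0, 1, 5), 2)
#' @export
p_brk <- function(U, n) {
  check_energy(U)
  check_size(n, 2)
  k <- max(length(U), length(n))
  U <- rep_len(U, k)
  n <- rep_len(n, k)
  pv <- param_vectors()
  row <- findInterval(n, pv$brks)
  X <- pv$X[row]; F <- pv$F[row]; G <- pv$G[row]
  X * (1 - F) + X * F * pracma::erf(G * U^2)
}

# internal fast paths without validation (hot loop)
p_act_fast <- function(U, n, pv) {
  row <- findInterval(n, pv$brks)
  pv$X[row] * (1 - pv$F[row]) + pv$X[row] * pv$F[row] * pracma::erf(pv$G[row] * U)
}
p_brk_fast <- function(U, n, pv) {
  row <- findInterval(n, pv$brks)
  pv$X[row] * (1 - pv$F[row]) + pv$X[row] * pv$F[row] * pracma::erf(pv$G[row] * U^2)
}

#' Decide the chemical outcome of a radical event
#'
#' Sequential Bernoulli decision: combination with probability
#' `p_act(U, n)`; otherwise, and only for `n >= 2`, breakdown with
#' probability `p_brk(U, n)`; otherwise no event.  Draws from R's random
#' number stream (Mersenne-Twister), so outcomes are reproducible under
#' `set.seed()`.
#'
#' @inheritParams p_act
#' @return A factor with levels `combination`, `breakdown`, `none`, one
#'   element per trial.
#' @examples
#' set.seed(1)
#' table(decide_outcome(rep(0.5, 1000), 6))
#' @export
decide_outcome <- function(U, n) {
  check_energy(U)
  check_size(n, 1)
  k <- max(length(U), length(n))
  U <- rep_len(U, k)
  n <- rep_len(n, k)
  out <- rep.int("none", k)
  comb <- runif(k) < p_act(U, n)
  out[comb] <- "combination"
  rest <- which(!comb & n >= 2)
  if (length(rest)) {
    brk <- runif(length(rest)) < p_brk(U[rest], n[rest])
    out[rest[brk]] <- "breakdown"
  }
  factor(out, levels = c("combination", "breakdown", "none"))
}
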
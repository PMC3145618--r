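#' Stepwise microsatellite mutation model
#'
#' Defines the per-division mutation process of a microsatellite locus:
#' with probability `mu` the repeat count mutates, and a mutation inserts or
#' deletes one or two repeat units. Insertions and deletions are equally
#' likely, and single-unit steps outnumber double-unit steps by
#' `single_to_double_odds` : 1. At most one mutation event occurs per locus
#' per division.
#'
#' With the defaults (`mu = 1/100`, odds 7:1) the per-division net-change
#' probabilities are P(0) = 0.99, P(+1) = P(-1) = (7/16) mu = 0.004375 and
#' P(+2) = P(-2) = (1/16) mu = 0.000625.
#'
#' @param mu Mutation probability per locus per cell division, in (0, 1).
#' @param single_to_double_odds Odds of a single-unit step relative to a
#'   double-unit step; must be positive.
#' @return An object of class `mutation_model`.
#' @examples
#' m <- mutation_model()
#' per_division_pmf(m)
#' @export
mutation_model <- function(mu = 1 / 100, single_to_double_odds = 7) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0 || mu >= 1)
    stop("'mu' must be a single probability strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(single_to_double_odds) || length(single_to_double_odds) != 1L ||
      is.na(single_to_double_odds) || single_to_double_odds <= 0)
    stop("'single_to_double_odds' must be a single positive number", call. = FALSE)
  structure(
    list(mu = mu, single_to_double_odds = single_to_double_odds,
         insertion_deletion_symmetric = TRUE),
    class = "mutation_model"
  )
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf(
    "Stepwise mutation model: mu = %g per locus per division, step odds %g:1 (|1|:|2|), symmetric\n",
    x$mu, x$single_to_double_odds))
  invisible(x)
}

#' Net repeat-change distribution after one cell division
#'
#' @param model A [mutation_model()].
#' @return A `step_distribution`: list with `t` (number of divisions), `k`
#'   (integer support of the net change) and `p` (probabilities summing
#'   to 1).
#' @export
per_division_pmf <- function(model) {
  stopifnot(inherits(model, "mutation_model"))
  r <- model$single_to_double_odds
  p1 <- model$mu * r / (2 * (r + 1))   # each direction, single step
  p2 <- model$mu * 1 / (2 * (r + 1))   # each direction, double step
  structure(
    list(t = 1L, k = -2:2, p = c(p2, p1, 1 - model$mu, p1, p2)),
    class = "step_distribution"
  )
}

#' @export
print.step_distribution <- function(x, ...) {
  cat(sprintf("Net repeat-change pmf after t = %d division(s); support %d..%d\n",
              x$t, min(x$k), max(x$k)))
  invisible(x)
}

# one exact convolution step of pmf (support k) with the 5-point division kernel
.convolve_step <- function(k, p, kern) {
  n <- length(p)
  out <- numeric(n + 4L)
  for (i in seq_len(5L)) out[i:(i + n - 1L)] <- out[i:(i + n - 1L)] + p * kern[i]
  list(k = (min(k) - 2L):(max(k) + 2L), p = out)
}

# drop tail entries whose cumulative mass is below tol; one guard entry is
# kept on each side so at most tol mass is lost per side per call
.truncate_tails <- function(k, p, tol = 1e-14) {
  csum <- cumsum(p)
  lo <- which(csum > tol)[1L]
  rsum <- rev(cumsum(rev(p)))
  hi <- max(which(rsum > tol))
  keep <- max(1L, lo - 1L):min(length(p), hi + 1L)
  list(k = k[keep], p = p[keep])
}

#' Net repeat-change distribution after t cell divisions
#'
#' The t-fold convolution of the per-division distribution, computed by
#' exact iterated polynomial multiplication with tail truncation below
#' 1e-12 total mass.
#'
#' @param model A [mutation_model()].
#' @param t Non-negative integer number of divisions.
#' @return A `step_distribution` with element `t = t`.
#' @export
t_step_distribution <- function(model, t) {
  stopifnot(inherits(model, "mutation_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t != round(t))
    stop("'t' must be a single non-negative integer", call. = FALSE)
  t <- as.integer(t)
  if (t == 0L)
    return(structure(list(t = 0L, k = 0L, p = 1), class = "step_distribution"))
  d1 <- per_division_pmf(model)
  k <- d1$k; p <- d1$p
  if (t > 1L) {
    for (i in 2:t) {
      z <- .convolve_step(k, p, d1$p)
      z <- .truncate_tails(z$k, z$p)
      k <- z$k; p <- z$p
    }
  }
  structure(list(t = t, k = k, p = p), class = "step_distribution")
}

#' Log-likelihood table of absolute net changes over a division grid
#'
#' Precomputes `log P(|net change| considerations | t)` for every t in
#' `0..t_max` and |net change| in `0..k_max`. Because the model is
#' symmetric, only the magnitude of an observed per-locus difference
#' matters, and `log P(d | t) = log P(-d | t)` is read from the column
#' `|d|`. Entries outside the (truncated) support get the sentinel
#' `-1e18` so that such t values are never selected by a likelihood
#' maximiser.
#'
#' @param model A [mutation_model()].
#' @param t_max Largest number of divisions on the grid.
#' @param k_max Largest absolute net change needed.
#' @return Numeric matrix with `t_max + 1` rows (t = 0..t_max) and
#'   `k_max + 1` columns (|d| = 0..k_max).
#' @export
step_loglik_table <- function(model, t_max, k_max) {
  stopifnot(inherits(model, "mutation_model"),
            t_max >= 0, k_max >= 0)
  t_max <- as.integer(t_max); k_max <- as.integer(k_max)
  out <- matrix(-1e18, nrow = t_max + 1L, ncol = k_max + 1L,
                dimnames = list(t = 0:t_max, abs_d = 0:k_max))
  out[1L, 1L] <- 0  # t = 0: point mass at 0
  d1 <- per_division_pmf(model)
  k <- d1$k; p <- d1$p
  for (t in seq_len(t_max)) {
    if (t > 1L) {
      z <- .convolve_step(k, p, d1$p)
      z <- .truncate_tails(z$k, z$p)
      k <- z$k; p <- z$p
    }
    idx <- which(k >= 0 & k <= k_max)
    vals <- p[idx]
    pos <- vals > 0
    out[t + 1L, k[idx][pos] + 1L] <- log(vals[pos])
  }
  out
}
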
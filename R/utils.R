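#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Centered circular moving average
#'
#' Smooths a series that wraps around (values along a circular trajectory)
#' with a centered window of odd width.
#'
#' @param x numeric vector, treated as circular.
#' @param window odd integer window width; `window = 1` is the identity.
#' @return numeric vector of the same length.
#' @export
smooth_series <- function(x, window) {
  n <- length(x)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  if (window == 1) return(x)
  half <- (window - 1) / 2
  # pad circularly and use a running mean via cumsum
  xp <- c(x[(n - half + 1):n], x, x[1:half])
  cs <- cumsum(c(0, xp))
  (cs[(window + 1):(window + n)] - cs[1:n]) / window
}

#' Fisher-Lee circular correlation of two angle vectors
#'
#' Pairwise form `sum sin(a_i - a_j) sin(b_i - b_j)` normalized by the
#' marginal pairwise sums: invariant to rotation of either variable and
#' well defined even when the angles are uniformly spread (where the
#' circular-mean form degenerates).
#'
#' @param a,b numeric vectors of angles (radians).
#' @return correlation in [-1, 1].
#' @keywords internal
circular_cor_angles <- function(a, b) {
  sa <- outer(a, a, function(x, y) sin(x - y))
  sb <- outer(b, b, function(x, y) sin(x - y))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(NA_real_)
  sum(sa * sb) / den
}

#' Circular rank correlation between two circular coordinates
#'
#' Converts each coordinate to ranks mapped onto the circle and computes the
#' Fisher-Lee circular correlation. Because a circular ordering has no
#' preferred origin or direction, the absolute value is returned by default.
#'
#' @param x,y numeric vectors of positions on a circle (any scale; only the
#'   induced circular ordering matters).
#' @param absolute return `abs(r)` (direction-free agreement); default `TRUE`.
#' @return correlation in [0, 1] (or [-1, 1] when `absolute = FALSE`).
#' @export
circular_rank_cor <- function(x, y, absolute = TRUE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  a <- 2 * pi * rank(x, ties.method = "average") / n
  b <- 2 * pi * rank(y, ties.method = "average") / n
  r <- circular_cor_angles(a, b)
  if (absolute) abs(r) else r
}

#' Test whether two circular orderings are identical
#'
#' Two vectors of circular positions define the same circular ordering when
#' one induced cyclic sequence of indices equals the other up to rotation
#' and/or reflection.
#'
#' @param x,y numeric position vectors of equal length (no ties).
#' @return logical.
#' @export
same_circular_ordering <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  ox <- order(x)
  oy <- order(y)
  # align both cyclic sequences to start at index 1
  rot <- function(o) { k <- which(o == 1L); c(o[k:length(o)], o[seq_len(k - 1L)]) }
  a <- rot(ox)
  f <- rot(oy)
  r <- rot(rev(oy))
  identical(a, f) || identical(a, r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
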
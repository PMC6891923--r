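#' Select waypoint cells across an embedding
#'
#' Waypoints are landmark cells spread over the embedding: for each
#' component, cells at evenly spaced ranks are taken as candidates, and each
#' candidate is replaced by the medoid of its local neighborhood (a median
#' filter that keeps outlier cells from being chosen). One waypoint is drawn
#' uniformly as the starting cell.
#'
#' @param E a [diffusion_embed()] result or a cells x dims matrix.
#' @param W number of waypoints (>= 4; two semicircles need two waypoints
#'   each).
#' @param seed integer seed for the random draws.
#' @param filter_k neighborhood size of the median filter (default 10).
#' @return list with `waypoints` (cell ids) and `start` (one cell id).
#' @export
select_waypoints <- function(E, W, seed = 1, filter_k = 10) {
  X <- if (inherits(E, "diffusion_embedding")) E$components else as.matrix(E)
  n <- nrow(X)
  ids <- rownames(X) %||% as.character(seq_len(n))
  if (W < 4) stop("need at least 4 waypoints (2 per semicircle)")
  if (W > n) stop("W exceeds the number of cells")
  with_seed(seed, {
    if (W == n) {
      wp <- seq_len(n)
    } else {
      D <- as.matrix(stats::dist(X))
      per <- ceiling(W / ncol(X))
      cand <- integer(0)
      for (m in seq_len(ncol(X))) {
        ord <- order(X[, m])
        cand <- c(cand, ord[unique(round(seq(1, n, length.out = per)))])
      }
      fk <- min(filter_k, n - 1)
      filt <- vapply(unique(cand), function(cidx) {
        nb <- order(D[cidx, ])[seq_len(fk + 1)]
        nb[which.min(rowSums(D[nb, nb, drop = FALSE]))]
      }, 0L)
      wp <- unique(filt)
      if (length(wp) > W) wp <- sort(sample(wp, W))
      if (length(wp) < W)
        wp <- sort(c(wp, sample(setdiff(seq_len(n), wp), W - length(wp))))
    }
    wp_ids <- ids[wp]
    list(waypoints = wp_ids, start = wp_ids[sample(length(wp_ids), 1)])
  })
}

#' Initial ordering by shortest-path distance from the starting cell
#'
#' @param G kNN graph from [build_knn_graph()].
#' @param s starting cell id.
#' @return named vector of Dijkstra shortest-path distances from `s`
#'   (`tau[s] == 0`).
#' @export
initial_ordering <- function(G, s) {
  d <- igraph::distances(G, v = s, algorithm = "dijkstra")[1, ]
  if (any(!is.finite(d))) stop("cell(s) unreachable from the starting cell")
  d
}

#' Perspective matrix of waypoint-relative positions
#'
#' `P[w, i] = tau[w] + D[w, i]` when `tau[i] > tau[w]`, else
#' `tau[w] - D[w, i]`: each waypoint's estimate of cell `i`'s trajectory
#' position, formed from its shortest-path distance to `i`.
#'
#' @param D waypoints x cells shortest-path distance matrix (row names =
#'   waypoint cell ids, column names = cell ids).
#' @param tau named numeric vector of current trajectory positions.
#' @return matrix `P` of the same shape as `D`.
#' @export
perspective_matrix <- function(D, tau) {
  tau_w <- tau[rownames(D)]
  tau_i <- tau[colnames(D)]
  ahead <- outer(tau_w, tau_i, function(w, i) i > w)
  P <- matrix(rep(tau_w, ncol(D)), nrow(D), ncol(D)) + ifelse(ahead, D, -D)
  dimnames(P) <- dimnames(D)
  P
}

#' Waypoint disagreement matrix
#'
#' `Q[wi, wj] = P[wi, wj] - tau[wj]`: how much waypoint `wi`'s perspective
#' of waypoint `wj` disagrees with `wj`'s own position. Near zero for
#' same-semicircle pairs, large for opposite-semicircle pairs (the two
#' shortest paths wrap around the circle differently).
#'
#' @param P perspective matrix (from [perspective_matrix()]).
#' @param tau named numeric vector of trajectory positions.
#' @param waypoints waypoint cell ids (columns of `P` to keep).
#' @return waypoints x waypoints matrix with zero diagonal.
#' @export
disagreement_matrix <- function(P, tau, waypoints = rownames(P)) {
  Q <- sweep(P[, waypoints, drop = FALSE], 2, tau[waypoints], `-`)
  Q
}

#' Split the circle into two semicircles from waypoint disagreement
#'
#' Waypoints are clustered into two groups by average-linkage hierarchical
#' clustering of `1 - Pearson correlation` between rows of the disagreement
#' magnitudes `|Q|`; the two groups are the two semicircles around the
#' starting cell. (Same-semicircle disagreements are near zero while
#' opposite-semicircle ones are large in magnitude but of data-dependent
#' sign, so the magnitude rows carry the clean two-block pattern.) The
#' starting cell's own row is identically zero and is excluded from the
#' clustering. Every remaining cell joins the semicircle of its nearest
#' waypoint (by shortest-path distance; ties go to semicircle 1).
#'
#' @param Q disagreement matrix.
#' @param D waypoints x cells shortest-path distance matrix.
#' @param exclude waypoint ids left out of the clustering and assigned like
#'   ordinary cells (the starting cell).
#' @return list with `S1`, `S2` (cell-id vectors) and `waypoint_side`
#'   (named 1/2 per waypoint). Errors with class `circlet_split_error` when
#'   a cluster holds fewer than two waypoints.
#' @export
split_semicircles <- function(Q, D, exclude = character(0)) {
  wp <- rownames(Q)
  keep <- setdiff(wp, exclude)
  C <- suppressWarnings(stats::cor(t(abs(Q[keep, , drop = FALSE]))))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  cl_k <- stats::cutree(hc, k = 2)
  # semicircle 1 is the cluster of the first waypoint (stable labeling)
  if (cl_k[1] == 2) cl_k <- 3 - cl_k
  if (min(table(cl_k)) < 2)
    stop(structure(class = c("circlet_split_error", "error", "condition"),
                   list(message = "a semicircle received fewer than 2 waypoints",
                        call = sys.call())))
  cl <- setNames(integer(length(wp)), wp)
  cl[keep] <- cl_k
  for (e in intersect(exclude, wp)) {
    # excluded waypoints join the side of their nearest clustered waypoint
    cl[e] <- cl_k[keep[which.min(D[keep, e])]]
  }
  # order waypoint rows S1-first so which.min ties resolve toward S1
  ord <- order(cl)
  Do <- D[ord, , drop = FALSE]
  cl_o <- cl[ord]
  nearest <- apply(Do, 2, which.min)
  side <- cl_o[nearest]
  list(S1 = colnames(D)[side == 1], S2 = colnames(D)[side == 2],
       waypoint_side = cl)
}

#' Refine a semicircle ordering by Gaussian-weighted waypoint perspectives
#'
#' Each cell's refined position is the weighted average of its semicircle's
#' waypoint perspectives, `tau_i = sum_w P[w, i] * Wgt[w, i]`, with Gaussian
#' weights `exp(-(D[w, i] / sigma)^2)` (`sigma` = standard deviation of the
#' semicircle's distance block) so closer waypoints get a bigger vote. By
#' default weights are normalized per cell over waypoints (so they sum to 1
#' and the estimate is a true weighted average); `weight_norm = "cells"`
#' normalizes each waypoint's weights over cells instead.
#'
#' @param P_S waypoints x cells perspective block for one semicircle.
#' @param D_S matching shortest-path distance block.
#' @param weight_norm `"waypoints"` (default) or `"cells"`.
#' @return named numeric vector of refined positions for the block's cells.
#' @export
refine_ordering <- function(P_S, D_S, weight_norm = c("waypoints", "cells")) {
  weight_norm <- match.arg(weight_norm)
  if (nrow(P_S) == 1) return(setNames(P_S[1, ], colnames(P_S)))
  sigma <- stats::sd(D_S)
  if (!is.finite(sigma) || sigma == 0)
    return(setNames(colMeans(P_S), colnames(P_S)))
  Wgt <- exp(-(D_S / sigma)^2)
  Wgt <- if (weight_norm == "waypoints")
    sweep(Wgt, 2, colSums(Wgt), `/`)
  else
    sweep(Wgt, 1, rowSums(Wgt), `/`)
  setNames(colSums(P_S * Wgt), colnames(P_S))
}

#' Fit a circular cell-cycle trajectory to a feature matrix
#'
#' The core estimator: embeds the cells x features matrix with diffusion
#' maps, builds a k-nearest-neighbor graph, orders cells by shortest-path
#' distance from a randomly chosen starting waypoint, splits the circle into
#' two semicircles via waypoint disagreement, refines each semicircle by
#' Gaussian-weighted waypoint voting, and iterates until successive
#' orderings correlate above `conv_threshold`. The merged trajectory
#' (one semicircle negated) is normalized to `[0, 1]`.
#'
#' @param x cells x features numeric matrix with cell ids as row names
#'   (see [extract_features()]).
#' @param M number of diffusion components (default 15).
#' @param k kNN graph neighbors (default 25).
#' @param W number of waypoints (default `min(150, ceiling(n / 4))`).
#' @param kernel_k diffusion-kernel neighborhood size (default 15).
#' @param seed integer seed driving all randomness (waypoint draw, starting
#'   cell); recorded in the fit.
#' @param max_iter maximum refinement iterations (default 50).
#' @param conv_threshold convergence threshold on the Pearson correlation of
#'   successive iterates (default 0.9999).
#' @param weight_norm passed to [refine_ordering()].
#' @param retries waypoint re-draws allowed when semicircle clustering
#'   degenerates (default 5).
#' @return an object of class `circlet`: list with `tau` (circular positions
#'   in `[0, 1]`), `tau_signed`, `semicircle` (1/2 per cell), `cell_ids`,
#'   `waypoints`, `start_cell`, `converged`, `iterations`, `trace`
#'   (per-iteration correlations), `embedding`, `graph`, `seed`, `params`.
#' @examples
#' theta <- sort(runif(120, 0, 2 * pi))
#' X <- cbind(cos(theta), sin(theta)) + matrix(rnorm(240, sd = 0.05), ncol = 2)
#' rownames(X) <- paste0("c", 1:120)
#' fit <- circlet(X, M = 2, k = 10, W = 24, kernel_k = 10, seed = 1)
#' circular_rank_cor(fit$tau, theta)
#' @export
circlet <- function(x, M = 15, k = 25, W = min(150, ceiling(nrow(x) / 4)),
                    kernel_k = 15, seed = 1, max_iter = 50,
                    conv_threshold = 0.9999,
                    weight_norm = c("waypoints", "cells"), retries = 5) {
  weight_norm <- match.arg(weight_norm)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("cell", seq_len(nrow(x)))
  M <- min(M, nrow(x) - 2)
  E <- diffusion_embed(x, M = M, kernel_k = min(kernel_k, nrow(x) - 2))
  g <- build_knn_graph(E, k = min(k, nrow(x) - 1))
  ids <- igraph::V(g)$name
  n <- length(ids)

  attempt <- 0
  repeat {
    wsel <- select_waypoints(E, W = W, seed = seed + attempt)
    wp <- wsel$waypoints
    s <- wsel$start
    D <- igraph::distances(g, v = wp, algorithm = "dijkstra")
    D <- D[, ids, drop = FALSE]
    tau <- D[s, ]
    trace <- numeric(0)
    converged <- FALSE
    split <- NULL
    fail <- FALSE
    for (t in seq_len(max_iter)) {
      P <- perspective_matrix(D, tau)
      Q <- disagreement_matrix(P, tau, wp)
      split <- tryCatch(split_semicircles(Q, D, exclude = s),
                        circlet_split_error = function(e) NULL)
      if (is.null(split)) { fail <- TRUE; break }
      tau_new <- setNames(numeric(n), ids)
      for (side in 1:2) {
        cells_S <- if (side == 1) split$S1 else split$S2
        wps_S <- wp[split$waypoint_side == side]
        if (!length(cells_S)) next
        tau_S <- refine_ordering(P[wps_S, cells_S, drop = FALSE],
                                 D[wps_S, cells_S, drop = FALSE],
                                 weight_norm = weight_norm)
        # first iterate starts from unsigned distances: orient S1 negative;
        # later iterates carry the sign through the perspectives themselves
        if (t == 1 && side == 1) tau_S <- -tau_S
        tau_new[cells_S] <- tau_S
      }
      r <- suppressWarnings(stats::cor(tau_new, tau))
      trace <- c(trace, r)
      tau <- tau_new
      if (is.finite(r) && r > conv_threshold) { converged <- TRUE; break }
    }
    if (!fail) break
    attempt <- attempt + 1
    if (attempt > retries)
      stop("semicircle clustering failed after ", retries, " waypoint re-draws")
    warning("degenerate semicircle split; re-drawing waypoints (attempt ",
            attempt, ")")
  }
  if (!converged)
    warning("did not converge within ", max_iter,
            " iterations; returning last iterate")
  rng <- range(tau)
  tau_final <- if (diff(rng) > 0) (tau - rng[1]) / diff(rng) else tau * 0
  semicircle <- setNames(ifelse(ids %in% split$S1, 1L, 2L), ids)
  structure(list(cell_ids = ids, tau = tau_final, tau_signed = tau,
                 semicircle = semicircle, waypoints = wp, start_cell = s,
                 converged = converged, iterations = length(trace),
                 trace = trace, embedding = E, graph = g, seed = seed,
                 params = list(M = M, k = k, W = W, kernel_k = kernel_k,
                               max_iter = max_iter,
                               conv_threshold = conv_threshold,
                               weight_norm = weight_norm)),
            class = "circlet")
}

#' @export
print.circlet <- function(x, ...) {
  cat("Circular trajectory fit (circlet)\n")
  cat("  cells:      ", length(x$cell_ids), "\n")
  cat("  waypoints:  ", length(x$waypoints), " (start: ", x$start_cell, ")\n",
      sep = "")
  cat("  iterations: ", x$iterations,
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  cat("  semicircles:", sum(x$semicircle == 1), "/", sum(x$semicircle == 2),
      "cells\n")
  invisible(x)
}

#' @export
summary.circlet <- function(object, ...) {
  cat("Circular cell-cycle trajectory\n\n")
  print(object)
  cat("\nconvergence trace (corr of successive iterates):\n")
  print(round(object$trace, 6))
  cat("\ntau quartiles:\n")
  print(stats::quantile(object$tau))
  invisible(object)
}

#' @export
fitted.circlet <- function(object, ...) object$tau

#' @export
plot.circlet <- function(x, components = c(1, 2), ...) {
  comp <- x$embedding$components[, components, drop = FALSE]
  cols <- grDevices::hsv(x$tau * 0.85)
  plot(comp, col = cols, pch = 19,
       xlab = colnames(comp)[1], ylab = colnames(comp)[2],
       main = "Diffusion embedding colored by circular pseudotime", ...)
  invisible(x)
}

#' Tabulate a fitted circular trajectory
#'
#' @param fit a [circlet()] fit.
#' @return data.frame with `cell_id`, `tau`, `semicircle`, `rank`.
#' @export
trajectory_table <- function(fit) {
  stopifnot(inherits(fit, "circlet"))
  data.frame(cell_id = fit$cell_ids, tau = unname(fit$tau),
             semicircle = unname(fit$semicircle),
             rank = rank(fit$tau, ties.method = "first"),
             stringsAsFactors = FALSE)
}

#' The two equivalent semicircle merge variants of a fit
#'
#' A converged fit merges the semicircle trajectories as
#' `[-tau_S1, tau_S2]`; the alternative merge `[tau_S1, -tau_S2]` defines
#' the same circular ordering (reflected). Both normalized variants are
#' returned for verification.
#'
#' @param fit a [circlet()] fit.
#' @return list with numeric vectors `primary` and `alternative`, both in
#'   `[0, 1]`.
#' @export
merge_variants <- function(fit) {
  norm01 <- function(v) { r <- range(v); if (diff(r) > 0) (v - r[1]) / diff(r) else v * 0 }
  list(primary = norm01(fit$tau_signed),
       alternative = norm01(-fit$tau_signed))
}
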
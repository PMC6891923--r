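#' Diffusion-map embedding of a feature matrix
#'
#' Reduces a cells x features matrix to `M` diffusion components: an
#' adaptive-bandwidth Gaussian kernel is evaluated on the union of each
#' point's `kernel_k` nearest neighbors, row-normalized into a Markov
#' transition matrix, and eigendecomposed (via the conjugate symmetric
#' matrix). The trivial constant component is dropped and the remaining
#' eigenvectors, scaled by their eigenvalues, are returned in decreasing
#' eigenvalue order.
#'
#' @param F cells x features numeric matrix with cell ids as row names.
#' @param M number of components to return (>= 2).
#' @param kernel_k neighborhood size for the adaptive kernel bandwidth
#'   (default 15); point `i`'s bandwidth is its distance to its
#'   `kernel_k`-th nearest neighbor.
#' @return object of class `diffusion_embedding`: list with `components`
#'   (cells x M matrix), `eigenvalues`, `cell_ids`.
#' @export
diffusion_embed <- function(F, M = 15, kernel_k = 15) {
  if (!all(is.finite(F))) stop("feature matrix contains non-finite values")
  n <- nrow(F)
  if (n < max(kernel_k, M) + 1)
    stop("need at least max(kernel_k, M) + 1 cells")
  D <- as.matrix(stats::dist(F))
  # adaptive bandwidth: distance to the kernel_k-th neighbor (excluding self)
  sig <- apply(D, 1, function(d) sort(d)[kernel_k + 1])
  sig[sig == 0] <- min(sig[sig > 0], 1e-12)
  W <- exp(-D^2 / outer(sig, sig))
  # keep only neighborhood entries (union-symmetrized kNN mask) + self
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(kernel_k + 1)]
    mask[i, nb] <- TRUE
  }
  mask <- mask | t(mask)
  W[!mask] <- 0
  deg <- rowSums(W)
  if (any(deg == 0)) stop("isolated point in kernel graph; increase kernel_k")
  ds <- 1 / sqrt(deg)
  S <- W * outer(ds, ds)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  if (M + 1 > n) stop("M exceeds available components")
  lam <- eig$values[2:(M + 1)]
  phi <- (ds * eig$vectors)[, 2:(M + 1), drop = FALSE]
  comp <- sweep(phi, 2, lam, `*`)
  colnames(comp) <- paste0("DC", seq_len(M))
  rownames(comp) <- rownames(F)
  structure(list(components = comp, eigenvalues = lam,
                 cell_ids = rownames(F)),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat("diffusion_embedding:", nrow(x$components), "cells,",
      ncol(x$components), "components\n")
  invisible(x)
}

#' Build a k-nearest-neighbor graph in an embedding
#'
#' Directed kNN relations by Euclidean distance, symmetrized by union; edge
#' weights are the Euclidean distances. Errors if the graph is disconnected
#' (a circular trajectory over a fragment would be meaningless).
#'
#' @param E a [diffusion_embed()] result or a plain cells x dims matrix.
#' @param k number of nearest neighbors (`k < n`).
#' @return an `igraph` weighted undirected graph whose vertex names are cell
#'   ids (or row indices as character).
#' @export
build_knn_graph <- function(E, k) {
  X <- if (inherits(E, "diffusion_embedding")) E$components else as.matrix(E)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of cells")
  D <- as.matrix(stats::dist(X))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1)]
    from <- c(from, rep(i, k)); to <- c(to, nb)
  }
  # union symmetrization: undirected edge when either direction is a kNN link
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  ids <- rownames(X) %||% as.character(seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[a], to = ids[b], weight = D[cbind(a, b)]),
    directed = FALSE,
    vertices = data.frame(name = ids))
  if (igraph::components(g)$no > 1)
    stop("kNN graph is disconnected; increase k")
  g
}
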
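# Shared fixtures and independent oracles, built in code at test time.

toy_binning <- function(sizes = c(chr1 = 2e6, chr2 = 1e6), bw = 1e5)
  genome_binning(sizes, bw)

toy_cell <- function(triplets, binning = toy_binning(), id = "c1")
  contact_map(do.call(rbind, lapply(triplets, function(t)
    data.frame(chrom = t[[1]], i = as.numeric(t[[2]]), j = as.numeric(t[[3]]),
               count = as.numeric(t[[4]])))), binning, cell_id = id)

random_toy_cell <- function(binning = toy_binning(), n = 30, id = "c") {
  ch <- sample(names(binning$chrom_sizes), n, replace = TRUE)
  nb <- binning$n_bins[ch]
  i <- floor(runif(n) * nb)
  j <- floor(runif(n) * nb)
  contact_map(data.frame(chrom = ch, i = pmin(i, j), j = pmax(i, j),
                         count = sample(1:3, n, replace = TRUE)),
              binning, cell_id = id)
}

# noisy 2D circle point cloud with known angles
circle_points <- function(n, noise = 0.05, r = 1) {
  theta <- sort(runif(n, 0, 2 * pi))
  X <- cbind(r * cos(theta), r * sin(theta)) +
    matrix(rnorm(2 * n, sd = noise), ncol = 2)
  rownames(X) <- sprintf("p%03d", seq_len(n))
  list(X = X, theta = setNames(theta, rownames(X)))
}

# weighted ring graph on n nodes (unit weights by default)
ring_graph <- function(n, weights = rep(1, n)) {
  ids <- as.character(seq_len(n) - 1)
  igraph::graph_from_data_frame(
    data.frame(from = ids, to = ids[c(2:n, 1)], weight = weights),
    directed = FALSE, vertices = data.frame(name = ids))
}

# Floyd-Warshall all-pairs shortest paths: independent of igraph's Dijkstra
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- adj
  D[D == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

ring_adjacency <- function(n, weights = rep(1, n)) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- weights[i]
  }
  dimnames(A) <- list(as.character(seq_len(n) - 1), as.character(seq_len(n) - 1))
  A
}

# brute-force insulation score by literal double summation over the formula
insulation_bruteforce <- function(A, scale) {
  n <- nrow(A)
  v <- rep(NA_real_, n)
  for (b in (scale + 1):(n - scale)) {
    sq <- 0
    for (i in (b - scale):(b + scale)) for (j in (b - scale):(b + scale))
      sq <- sq + A[i, j]
    cr <- 0
    for (i in (b - scale):b) for (j in b:(b + scale)) cr <- cr + A[i, j]
    v[b] <- if (cr > 0) sq / cr else NA_real_
  }
  v
}

# ROC AUC by explicit threshold sweep (trapezoidal), positives score LOW:
# classify "positive" when value < t, sweep t over all distinct values
auc_threshold_sweep <- function(pos, neg) {
  thr <- c(sort(unique(c(pos, neg))), Inf)
  tpr <- vapply(thr, function(t) mean(pos < t), 0)
  fpr <- vapply(thr, function(t) mean(neg < t), 0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# number of runs of a label sequence read circularly
circular_runs <- function(x) {
  r <- rle(x)$lengths
  n <- length(r)
  if (n > 1 && x[1] == x[length(x)]) n - 1 else n
}

# memoized default simulation shared by the heavier tests
.sim_cache <- new.env()
default_sim <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- simulate_schic(sim_spec(seed = seed))
    Fm <- suppressMessages(extract_features(sim$cells))
    .sim_cache[[key]] <- list(sim = sim, features = Fm,
                              theta = setNames(sim$truth$theta, sim$truth$cell_id),
                              labels = setNames(sim$truth$phase, sim$truth$cell_id))
  }
  .sim_cache[[key]]
}
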
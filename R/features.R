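#' Contact-distance distribution (CDD) features for one cell
#'
#' Distributes a cell's contacts over logarithmically spaced genomic-distance
#' bins. For each exponent step `s` the bin of a contact at distance `d` (bp)
#' is `loc = floor((log2(d) + s) / s)` (default variant) or
#' `floor(log2(d) / s)` (`variant = "plain"`); counts per bin are normalized
#' to probabilities that sum to 1 per step, and the per-step vectors are
#' concatenated. Only contacts with `d > min_distance` contribute.
#'
#' @param cell a [contact_map()].
#' @param steps exponent steps; default `c(0.1, 0.125, 0.2, 0.33)`.
#' @param min_distance minimum genomic distance in bp (strict; default 20 kb).
#' @param variant log-bin formula variant, `"shifted"` (default) or `"plain"`.
#' @return named numeric feature vector (probabilities; sums to 1 per step).
#' @export
cdd_features <- function(cell, steps = c(0.1, 0.125, 0.2, 0.33),
                         min_distance = 20e3,
                         variant = c("shifted", "plain")) {
  variant <- match.arg(variant)
  stopifnot(all(steps > 0), min_distance > 0)
  dc <- contact_distances(cell)
  dc <- dc[dc$distance > min_distance, ]
  if (!nrow(dc))
    stop("no usable contacts (d > ", min_distance, ") in cell '",
         cell$cell_id, "'")
  loc_of <- function(d, s)
    if (variant == "shifted") floor((log2(d) + s) / s) else floor(log2(d) / s)
  d_max <- max(cell$binning$chrom_sizes)
  out <- numeric(0)
  for (s in steps) {
    lo <- loc_of(min_distance, s)
    hi <- loc_of(d_max, s)
    counts <- numeric(hi - lo + 1)
    loc <- loc_of(dc$distance, s)
    agg <- rowsum(dc$count, loc)
    counts[as.integer(rownames(agg)) - lo + 1] <- agg[, 1]
    p <- counts / sum(counts)
    names(p) <- sprintf("cdd_s%s_loc%d", format(s), lo:hi)
    out <- c(out, p)
  }
  out
}

#' CDD feature matrix over a list of cells
#'
#' @param cells list of [contact_map()] objects sharing one binning.
#' @param ... passed to [cdd_features()].
#' @return cells x features matrix with cell ids as row names.
#' @export
cdd_matrix <- function(cells, ...) {
  rows <- lapply(cells, cdd_features, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(cells, `[[`, "", "cell_id")
  m
}

#' Pairs' contact coverage (PCC) features
#'
#' The interaction significance of bin pair `(i, j)` is its mean count across
#' all cells, `value(A_ij) = sum_k A_ij^k / K`. Pairs whose value exceeds the
#' `value_quantile` quantile over all observed pairs are retained as
#' significant; each cell's feature at a retained pair is its count there
#' normalized by the cell's total contacts. The across-cell variance
#' `var(A_ij)` is available as an alternative selector.
#'
#' @param cells list of >= 2 [contact_map()] objects sharing one binning.
#' @param value_quantile selection quantile on pair values (default 0.99,
#'   i.e. keep the top 1 percent).
#' @param selector rank pairs by mean (`"value"`, default) or variance
#'   (`"variance"`) across cells.
#' @return cells x retained-pairs matrix with cell ids as row names.
#' @export
pcc_features <- function(cells, value_quantile = 0.99,
                         selector = c("value", "variance")) {
  selector <- match.arg(selector)
  stopifnot(length(cells) >= 2, value_quantile > 0, value_quantile < 1)
  K <- length(cells)
  ids <- vapply(cells, `[[`, "", "cell_id")
  all_ct <- do.call(rbind, lapply(seq_along(cells), function(k) {
    ct <- cells[[k]]$contacts
    if (nrow(ct)) ct$cell <- k
    ct
  }))
  if (!nrow(all_ct) || all(all_ct$count == 0)) stop("all contact counts are zero")
  key <- paste(all_ct$chrom, all_ct$i, all_ct$j)
  sums <- rowsum(all_ct$count, key)
  value <- sums[, 1] / K
  if (selector == "variance") {
    # var over all K cells, zeros included for cells lacking the pair
    sq <- rowsum(all_ct$count^2, key)
    stat <- (sq[, 1] - K * (sums[, 1] / K)^2) / (K - 1)
    names(stat) <- rownames(sq)
  } else stat <- setNames(value, rownames(sums))
  thr <- stats::quantile(stat, value_quantile, names = FALSE)
  keep <- names(stat)[stat > thr]
  if (!length(keep))
    stop("no bin pairs above the ", value_quantile,
         " quantile; lower value_quantile")
  keep <- sort(keep)
  m <- matrix(0, K, length(keep), dimnames = list(ids, paste0("pcc_", gsub(" ", "_", keep))))
  hit <- key %in% keep
  idx <- cbind(all_ct$cell[hit], match(key[hit], keep))
  m[idx] <- all_ct$count[hit]
  tot <- vapply(cells, `[[`, 0, "total_contacts")
  tot[tot == 0] <- 1
  m / tot
}

#' Insulation score per bin
#'
#' For each interior bin `b` of each chromosome the insulation score is the
#' ratio of the total contacts in the square window
#' `i, j in [b - scale, b + scale]` of the symmetric contact matrix to the
#' contacts in the cross window `i in [b - scale, b], j in [b, b + scale]`
#' (contacts bridging the bin). Large values mark insulating (boundary-like)
#' bins. Non-interior bins and bins with a zero cross-window sum are `NA`.
#'
#' @param map a [contact_map()] (single cell or pooled).
#' @param scale window half-width in bins (>= 1).
#' @param chroms chromosomes to score (default: all in the binning).
#' @return named list: per chromosome, a numeric vector over bins
#'   (`NA` where undefined).
#' @export
insulation_score <- function(map, scale, chroms = names(map$binning$chrom_sizes)) {
  stopifnot(scale >= 1)
  out <- list()
  for (ch in chroms) {
    A <- dense_matrix(map, ch)
    n <- nrow(A)
    v <- rep(NA_real_, n)
    if (n >= 2 * scale + 1) {
      # summed-area table for O(1) rectangle sums
      S <- matrix(0, n + 1, n + 1)
      S[-1, -1] <- apply(apply(A, 2, cumsum), 1, cumsum)
      rect <- function(r1, r2, c1, c2)
        S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
      for (b in (scale + 1):(n - scale)) {
        sq <- rect(b - scale, b + scale, b - scale, b + scale)
        cr <- rect(b - scale, b, b, b + scale)
        v[b] <- if (cr > 0) sq / cr else NA_real_
      }
    }
    out[[ch]] <- v
  }
  out
}

#' Insulation (Ins) feature matrix over a list of cells
#'
#' Scores every cell's bins with [insulation_score()] and keeps the bins whose
#' across-cell mean (or variance) of the score exceeds the
#' `selection_quantile` quantile over candidate bins. Only bins with a defined
#' score in every cell are candidates.
#'
#' @param cells list of >= 2 [contact_map()] objects sharing one binning.
#' @param scale window half-width in bins.
#' @param selection_quantile quantile threshold (default 0.90).
#' @param selection_mode `"mean"` (default) or `"variance"`.
#' @return cells x selected-bins matrix with cell ids as row names.
#' @export
ins_features <- function(cells, scale, selection_quantile = 0.90,
                         selection_mode = c("mean", "variance")) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(length(cells) >= 2)
  ids <- vapply(cells, `[[`, "", "cell_id")
  per_cell <- lapply(cells, function(cl)
    unlist(insulation_score(cl, scale)))
  m <- do.call(rbind, per_cell)
  rownames(m) <- ids
  chroms <- names(cells[[1]]$binning$n_bins)
  colnames(m) <- unlist(lapply(chroms, function(ch)
    sprintf("ins_%s_b%d", ch, seq_len(cells[[1]]$binning$n_bins[[ch]]) - 1L)))
  ok <- colSums(is.na(m)) == 0
  m <- m[, ok, drop = FALSE]
  if (!ncol(m)) stop("insulation undefined everywhere; maps too sparse")
  stat <- if (selection_mode == "mean") colMeans(m) else apply(m, 2, stats::var)
  thr <- stats::quantile(stat, selection_quantile, names = FALSE)
  keep <- stat > thr
  if (selection_quantile == 0) keep <- rep(TRUE, length(stat))
  if (!any(keep))
    stop("no bin passes the ", selection_quantile,
         " quantile; lower selection_quantile")
  m[, keep, drop = FALSE]
}

#' Multiple composite metrics (MCM) for one cell
#'
#' The per-cell summary metrics: percentage of near contacts
#' (`d < near_max`), percentage of mitotic-band contacts
#' (`mitotic_band[1] <= d <= mitotic_band[2]`), mean genomic distance of
#' far-end contacts (`d > far_min`), and — when a replication-timing
#' annotation is supplied — the fraction of early-replicating fragment ends
#' out of all fragment ends.
#'
#' @param cell a [contact_map()].
#' @param near_max near-contact threshold in bp (default 2 Mb).
#' @param mitotic_band mitotic-band distance range in bp (default 2-12 Mb).
#' @param far_min far-end threshold in bp (default 4.5 Mb).
#' @param replication_timing optional interval data.frame of early-replicating
#'   regions (see [genomic_intervals()]); when `NULL` the early fraction is
#'   omitted and the vector has three entries.
#' @return named numeric vector (`pct_near`, `pct_mitotic`, `mean_far_dist`
#'   and optionally `early_frac`). Percentages are on the 0-100 scale. Cells
#'   without far contacts get `mean_far_dist = far_min` with a warning.
#' @export
mcm_features <- function(cell, near_max = 2e6, mitotic_band = c(2e6, 12e6),
                         far_min = 4.5e6, replication_timing = NULL) {
  stopifnot(near_max <= mitotic_band[1], mitotic_band[1] < mitotic_band[2])
  dc <- contact_distances(cell)
  if (!nrow(dc) || sum(dc$count) == 0)
    stop("cell '", cell$cell_id, "' has no contacts")
  tot <- sum(dc$count)
  pct_near <- 100 * sum(dc$count[dc$distance < near_max]) / tot
  mit <- dc$distance >= mitotic_band[1] & dc$distance <= mitotic_band[2]
  pct_mitotic <- 100 * sum(dc$count[mit]) / tot
  far <- dc$distance > far_min
  if (any(far)) {
    mean_far <- sum(dc$distance[far] * dc$count[far]) / sum(dc$count[far])
  } else {
    warning("cell '", cell$cell_id, "' has no far contacts; mean_far_dist set to far_min")
    mean_far <- far_min
  }
  out <- c(pct_near = pct_near, pct_mitotic = pct_mitotic,
           mean_far_dist = mean_far)
  if (!is.null(replication_timing)) {
    bw <- cell$binning$bin_width
    ct <- cell$contacts
    fends <- genomic_intervals(rep(ct$chrom, 2),
                               c(ct$i, ct$j) * bw,
                               c(ct$i, ct$j) * bw + bw)
    w <- rep(ct$count, 2)
    early <- overlaps_any(fends, replication_timing)
    out <- c(out, early_frac = sum(w[early]) / sum(w))
  }
  out
}

#' MCM feature matrix over a list of cells
#'
#' @param cells list of [contact_map()] objects.
#' @param ... passed to [mcm_features()].
#' @return cells x metrics matrix with cell ids as row names.
#' @export
mcm_matrix <- function(cells, ...) {
  m <- do.call(rbind, lapply(cells, mcm_features, ...))
  rownames(m) <- vapply(cells, `[[`, "", "cell_id")
  m
}

#' Assemble named feature sets into one feature matrix
#'
#' Column-binds per-set matrices (rows = cells, matched by cell id) and
#' optionally standardizes every column to zero mean and unit variance.
#' Constant columns are dropped (with a message) when standardizing.
#'
#' @param sets named list of cells x features matrices with identical row
#'   names.
#' @param standardize center/scale columns (default `TRUE`).
#' @return cells x features matrix; attribute `"provenance"` records the set
#'   names and column counts.
#' @export
assemble_features <- function(sets, standardize = TRUE) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  ids <- rownames(sets[[1]])
  for (nm in names(sets)) {
    miss <- setdiff(ids, rownames(sets[[nm]]))
    extra <- setdiff(rownames(sets[[nm]]), ids)
    if (length(miss) || length(extra))
      stop("feature set '", nm, "' does not cover the same cells; missing: ",
           paste(miss, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "))
    sets[[nm]] <- sets[[nm]][ids, , drop = FALSE]
  }
  m <- do.call(cbind, sets)
  if (standardize) {
    v <- apply(m, 2, stats::var)
    if (any(v == 0)) {
      message(sum(v == 0), " constant feature column(s) dropped")
      m <- m[, v > 0, drop = FALSE]
    }
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  attr(m, "provenance") <- list(sets = names(sets),
                                n_features = vapply(sets, ncol, 0L),
                                standardized = standardize)
  m
}

#' Extract and assemble the standard feature combination from cells
#'
#' Convenience wrapper running the requested feature sets and assembling
#' them. The default combination MCM + PCC + CDD pairs one global-structure
#' feature set with two local-interaction sets.
#'
#' @param cells list of [contact_map()] objects sharing one binning.
#' @param sets character subset of `c("mcm", "cdd", "pcc", "ins")`.
#' @param cdd,pcc,ins,mcm named lists of extra arguments for the per-set
#'   extractors.
#' @param standardize passed to [assemble_features()].
#' @return assembled feature matrix.
#' @export
extract_features <- function(cells, sets = c("mcm", "cdd", "pcc"),
                             cdd = list(), pcc = list(), ins = list(),
                             mcm = list(), standardize = TRUE) {
  sets <- match.arg(sets, c("mcm", "cdd", "pcc", "ins"), several.ok = TRUE)
  out <- list()
  for (s in sets)
    out[[s]] <- switch(s,
      mcm = do.call(mcm_matrix, c(list(cells), mcm)),
      cdd = do.call(cdd_matrix, c(list(cells), cdd)),
      pcc = do.call(pcc_features, c(list(cells), pcc)),
      ins = do.call(ins_features, c(list(cells), ins)))
  assemble_features(out, standardize = standardize)
}
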
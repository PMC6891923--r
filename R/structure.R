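#' Call insulation boundaries from per-stage insulation profiles
#'
#' With the square-to-cross-window insulation score, insulating (boundary)
#' bins are local maxima of the profile. Candidate bins (local maxima with
#' positive prominence) are kept when their score exceeds a uniform
#' threshold: the `quantile` quantile of insulation scores over all defined
#' bins of all stages jointly.
#'
#' @param profiles named list: per stage, an [insulation_score()] result
#'   (list of per-chromosome score vectors).
#' @param binning the shared [genome_binning()].
#' @param quantile threshold quantile (default 0.90).
#' @return data.frame of boundary calls: `chrom`, `start`, `end` (the bin),
#'   `name`, `score`, `stage`.
#' @export
call_boundaries <- function(profiles, binning, quantile = 0.90) {
  all_vals <- unlist(profiles)
  all_vals <- all_vals[is.finite(all_vals)]
  if (!length(all_vals)) stop("insulation undefined everywhere")
  thr <- if (quantile > 0) stats::quantile(all_vals, quantile, names = FALSE)
         else -Inf
  bw <- binning$bin_width
  out <- list()
  for (st in names(profiles)) {
    for (ch in names(profiles[[st]])) {
      v <- profiles[[st]][[ch]]
      n <- length(v)
      for (b in seq_len(n)) {
        if (!is.finite(v[b])) next
        left <- if (b > 1) v[b - 1] else NA
        right <- if (b < n) v[b + 1] else NA
        # interior local maximum: both flanks defined, rises from the left
        is_max <- is.finite(left) && is.finite(right) &&
                  v[b] > left && v[b] >= right
        if (is_max && v[b] > thr) {
          out[[length(out) + 1]] <- data.frame(
            chrom = ch, start = (b - 1) * bw,
            end = min(b * bw, binning$chrom_sizes[[ch]]),
            name = sprintf("%s_%s_b%d", st, ch, b - 1),
            score = v[b], stage = st, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      score = numeric(), stage = character()))
  do.call(rbind, out)
}

#' Merge per-stage boundary calls and classify them
#'
#' Boundaries from different substages lying within one bin of each other
#' are merged (greedily along each chromosome), subject to the size cap
#' `n_stages * bin_width` on the merged extent; the merged score is the max
#' of the members. Boundaries present in all substages are `common`, those
#' in exactly one are `specific:<stage>`, the rest `other`.
#'
#' @param boundaries [call_boundaries()] output (or a previous merge).
#' @param n_stages number of substages.
#' @param bin_width bin width in bp.
#' @return data.frame: `chrom`, `start`, `end`, `name`, `score`, `stages`
#'   (comma-joined), `n_stages_present`, `class`.
#' @export
merge_and_classify <- function(boundaries, n_stages, bin_width) {
  if (!nrow(boundaries))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      stages = character(), n_stages_present = integer(),
                      class = character()))
  stage_of <- if ("stages" %in% names(boundaries))
    strsplit(boundaries$stages, ",") else as.list(boundaries$stage)
  cap <- n_stages * bin_width
  out <- list()
  for (ch in unique(boundaries$chrom)) {
    idx <- which(boundaries$chrom == ch)
    idx <- idx[order(boundaries$start[idx])]
    cur <- NULL
    flush <- function(cur) {
      stgs <- sort(unique(unlist(cur$stages)))
      k <- length(stgs)
      cls <- if (k == n_stages) "common"
             else if (k == 1) paste0("specific:", stgs) else "other"
      data.frame(chrom = ch, start = cur$start, end = cur$end,
                 name = sprintf("%s_%d_%d", ch, cur$start, cur$end),
                 score = cur$score, stages = paste(stgs, collapse = ","),
                 n_stages_present = k, class = cls, stringsAsFactors = FALSE)
    }
    for (i in idx) {
      s <- boundaries$start[i]; e <- boundaries$end[i]
      if (is.null(cur)) {
        cur <- list(start = s, end = e, score = boundaries$score[i],
                    stages = stage_of[i])
      } else if (s - cur$end <= bin_width &&
                 max(e, cur$end) - cur$start < cap) {
        cur$end <- max(e, cur$end)
        cur$score <- max(cur$score, boundaries$score[i])
        cur$stages <- c(cur$stages, stage_of[i])
      } else {
        out[[length(out) + 1]] <- flush(cur)
        cur <- list(start = s, end = e, score = boundaries$score[i],
                    stages = stage_of[i])
      }
    }
    out[[length(out) + 1]] <- flush(cur)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enrichment of regions for genomic feature classes
#'
#' Observed overlap counts (features of each class overlapping any region)
#' divided by the mean count over `n_draws` randomizations in which each
#' region is replaced by a random same-size region of the same chromosome.
#'
#' @param regions interval data.frame (boundaries or loop anchors).
#' @param features interval data.frame with a `class` column (e.g. 3'UTR,
#'   5'UTR, exon, intron, promoter).
#' @param chrom_sizes named chromosome lengths.
#' @param n_draws number of random draws (default 1000).
#' @param seed integer seed.
#' @return data.frame per class: `class`, `observed`, `expected`, `fold`.
#' @export
feature_enrichment <- function(regions, features, chrom_sizes,
                               n_draws = 1000, seed = 1) {
  missing_ch <- setdiff(unique(regions$chrom), names(chrom_sizes))
  if (length(missing_ch)) stop("chrom_sizes missing: ",
                               paste(missing_ch, collapse = ", "))
  drop <- !(regions$chrom %in% unique(features$chrom))
  if (any(drop)) {
    warning(sum(drop), " region(s) on chromosomes absent from features excluded")
    regions <- regions[!drop, ]
  }
  classes <- sort(unique(features$class))
  count_by_class <- function(regs) vapply(classes, function(cl) {
    f <- features[features$class == cl, ]
    sum(overlaps_any(f, regs))
  }, 0)
  obs <- count_by_class(regions)
  width <- regions$end - regions$start
  exp_sum <- numeric(length(classes))
  with_seed(seed, {
    for (d in seq_len(n_draws)) {
      s <- floor(stats::runif(nrow(regions), 0,
                              chrom_sizes[regions$chrom] - width))
      rnd <- genomic_intervals(regions$chrom, s, s + width)
      exp_sum <- exp_sum + count_by_class(rnd)
    }
  })
  expd <- exp_sum / n_draws
  data.frame(class = classes, observed = obs, expected = expd,
             fold = ifelse(expd > 0, obs / expd,
                           ifelse(obs > 0, Inf, NA)),
             row.names = NULL)
}

#' Normalize a dense contact matrix
#'
#' `"oe"` divides each diagonal by its mean (observed/expected);
#' `"kr"` balances the matrix to uniform row/column sums by iterative
#' proportional fitting (tolerance 1e-6, max 200 iterations);
#' `"none"` returns the matrix unchanged.
#'
#' @param A symmetric numeric matrix.
#' @param method `"oe"`, `"kr"` or `"none"`.
#' @return normalized matrix.
#' @export
normalize_map <- function(A, method = c("oe", "kr", "none")) {
  method <- match.arg(method)
  if (method == "none") return(A)
  n <- nrow(A)
  if (method == "oe") {
    B <- A
    for (d in 0:(n - 1)) {
      i <- seq_len(n - d)
      m <- mean(A[cbind(i, i + d)])
      if (m > 0) {
        B[cbind(i, i + d)] <- A[cbind(i, i + d)] / m
        if (d > 0) B[cbind(i + d, i)] <- B[cbind(i, i + d)]
      }
    }
    return(B)
  }
  # iterative proportional fitting toward doubly stochastic (nonzero rows)
  x <- rep(1, n)
  nz <- rowSums(A) > 0
  for (it in seq_len(200)) {
    r <- (A %*% (x))[, 1] * x
    r[!nz] <- 1
    if (max(abs(r[nz] - 1)) < 1e-6) break
    x[nz] <- x[nz] / sqrt(r[nz])
  }
  diag(x) %*% A %*% diag(x)
}

#' Aggregate peak analysis (APA) of a loop set
#'
#' Averages `(2 pad + 1) x (2 pad + 1)`-bin submatrices of the normalized
#' contact map centered at each loop (upper triangle). With 25 kb bins and
#' `pad = 6` the window is the standard 325 kb x 325 kb square (13 x 13
#' bins). Enrichment is the central pixel over the mean of the lower-left
#' corner block (KR mode) or over the mean of the four corner blocks (o/e
#' mode); corner blocks are `floor(pad / 2)` pixels square. Loops whose
#' window would leave the matrix or cross the diagonal are skipped and
#' counted.
#'
#' @param loops BEDPE-style loop data.frame (see [read_bedpe()]).
#' @param map a pooled [contact_map()].
#' @param pad window half-width in bins (default 6).
#' @param norm normalization mode, `"kr"`, `"oe"` or `"none"` (corner rule:
#'   `"oe"` uses four corners, otherwise lower-left).
#' @return object of class `apa_result`: list with `matrix` (average
#'   submatrix), `enrichment`, `norm`, `pad`, `corner`, `n_used`,
#'   `n_skipped`.
#' @export
apa <- function(loops, map, pad = 6, norm = c("kr", "oe", "none")) {
  norm <- match.arg(norm)
  bw <- map$binning$bin_width
  side <- 2 * pad + 1
  acc <- matrix(0, side, side)
  n_used <- 0L; n_skipped <- 0L
  for (ch in unique(loops$chrom1)) {
    A <- normalize_map(dense_matrix(map, ch),
                       if (norm == "none") "none" else norm)
    n <- nrow(A)
    lp <- loops[loops$chrom1 == ch, ]
    i <- floor((lp$start1 + lp$end1) / 2 / bw) + 1
    j <- floor((lp$start2 + lp$end2) / 2 / bw) + 1
    for (r in seq_len(nrow(lp))) {
      if (i[r] - pad < 1 || j[r] + pad > n || (j[r] - i[r]) <= 2 * pad) {
        n_skipped <- n_skipped + 1L
        next
      }
      acc <- acc + A[(i[r] - pad):(i[r] + pad), (j[r] - pad):(j[r] + pad)]
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0) stop("no usable loops (all skipped)")
  avg <- acc / n_used
  q <- max(1, floor(pad / 2))
  center <- avg[pad + 1, pad + 1]
  ll <- avg[(side - q + 1):side, 1:q]   # lower-left: large i, small j
  corners <- c(avg[1:q, 1:q], avg[1:q, (side - q + 1):side],
               avg[(side - q + 1):side, 1:q],
               avg[(side - q + 1):side, (side - q + 1):side])
  enr <- if (norm == "oe") center / mean(corners) else center / mean(ll)
  structure(list(matrix = avg, enrichment = enr, norm = norm, pad = pad,
                 corner = q, n_used = n_used, n_skipped = n_skipped),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat("APA (", x$norm, "): ", nrow(x$matrix), "x", ncol(x$matrix),
      " window, ", x$n_used, " loops used (", x$n_skipped, " skipped), ",
      "enrichment = ", round(x$enrichment, 3), "\n", sep = "")
  invisible(x)
}

#' Compare the enrichment of two loop sets
#'
#' For each APA result the vector of central-pixel to lower-left-corner
#' pixel ratios is formed; the two vectors are compared with the Wilcoxon
#' rank-sum test. Significance tiers follow the thresholds 1e-2, 1e-5,
#' 1e-8, 1e-11.
#'
#' @param apaA,apaB [apa()] results with equal `pad`.
#' @return list with `statistic`, `p_value`, `stars` (`""` to `"****"`).
#' @export
compare_loop_sets <- function(apaA, apaB) {
  if (apaA$pad != apaB$pad || !all(dim(apaA$matrix) == dim(apaB$matrix)))
    stop("APA results have mismatched shapes")
  ratios <- function(x) {
    side <- nrow(x$matrix); q <- x$corner
    center <- x$matrix[x$pad + 1, x$pad + 1]
    as.numeric(center / x$matrix[(side - q + 1):side, 1:q])
  }
  vA <- ratios(apaA); vB <- ratios(apaB)
  wt <- suppressWarnings(stats::wilcox.test(vA, vB))
  p <- wt$p.value
  stars <- if (p < 1e-11) "****" else if (p < 1e-8) "***"
           else if (p < 1e-5) "**" else if (p < 1e-2) "*" else ""
  list(statistic = unname(wt$statistic), p_value = p, stars = stars)
}

#' Loops of one list absent from another
#'
#' Returns the loops of `listA` having no loop in `listB` whose two anchors
#' both overlap the corresponding anchors (interval overlap with optional
#' slack in bp).
#'
#' @param listA,listB BEDPE-style loop data.frames.
#' @param slack overlap slack in bp (default 0).
#' @return subset of `listA`.
#' @export
loop_set_difference <- function(listA, listB, slack = 0) {
  if (!nrow(listB)) return(listA)
  keep <- vapply(seq_len(nrow(listA)), function(r) {
    same <- listB$chrom1 == listA$chrom1[r]
    if (!any(same)) return(TRUE)
    b <- listB[same, ]
    hit1 <- listA$start1[r] < b$end1 + slack & b$start1 - slack < listA$end1[r]
    hit2 <- listA$start2[r] < b$end2 + slack & b$start2 - slack < listA$end2[r]
    !any(hit1 & hit2)
  }, TRUE)
  listA[keep, ]
}

#' Closest distance from genes to loop anchors
#'
#' @param genes interval data.frame of genes.
#' @param loops BEDPE-style loop data.frame.
#' @return named numeric vector of per-gene minimum genomic distances (bp;
#'   0 when overlapping an anchor, `Inf` with a warning for genes on
#'   chromosomes without loops).
#' @export
gene_loop_distances <- function(genes, loops) {
  anchors <- loop_anchors(loops)
  d <- min_distance_to_set(genes, anchors)
  names(d) <- genes$name
  if (any(is.infinite(d)))
    warning(sum(is.infinite(d)),
            " gene(s) on chromosomes without loops (distance Inf)")
  d
}

#' Smooth a per-cell signal along the trajectory
#'
#' Orders the signal by circular position and applies a centered circular
#' moving average — e.g. loop contact counts over 101 cells, insulation
#' scores of a boundary (400 kb window) over 101 cells, or expression over
#' 31 cells.
#'
#' @param signal named numeric vector (one value per cell).
#' @param traj a [circlet()] fit or named tau vector.
#' @param window odd window width.
#' @return named smoothed vector in trajectory order.
#' @export
smooth_cell_signal <- function(signal, traj, window) {
  tau <- if (inherits(traj, "circlet")) traj$tau else traj
  common <- intersect(names(tau), names(signal))
  if (window > length(common)) stop("window exceeds the number of cells")
  ord <- names(sort(tau[common]))
  setNames(smooth_series(signal[ord], window), ord)
}

#' Per-cell contact count within a loop, chromosome-normalized
#'
#' Counts each cell's contacts whose bin pair falls inside the loop's
#' anchor rectangle and (by default) normalizes by the cell's total contact
#' count on that chromosome.
#'
#' @param cells list of [contact_map()] objects.
#' @param loop single-row BEDPE-style loop.
#' @param normalize divide by the per-cell chromosome total (default
#'   `TRUE`).
#' @return named numeric vector per cell.
#' @export
loop_contact_signal <- function(cells, loop, normalize = TRUE) {
  bw <- cells[[1]]$binning$bin_width
  i1 <- floor(loop$start1 / bw); i2 <- floor((loop$end1 - 1) / bw)
  j1 <- floor(loop$start2 / bw); j2 <- floor((loop$end2 - 1) / bw)
  vapply(cells, function(cl) {
    ct <- cl$contacts[cl$contacts$chrom == loop$chrom1, ]
    v <- sum(ct$count[ct$i >= i1 & ct$i <= i2 & ct$j >= j1 & ct$j <= j2])
    if (normalize) {
      tot <- sum(ct$count)
      if (tot > 0) v / tot else 0
    } else v
  }, 0) -> out
  names(out) <- vapply(cells, `[[`, "", "cell_id")
  out
}
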
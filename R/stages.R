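#' Smoothed adjacent-cell distance vector along a trajectory
#'
#' Orders cells by their circular position, computes the Euclidean distance
#' between each pair of adjacent cells in the top diffusion components
#' (circular adjacency: the last cell neighbors the first), and smooths the
#' distance vector with a centered circular moving average. Peaks of this
#' vector mark phase transitions (density gaps along the circle).
#'
#' @param E a [diffusion_embed()] result or a cells x dims matrix.
#' @param tau named numeric vector of circular positions.
#' @param n_components number of leading components used (default 3).
#' @param window smoothing window (odd; default 11).
#' @return named numeric vector: for each cell in trajectory order, the
#'   smoothed distance to its successor.
#' @export
adjacent_distance <- function(E, tau, n_components = 3, window = 11) {
  X <- if (inherits(E, "diffusion_embedding")) E$components else as.matrix(E)
  X <- X[, seq_len(min(n_components, ncol(X))), drop = FALSE]
  if (nrow(X) < 12) stop("need at least 12 cells")
  ord <- names(sort(tau))
  Xo <- X[ord, , drop = FALSE]
  nxt <- c(2:nrow(Xo), 1)
  d <- sqrt(rowSums((Xo - Xo[nxt, , drop = FALSE])^2))
  setNames(smooth_series(d, window), ord)
}

# prominence of circular local maxima: height above the larger of the two
# valley minima encountered before a higher value is reached on each side
circular_peaks <- function(v) {
  n <- length(v)
  at <- function(i) v[((i - 1) %% n) + 1]
  is_peak <- vapply(seq_len(n), function(i)
    at(i) > at(i - 1) && at(i) >= at(i + 1), TRUE)
  peaks <- which(is_peak)
  prom <- vapply(peaks, function(p) {
    lo_l <- lo_r <- at(p)
    i <- p
    repeat {
      i <- i - 1
      if (at(i) > at(p) || i == p - n) break
      lo_l <- min(lo_l, at(i))
    }
    i <- p
    repeat {
      i <- i + 1
      if (at(i) > at(p) || i == p + n) break
      lo_r <- min(lo_r, at(i))
    }
    at(p) - max(lo_l, lo_r)
  }, 0)
  data.frame(index = peaks, height = v[peaks], prominence = prom)
}

#' Locate stage-transition cuts from the adjacent-distance vector
#'
#' @param dist_vec smoothed circular distance vector ([adjacent_distance()]).
#' @param n_peaks number of cuts to return (local maxima ranked by
#'   prominence).
#' @return integer indices (positions in trajectory order) of the cut
#'   adjacencies, sorted; errors when fewer peaks exist.
#' @export
find_stage_cuts <- function(dist_vec, n_peaks) {
  pk <- circular_peaks(dist_vec)
  if (nrow(pk) < n_peaks)
    stop("only ", nrow(pk), " peak(s) found, ", n_peaks,
         " requested; supply split_spec cuts")
  sort(pk$index[order(-pk$prominence)][seq_len(n_peaks)])
}

#' Divide a circular trajectory into contiguous substages
#'
#' Cuts the circle at the most prominent peaks of the smoothed
#' adjacent-cell distance vector, plus any explicit `split_spec` cut
#' positions (tau values). The wrap point `tau = 0` counts as one implicit
#' cut, so `n_stages` arcs need `n_stages - 1` further cuts. With the
#' default 12 stages the canonical cell-cycle substage names are assigned
#' (Post-M, G1-1, G1-2, G1-ES, ES, ES-MS, MS-1, MS-2, MS-LS, LS-G2, G2,
#' Pre-M), anchored by majority FACS label when `labels` are given, else by
#' the arc whose pooled map is richest in mitotic-band contacts (assigned
#' Pre-M), else starting at `tau = 0`.
#'
#' @param E embedding (see [adjacent_distance()]).
#' @param fit a [circlet()] fit (or named tau vector).
#' @param n_stages number of arcs (default 12).
#' @param split_spec numeric tau cut positions supplied manually (default
#'   none; when it provides all `n_stages - 1` cuts no peaks are used).
#' @param labels optional named FACS label vector for anchoring.
#' @param cells optional list of [contact_map()] for the mitotic anchor.
#' @param window smoothing window (default 11).
#' @return object of class `stage_partition`: list with `stage` (named
#'   factor per cell in canonical order), `cuts` (tau positions),
#'   `stage_names`, and `merge5` (map of the 12 substages onto the 5 merged
#'   stages G1, ES, MS, MS-G2, G2; transition arcs unassigned).
#' @export
divide_stages <- function(E, fit, n_stages = 12, split_spec = NULL,
                          labels = NULL, cells = NULL, window = 11) {
  tau <- if (inherits(fit, "circlet")) fit$tau else fit
  ord <- names(sort(tau))
  n <- length(tau)
  need <- n_stages - 1 - length(split_spec)
  if (need < 0) stop("more split_spec cuts than n_stages - 1")
  cut_tau <- as.numeric(split_spec)
  if (need > 0) {
    dv <- adjacent_distance(E, tau, window = window)
    idx <- find_stage_cuts(dv, need)
    # cut between cell idx and its successor: midpoint tau
    t_ord <- sort(tau)
    cut_tau <- c(cut_tau,
                 vapply(idx, function(i)
                   if (i < n) (t_ord[i] + t_ord[i + 1]) / 2
                   else ((t_ord[n] + 1 + t_ord[1]) / 2) %% 1, 0))
  }
  cut_tau <- sort(unique(cut_tau %% 1))
  arc <- findInterval(tau, c(0, cut_tau, 1), rightmost.closed = TRUE)
  arc[arc > n_stages] <- n_stages
  n_arcs <- length(cut_tau) + 1
  if (n_arcs != n_stages)
    stop("got ", n_arcs, " arcs but n_stages = ", n_stages)

  if (n_stages == 12) {
    nm <- stage_names_12
    rot <- 0
    if (!is.null(labels)) {
      expected <- list("Post-M" = "G1", "G1-1" = "G1", "G1-2" = "G1",
                       "G1-ES" = c("G1", "ES"), "ES" = "ES",
                       "ES-MS" = c("ES", "MS"), "MS-1" = "MS", "MS-2" = "MS",
                       "MS-LS" = c("MS", "LS/G2"), "LS-G2" = "LS/G2",
                       "G2" = "LS/G2", "Pre-M" = "LS/G2")
      lab <- labels[names(tau)]
      score <- vapply(0:11, function(r) {
        nms <- nm[((seq_len(12) - 1 + r) %% 12) + 1]
        sum(mapply(function(a, l) !is.na(l) && l %in% expected[[nms[a]]],
                   arc, lab))
      }, 0)
      rot <- which.max(score) - 1
    } else if (!is.null(cells)) {
      ids_by_arc <- split(names(tau), arc)
      mit <- vapply(seq_len(12), function(a) {
        pool <- pool_cells(cells[match(ids_by_arc[[as.character(a)]],
                                       vapply(cells, `[[`, "", "cell_id"))])
        dc <- contact_distances(pool)
        sum(dc$count[dc$distance >= 2e6 & dc$distance <= 12e6]) /
          sum(dc$count)
      }, 0)
      # the most mitotic arc is Pre-M; Post-M starts right after it
      rot <- (which(nm == "Pre-M") - which.max(mit)) %% 12
    }
    nm_arcs <- nm[((seq_len(12) - 1 + rot) %% 12) + 1]
  } else {
    nm_arcs <- paste0("S", seq_len(n_stages))
  }
  stage <- factor(nm_arcs[arc],
                  levels = if (n_stages == 12) stage_names_12 else nm_arcs)
  names(stage) <- names(tau)
  merge5 <- c("G1-1" = "G1", "G1-2" = "G1", "ES" = "ES", "MS-1" = "MS",
              "MS-2" = "MS", "MS-LS" = "MS-G2", "LS-G2" = "MS-G2",
              "G2" = "G2")
  structure(list(stage = stage, cuts = cut_tau, stage_names = levels(stage),
                 merge5 = if (n_stages == 12) merge5 else NULL,
                 order = ord),
            class = "stage_partition")
}

#' @export
print.stage_partition <- function(x, ...) {
  cat("stage_partition:", length(x$stage_names), "stages\n")
  print(table(x$stage))
  invisible(x)
}

#' Merge a 12-substage partition to the 5 larger stages
#'
#' G1 = G1-1 + G1-2; ES = ES; MS = MS-1 + MS-2; MS-G2 = MS-LS + LS-G2;
#' G2 = G2. Cells in transition arcs (Post-M, G1-ES, ES-MS, Pre-M) are
#' unassigned (`NA`).
#'
#' @param partition a 12-stage [divide_stages()] result.
#' @return named factor of merged stage per cell.
#' @export
merge_stages <- function(partition) {
  stopifnot(inherits(partition, "stage_partition"),
            !is.null(partition$merge5))
  m <- partition$merge5[as.character(partition$stage)]
  factor(setNames(m, names(partition$stage)),
         levels = c("G1", "ES", "MS", "MS-G2", "G2"))
}

#' Pool per-stage Hi-C maps and contact-probability curves
#'
#' @param cells list of [contact_map()] objects.
#' @param partition a [divide_stages()] result (or named stage factor).
#' @param cdd_step exponent step for the per-stage log-distance
#'   contact-probability curve (default 0.33).
#' @param min_distance distance floor for the curves (default 20 kb).
#' @return list per stage: `map` (pooled [contact_map()]) and `curve`
#'   (named probability vector over log2-distance bins, summing to 1).
#'   Empty stages are flagged with `NULL` entries.
#' @export
pool_stage_maps <- function(cells, partition, cdd_step = 0.33,
                            min_distance = 20e3) {
  stage <- if (inherits(partition, "stage_partition")) partition$stage
           else partition
  ids <- vapply(cells, `[[`, "", "cell_id")
  out <- list()
  for (st in levels(stage)) {
    members <- names(stage)[!is.na(stage) & stage == st]
    if (!length(members)) {
      warning("stage '", st, "' is empty; omitted")
      out[[st]] <- NULL
      next
    }
    pool <- pool_cells(cells[match(members, ids)], cell_id = st)
    curve <- tryCatch(cdd_features(pool, steps = cdd_step,
                                   min_distance = min_distance),
                      error = function(e) NULL)
    out[[st]] <- list(map = pool, curve = curve)
  }
  out
}
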
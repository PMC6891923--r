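#' Cell-cycle phase labels
#'
#' FACS phase labels used only for evaluating a reconstructed trajectory,
#' never by the ordering itself. The cyclic phase order is fixed as
#' G1 -> ES -> MS -> LS/G2 -> G1.
#'
#' @name phase_labels
#' @format named character vector `cell_id -> phase`; cells may be missing
#'   or labeled `"unlabeled"`.
NULL

phase_order <- c("G1", "ES", "MS", "LS/G2")

successive_pairs <- function() list(c("G1", "ES"), c("ES", "MS"),
                                    c("MS", "LS/G2"), c("LS/G2", "G1"))

#' Read a cell-label TSV (cell_id, phase)
#'
#' @param path two-column TSV; phases in `G1, ES, MS, LS/G2, unlabeled`.
#' @return named character vector of labels.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

labeled_subset <- function(tau, labels) {
  lab <- labels[names(tau)]
  keep <- !is.na(lab) & lab %in% phase_order
  list(tau = tau[keep], labels = lab[keep])
}

#' Label change score (LCS) of a circular ordering
#'
#' Counts label changes between adjacent experimentally labeled cells along
#' the circular trajectory (including the wrap-around adjacency; unlabeled
#' cells are skipped) and scores
#' `LCS = 1 - (s_c - 4) / (N - 4)`, clamped to `[0, 1]`. Four contiguous
#' label arcs give the perfect score 1 (only the four unavoidable junction
#' changes); fully alternating labels give 0.
#'
#' @param ordering either a named numeric vector of circular positions
#'   (cells ordered by value) or a character vector of cell ids in circular
#'   order.
#' @param labels named label vector (see [read_labels()]).
#' @return LCS in `[0, 1]`.
#' @export
lcs <- function(ordering, labels) {
  if (is.numeric(ordering)) {
    sub <- labeled_subset(ordering, labels)
    lab <- sub$labels[order(sub$tau)]
  } else {
    lab <- labels[ordering]
    lab <- lab[!is.na(lab) & lab %in% phase_order]
  }
  N <- length(lab)
  if (N <= 4) stop("LCS needs more than 4 labeled cells")
  s_c <- sum(lab != c(lab[-1], lab[1]))
  min(1, max(0, 1 - (s_c - 4) / (N - 4)))
}

#' AUC between two successive cell-cycle phases
#'
#' The first phase of the pair is the positive class and the next phase the
#' negative one. Because the trajectory is circular, positions are first
#' rotated so the pair's labeled cells span a contiguous arc (the cut is
#' placed in the largest gap between the pair's cells); the AUC is then the
#' rank statistic `P(tau_pos < tau_neg) + 0.5 P(tie)` over all cross-phase
#' cell pairs (earlier positives score higher).
#'
#' @param tau named numeric vector of circular positions in `[0, 1]`.
#' @param labels named label vector.
#' @param pair character pair `c(positive_phase, negative_phase)`.
#' @param symmetric report `max(AUC, 1 - AUC)` (direction-free); default
#'   `FALSE` (literal orientation).
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when a phase is empty.
#' @export
auc_successive <- function(tau, labels, pair, symmetric = FALSE) {
  sub <- labeled_subset(tau, labels)
  pos <- sub$tau[sub$labels == pair[1]]
  neg <- sub$tau[sub$labels == pair[2]]
  if (!length(pos) || !length(neg)) {
    warning("phase '", pair[which(!c(length(pos), length(neg)))[1]],
            "' has no labeled cells; AUC undefined")
    return(NA_real_)
  }
  both <- sort(c(pos, neg) %% 1)
  gaps <- diff(c(both, both[1] + 1))
  cut <- (both[which.max(gaps)] + max(gaps) / 2) %% 1
  p <- (pos - cut) %% 1
  q <- (neg - cut) %% 1
  cmp <- outer(p, q, `<`)
  ties <- outer(p, q, `==`)
  auc <- (sum(cmp) + 0.5 * sum(ties)) / (length(p) * length(q))
  if (symmetric) max(auc, 1 - auc) else auc
}

#' Score a reconstructed trajectory against FACS phase labels
#'
#' Computes the five evaluation indexes: the LCS and the AUC between each of
#' the four successive phase pairs (G1-ES, ES-MS, MS-LS/G2, LS/G2-G1). The
#' direction of a circular trajectory is arbitrary, so the orientation
#' (`tau` vs `1 - tau`) maximizing the summed AUC is scored. With a
#' `baseline` report, per-score ratios and the summed increase ratio are
#' added.
#'
#' @param traj a [circlet()] fit or a named numeric `tau` vector.
#' @param labels named label vector.
#' @param baseline optional `circlet_scores` object to compare against.
#' @param symmetric passed to [auc_successive()].
#' @return object of class `circlet_scores`: list with `lcs`, `auc` (named
#'   vector over the four pairs), `scores` (all five), and when a baseline
#'   is given, `ratio` and `summed_increase`.
#' @export
evaluate_trajectory <- function(traj, labels, baseline = NULL,
                                symmetric = FALSE) {
  tau <- if (inherits(traj, "circlet")) traj$tau else traj
  pairs <- successive_pairs()
  auc_for <- function(tv) vapply(pairs, function(p)
    auc_successive(tv, labels, p, symmetric = symmetric), 0)
  a_fwd <- suppressWarnings(auc_for(tau))
  a_rev <- suppressWarnings(auc_for(1 - tau))
  auc <- if (sum(a_rev, na.rm = TRUE) > sum(a_fwd, na.rm = TRUE)) a_rev else a_fwd
  names(auc) <- vapply(pairs, function(p) paste(p, collapse = "-"), "")
  res <- list(lcs = lcs(tau, labels), auc = auc)
  res$scores <- c(LCS = res$lcs, auc)
  if (!is.null(baseline)) {
    res$ratio <- res$scores / baseline$scores
    res$summed_increase <-
      (sum(res$scores, na.rm = TRUE) - sum(baseline$scores, na.rm = TRUE)) /
      sum(baseline$scores, na.rm = TRUE)
  }
  structure(res, class = "circlet_scores")
}

#' @export
print.circlet_scores <- function(x, ...) {
  cat("Trajectory evaluation\n")
  print(round(x$scores, 4))
  if (!is.null(x$ratio)) {
    cat("ratios vs baseline:\n")
    print(round(x$ratio, 4))
    cat("summed increase:", round(x$summed_increase, 4), "\n")
  }
  invisible(x)
}

#' Robustness of reconstruction to cell deletion or fill-in
#'
#' Repeatedly perturbs the cell set (random deletion of a fraction of cells,
#' or duplication of cells with bootstrap-resampled contacts), re-runs
#' feature extraction and trajectory reconstruction, and reports the
#' circular rank correlation between the recovered ordering and the true
#' angular positions of the surviving original cells.
#'
#' @param cells list of [contact_map()] objects.
#' @param theta named numeric vector of true angular positions (radians or
#'   any circular scale) for the cells.
#' @param mode `"delete"` or `"fill"`.
#' @param fraction fraction of cells to delete / duplicate (`0 <= f < 1`).
#' @param repeats number of perturbed reconstructions (default 20).
#' @param seed integer seed; repeat `r` uses `seed + r`.
#' @param feature_args,circlet_args extra arguments for [extract_features()]
#'   and [circlet()].
#' @return data.frame with one row per repeat: `repeat_id`, `n_cells`,
#'   `circ_cor`, `converged`.
#' @export
robustness_suite <- function(cells, theta, mode = c("delete", "fill"),
                             fraction, repeats = 20, seed = 1,
                             feature_args = list(), circlet_args = list()) {
  mode <- match.arg(mode)
  if (fraction >= 1 || fraction < 0) stop("fraction must be in [0, 1)")
  ids <- vapply(cells, `[[`, "", "cell_id")
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    pert <- perturb_cells(cells, mode = mode, fraction = fraction,
                          seed = seed + r)
    Fm <- suppressMessages(
      do.call(extract_features, c(list(pert$cells), feature_args)))
    fit <- do.call(circlet, c(list(Fm), circlet_args,
                              list(seed = seed + r)))
    # score on surviving original cells only (duplicates share truth theta)
    orig <- intersect(fit$cell_ids, ids)
    cc <- circular_rank_cor(fit$tau[orig], theta[orig])
    out[[r]] <- data.frame(repeat_id = r, n_cells = length(fit$cell_ids),
                           circ_cor = cc, converged = fit$converged)
  }
  do.call(rbind, out)
}
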
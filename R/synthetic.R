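#' Specification for a synthetic single-cell Hi-C dataset
#'
#' Cells sit at angular positions `theta` on a circle emulating cell-cycle
#' progression. Each cell's contacts are drawn from a mixture of three
#' genomic-distance bands whose weights vary smoothly and cyclically with
#' `theta`: short-range contacts (200 kb - 2 Mb) peak in S/G2, the mitotic
#' band (2 - 12 Mb) peaks at the M-phase point `theta = 0`, and long-range
#' contacts (> 5 Mb) peak in G1 — so the weight curve traces an injective
#' closed loop and the angular position is identifiable from the contact
#' distance structure. Planted TAD boundaries deplete spanning contacts and
#' planted loop anchors receive focal contacts, both with cyclic intensity.
#' Four contiguous phase-label arcs partition the circle.
#'
#' @param n_cells number of cells (default 400).
#' @param contacts_mean,contacts_dispersion negative-binomial contact count
#'   per cell (default mean 5000, size 20).
#' @param chrom_sizes named chromosome lengths (default 2 x 50 Mb).
#' @param bin_width bin width for the emitted contact maps (default 500 kb).
#' @param phase_fractions fractions of the circle occupied by the G1, ES,
#'   MS, LS/G2 label arcs (default `c(0.24, 0.26, 0.22, 0.28)`, realistic
#'   FACS label proportions for a cycling mESC population).
#' @param bands list of `c(lo, hi)` bp ranges for the short, mitotic and
#'   long distance bands.
#' @param boundary_spacing spacing of planted TAD boundaries in bp
#'   (default 5 Mb).
#' @param loop_fraction_max peak fraction of a cell's contacts placed on
#'   planted loop anchors (default 0.05).
#' @param insulation_max peak probability that a boundary-spanning
#'   short-range contact is depleted (default 0.6).
#' @param seed integer seed.
#' @return object of class `sim_spec` (a list of the above).
#' @export
sim_spec <- function(n_cells = 400, contacts_mean = 5000,
                     contacts_dispersion = 20,
                     chrom_sizes = c(chrA = 50e6, chrB = 50e6),
                     bin_width = 500e3,
                     phase_fractions = c(G1 = 0.24, ES = 0.26,
                                         MS = 0.22, "LS/G2" = 0.28),
                     bands = list(short = c(200e3, 2e6),
                                  mitotic = c(2e6, 12e6),
                                  long = c(5e6, 25e6)),
                     boundary_spacing = 5e6,
                     loop_fraction_max = 0.05,
                     insulation_max = 0.6,
                     seed = 1) {
  stopifnot(abs(sum(phase_fractions) - 1) < 1e-8, n_cells >= 8)
  structure(as.list(environment()), class = "sim_spec")
}

# raised-cosine bump centered at `center`, in [0, 1]
cyclic_bump <- function(theta, center) (1 + cos(theta - center)) / 2

# band mixture weights at angle theta: rows = cells, cols = bands
band_weights <- function(theta) {
  w <- cbind(short = 0.25 + 0.50 * cyclic_bump(theta, 1.2 * pi),
             mitotic = 0.05 + 0.60 * cyclic_bump(theta, 0),
             long = 0.15 + 0.50 * cyclic_bump(theta, 0.5 * pi))
  w / rowSums(w)
}

loop_intensity <- function(theta, max_frac) max_frac * cyclic_bump(theta, 0.5 * pi)
insulation_strength <- function(theta, max_p) max_p * cyclic_bump(theta, 0.55 * pi)

stage_names_12 <- c("Post-M", "G1-1", "G1-2", "G1-ES", "ES", "ES-MS",
                    "MS-1", "MS-2", "MS-LS", "LS-G2", "G2", "Pre-M")

#' Generate a synthetic single-cell Hi-C dataset with circular ground truth
#'
#' @param spec a [sim_spec()].
#' @param keep_pairs also return the raw contact positions per cell (for
#'   re-binning at other resolutions); default `FALSE`.
#' @return list with `cells` (list of [contact_map()]), `truth` (data.frame
#'   `cell_id`, `theta`, `phase`, `stage`), `boundaries` (interval
#'   data.frame of planted boundaries), `loops` (BEDPE-style data.frame of
#'   planted loops), `binning`, `spec`, and optionally `pairs`.
#' @export
simulate_schic <- function(spec, keep_pairs = FALSE) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    theta <- sort(stats::runif(n, 0, 2 * pi))
    ids <- sprintf("cell%04d", seq_len(n))
    # contiguous phase arcs starting at theta = 0
    cuts <- 2 * pi * cumsum(c(0, spec$phase_fractions))
    phase <- names(spec$phase_fractions)[findInterval(theta, cuts,
                                                      rightmost.closed = TRUE)]
    stage <- stage_names_12[pmin(12L, 1L + floor(theta / (2 * pi) * 12))]

    sizes <- spec$chrom_sizes
    chroms <- names(sizes)
    binning <- genome_binning(sizes, spec$bin_width)
    # planted boundaries and loops, identical across cells
    bnd <- do.call(rbind, lapply(chroms, function(ch) {
      pos <- seq(spec$boundary_spacing, sizes[[ch]] - spec$boundary_spacing / 2,
                 by = spec$boundary_spacing)
      genomic_intervals(ch, pos - 20e3, pos + 20e3,
                        name = sprintf("bnd_%s_%d", ch, seq_along(pos)))
    }))
    loops <- do.call(rbind, lapply(chroms, function(ch) {
      a1 <- seq(8e6, sizes[[ch]] - 10e6, by = 4e6)
      data.frame(chrom1 = ch, start1 = a1, end1 = a1 + 50e3,
                 chrom2 = ch, start2 = a1 + 1e6, end2 = a1 + 1e6 + 50e3,
                 name = sprintf("loop_%s_%d", ch, seq_along(a1)), score = 1,
                 stringsAsFactors = FALSE)
    }))
    bnd_mid <- (bnd$start + bnd$end) / 2

    band_lims <- spec$bands
    wts <- band_weights(theta)
    loop_frac <- loop_intensity(theta, spec$loop_fraction_max)
    ins_p <- insulation_strength(theta, spec$insulation_max)

    cells <- vector("list", n)
    raw <- if (keep_pairs) vector("list", n) else NULL
    for (c_i in seq_len(n)) {
      n_c <- max(200L, stats::rnbinom(1, mu = spec$contacts_mean,
                                      size = spec$contacts_dispersion))
      n_loop <- stats::rbinom(1, n_c, loop_frac[c_i])
      n_band <- n_c - n_loop
      nb <- stats::rmultinom(1, n_band, wts[c_i, ])[, 1]
      d <- unlist(lapply(seq_along(nb), function(b) {
        lim <- band_lims[[b]]
        2^stats::runif(nb[b], log2(lim[1]), log2(lim[2]))
      }))
      ch <- sample(chroms, length(d), replace = TRUE,
                   prob = sizes / sum(sizes))
      pos1 <- stats::runif(length(d), 0, sizes[ch] - d)
      pos2 <- pos1 + d
      # insulation: deplete short-range contacts spanning a planted boundary
      span <- rep(FALSE, length(d))
      shortish <- d < 3e6
      if (any(shortish)) {
        for (cc in chroms) {
          m <- bnd_mid[bnd$chrom == cc]
          sel <- shortish & ch == cc
          span[sel] <- findInterval(pos2[sel], m) > findInterval(pos1[sel], m)
        }
      }
      drop <- span & stats::runif(length(d)) < ins_p[c_i]
      ch <- ch[!drop]; pos1 <- pos1[!drop]; pos2 <- pos2[!drop]
      if (n_loop > 0) {
        li <- sample(nrow(loops), n_loop, replace = TRUE)
        lp1 <- stats::runif(n_loop, loops$start1[li], loops$end1[li])
        lp2 <- stats::runif(n_loop, loops$start2[li], loops$end2[li])
        ch <- c(ch, loops$chrom1[li]); pos1 <- c(pos1, lp1); pos2 <- c(pos2, lp2)
      }
      if (keep_pairs)
        raw[[c_i]] <- data.frame(chrom = ch, pos1 = pos1, pos2 = pos2)
      cells[[c_i]] <- contact_map(
        data.frame(chrom = ch,
                   i = floor(pos1 / spec$bin_width),
                   j = floor(pos2 / spec$bin_width),
                   count = 1),
        binning, cell_id = ids[c_i])
    }
    truth <- data.frame(cell_id = ids, theta = theta, phase = phase,
                        stage = stage, stringsAsFactors = FALSE)
    out <- list(cells = cells, truth = truth, boundaries = bnd,
                loops = loops, binning = binning, spec = spec)
    if (keep_pairs) out$pairs <- raw
    out
  })
}

#' Perturb a cell list by deletion or fill-in
#'
#' `delete` removes a random fraction of cells; `fill` duplicates a random
#' fraction of cells, resampling each duplicate's contact counts
#' (multinomial bootstrap over its bin pairs) so the duplicate is a noisy
#' replicate at the same circular position.
#'
#' @param cells list of [contact_map()] objects.
#' @param mode `"delete"` or `"fill"`.
#' @param fraction fraction of cells to delete / duplicate (`0 <= f < 1`).
#' @param seed integer seed.
#' @return list with `cells` (perturbed list) and `source_ids` (for each
#'   output cell, the originating cell id).
#' @export
perturb_cells <- function(cells, mode = c("delete", "fill"), fraction,
                          seed = 1) {
  mode <- match.arg(mode)
  if (fraction >= 1 || fraction < 0) stop("fraction must be in [0, 1)")
  ids <- vapply(cells, `[[`, "", "cell_id")
  n <- length(cells)
  m <- round(fraction * n)
  with_seed(seed, {
    if (m == 0) return(list(cells = cells, source_ids = ids))
    if (mode == "delete") {
      keep <- sort(sample(n, n - m))
      list(cells = cells[keep], source_ids = ids[keep])
    } else {
      dup <- sample(n, m, replace = TRUE)
      extra <- lapply(seq_along(dup), function(k) {
        src <- cells[[dup[k]]]
        ct <- src$contacts
        new_counts <- stats::rmultinom(1, src$total_contacts,
                                       ct$count / src$total_contacts)[, 1]
        ct$count <- new_counts
        ct <- ct[ct$count > 0, ]
        contact_map(ct, src$binning,
                    cell_id = paste0(src$cell_id, "_dup", k))
      })
      list(cells = c(cells, extra), source_ids = c(ids, ids[dup]))
    }
  })
}
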
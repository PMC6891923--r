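make_profiles <- function() {
  # two stages, one chromosome, 12 bins; boundary-like maxima planted
  list(s1 = list(chr1 = c(NA, NA, 1, 1, 5, 1, 1, 1, 3, 1, NA, NA)),
       s2 = list(chr1 = c(NA, NA, 1, 1, 5, 1, 1, 4, 1, 1, NA, NA)))
}

test_that("boundary calling applies one global quantile across stages", {
  gb <- genome_binning(c(chr1 = 1.2e6), 1e5)
  pr <- make_profiles()
  b0 <- call_boundaries(pr, gb, quantile = 0)
  # all local maxima kept at quantile 0
  expect_setequal(b0$start[b0$stage == "s1"], c(4e5, 8e5))
  expect_setequal(b0$start[b0$stage == "s2"], c(4e5, 7e5))

  # brute-force oracle for the global threshold
  all_vals <- unlist(pr)
  thr <- quantile(all_vals[is.finite(all_vals)], 0.8)
  b <- call_boundaries(pr, gb, quantile = 0.8)
  expect_true(all(b$score > thr))
  # the s1 score-3 maximum is below the joint quantile -> excluded,
  # even though within s1 alone it is a strong candidate
  expect_false(any(b$stage == "s1" & b$start == 8e5))
  expect_setequal(b$start[b$stage == "s2" & b$score == 4], 7e5)
})

test_that("boundary merging respects the size cap and classifies common/specific", {
  bw <- 4e4
  mk <- function(start, stage, score = 2)
    data.frame(chrom = "chr1", start = start, end = start + bw,
               name = "x", score = score, stage = stage,
               stringsAsFactors = FALSE)
  # same bin in all 5 stages -> common; isolated single-stage bin -> specific
  b <- rbind(mk(0, "a"), mk(0, "b"), mk(0, "c"), mk(0, "d"), mk(0, "e", 7),
             mk(10 * bw, "c"))
  m <- merge_and_classify(b, n_stages = 5, bin_width = bw)
  expect_equal(m$class[m$start == 0], "common")
  expect_equal(m$score[m$start == 0], 7)  # max over members
  expect_equal(m$class[m$start == 10 * bw], "specific:c")

  # adjacency chain: bins 0..7 one bin apart would merge unbounded;
  # the 5-bin cap splits the chain (hand oracle: extent < 5 * bw)
  chain <- do.call(rbind, lapply(0:7, function(k) mk(k * bw, "a")))
  mc <- merge_and_classify(chain, n_stages = 5, bin_width = bw)
  expect_true(all(mc$end - mc$start < 5 * bw))
  expect_equal(sum(mc$end - mc$start), 8 * bw)  # nothing lost

  # idempotence: re-merging a merged set changes nothing
  m2 <- merge_and_classify(mc, n_stages = 5, bin_width = bw)
  expect_equal(m2[, c("chrom", "start", "end", "score", "class")],
               mc[, c("chrom", "start", "end", "score", "class")])
})

test_that("feature enrichment matches the exhaustive placement expectation", {
  sizes <- c(chrA = 1e4, chrB = 8e3)
  feats <- rbind(
    genomic_intervals("chrA", c(0, 4000, 7000), c(1000, 5000, 8000),
                      name = "e"),
    genomic_intervals("chrB", c(2000, 6000), c(3000, 7000), name = "p"))
  feats$class <- c("exon", "exon", "exon", "promoter", "promoter")
  regions <- genomic_intervals(c("chrA", "chrA", "chrB"),
                               c(500, 6500, 2500), c(700, 6700, 2700))

  # saturating features -> fold ~ 1
  tile <- genomic_intervals(c("chrA", "chrB"), c(0, 0), sizes)
  tile$class <- "all"
  fe1 <- feature_enrichment(regions, tile, sizes, n_draws = 50, seed = 1)
  expect_equal(fe1$fold, 1)

  # disjoint features -> fold 0
  far <- genomic_intervals("chrA", 9000, 9500)
  far$class <- "x"
  fe0 <- feature_enrichment(regions[1:2, ], far, sizes, n_draws = 50, seed = 1)
  expect_equal(fe0$observed, 0)
  expect_equal(fe0$fold, 0)

  # Monte-Carlo fold within 3 SE of the exhaustive placement expectation
  fe <- feature_enrichment(regions, feats, sizes, n_draws = 1000, seed = 7)
  exhaustive_expect <- function(cl) {
    f <- feats[feats$class == cl, ]
    per_draw <- function() NULL
    # expectation of the per-draw count: sum over features of
    # P(feature overlaps any randomized region); randomized regions are
    # independent uniform placements, so compute by integration over starts
    tot <- 0
    for (fi in seq_len(nrow(f))) {
      p_miss <- 1
      for (ri in seq_len(nrow(regions))) {
        if (regions$chrom[ri] != f$chrom[fi]) next
        w <- regions$end[ri] - regions$start[ri]
        L <- sizes[[regions$chrom[ri]]] - w   # start in [0, L]
        lo <- max(0, f$start[fi] - w)
        hi <- min(L, f$end[fi])
        p_hit <- max(0, hi - lo) / L
        p_miss <- p_miss * (1 - p_hit)
      }
      tot <- tot + (1 - p_miss)
    }
    tot
  }
  for (cl in unique(feats$class)) {
    ev <- exhaustive_expect(cl)
    se <- sqrt(ev) / sqrt(1000) + 1e-9
    got <- fe$expected[fe$class == cl]
    expect_lt(abs(got - ev), 3 * max(se, 0.05))
  }
  expect_warning(
    feature_enrichment(genomic_intervals("chrB", 0, 100, name = "g"),
                       feats[feats$chrom == "chrA", ], sizes,
                       n_draws = 5, seed = 1),
    "excluded")
})

test_that("APA is flat on uniform maps and recovers planted spikes", {
  gb <- genome_binning(c(chr1 = 5e6), 25e3)   # 200 bins of 25 kb
  n <- gb$n_bins[["chr1"]]
  ones <- do.call(rbind, lapply(0:(n - 1), function(i)
    data.frame(chrom = "chr1", i = i, j = i:(n - 1), count = 1)))
  u <- contact_map(ones, gb, "u")
  loops <- data.frame(chrom1 = "chr1", start1 = 50 * 25e3, end1 = 51 * 25e3,
                      chrom2 = "chr1", start2 = 120 * 25e3, end2 = 121 * 25e3,
                      name = "L", score = 1)
  # 325 kb window at 25 kb bins: 13 x 13
  r_none <- apa(loops, u, pad = 6, norm = "none")
  expect_equal(dim(r_none$matrix), c(13, 13))
  expect_equal(r_none$enrichment, 1)
  r_oe <- apa(loops, u, pad = 6, norm = "oe")
  expect_equal(r_oe$enrichment, 1)
  r_kr <- apa(loops, u, pad = 6, norm = "kr")
  expect_equal(r_kr$enrichment, 1, tolerance = 1e-4)

  # spiked center 10x over background 1 -> o/e-corner ratio 10
  spiked <- ones
  spiked$count[spiked$i == 50 & spiked$j == 120] <- 10
  sp <- contact_map(spiked, gb, "sp")
  r_sp <- apa(loops, sp, pad = 6, norm = "none")
  expect_equal(r_sp$enrichment, 10)

  # o/e enrichment is invariant to uniform scaling of the map
  scaled <- ones; scaled$count <- scaled$count * 13
  r_sc <- apa(loops, contact_map(scaled, gb, "s"), pad = 6, norm = "oe")
  expect_equal(r_sc$enrichment, r_oe$enrichment)

  # loops too close to the diagonal are skipped
  near <- data.frame(chrom1 = "chr1", start1 = 50 * 25e3, end1 = 51 * 25e3,
                     chrom2 = "chr1", start2 = 55 * 25e3, end2 = 56 * 25e3,
                     name = "N", score = 1)
  expect_error(apa(near, u, pad = 6), "no usable loops")
})

test_that("loop-set comparison is null for identical or rescaled inputs", {
  gb <- genome_binning(c(chr1 = 5e6), 25e3)
  n <- gb$n_bins[["chr1"]]
  set.seed(51)
  df <- do.call(rbind, lapply(0:(n - 1), function(i)
    data.frame(chrom = "chr1", i = i, j = i:(n - 1),
               count = sample(1:5, n - i, replace = TRUE))))
  m <- contact_map(df, gb, "m")
  loops <- data.frame(chrom1 = "chr1",
                      start1 = c(40, 80) * 25e3, end1 = c(41, 81) * 25e3,
                      chrom2 = "chr1",
                      start2 = c(110, 150) * 25e3, end2 = c(111, 151) * 25e3,
                      name = c("a", "b"), score = 1)
  rA <- apa(loops, m, pad = 6, norm = "oe")
  cmp <- compare_loop_sets(rA, rA)
  expect_gt(cmp$p_value, 0.9)
  expect_equal(cmp$stars, "")

  df2 <- df; df2$count <- df2$count * 2
  rB <- apa(loops, contact_map(df2, gb, "m2"), pad = 6, norm = "oe")
  cmp2 <- compare_loop_sets(rA, rB)
  expect_gt(cmp2$p_value, 0.9)
  expect_error(compare_loop_sets(rA, apa(loops, m, pad = 4, norm = "oe")),
               "mismatch")
})

test_that("loop set difference follows anchor-wise overlap", {
  A <- data.frame(chrom1 = "chr1", start1 = c(1e4, 5e4, 9e4),
                  end1 = c(2e4, 6e4, 1e5),
                  chrom2 = "chr1", start2 = c(2e5, 25e4, 3e5),
                  end2 = c(2.1e5, 2.6e5, 3.1e5),
                  name = c("a", "b", "c"), score = 1,
                  stringsAsFactors = FALSE)
  expect_equal(nrow(loop_set_difference(A, A)), 0)
  B_far <- A; B_far$start1 <- B_far$start1 + 1e6; B_far$end1 <- B_far$end1 + 1e6
  B_far$start2 <- B_far$start2 + 1e6; B_far$end2 <- B_far$end2 + 1e6
  expect_equal(loop_set_difference(A, B_far), A)

  # partial overlap: B matches anchor1 of "a" but not anchor2 -> "a" kept;
  # B matches both anchors of "b" -> "b" removed
  B <- data.frame(chrom1 = "chr1", start1 = c(1.5e4, 5.5e4),
                  end1 = c(2.5e4, 6.5e4),
                  chrom2 = "chr1", start2 = c(4e5, 2.55e5),
                  end2 = c(4.1e5, 2.65e5),
                  name = c("x", "y"), score = 1, stringsAsFactors = FALSE)
  d <- loop_set_difference(A, B, slack = 0)
  expect_setequal(d$name, c("a", "c"))
})

test_that("gene-to-loop distances are genomic minima with Inf flags", {
  loops <- data.frame(chrom1 = "chr1", start1 = 1e5, end1 = 1.2e5,
                      chrom2 = "chr1", start2 = 5e5, end2 = 5.2e5,
                      name = "L", score = 1, stringsAsFactors = FALSE)
  genes <- genomic_intervals(c("chr1", "chr1", "chr2"),
                             c(1.1e5, 3e5, 100), c(1.15e5, 3.1e5, 200),
                             name = c("inside", "between", "orphan"))
  expect_warning(d <- gene_loop_distances(genes, loops), "Inf")
  expect_equal(unname(d["inside"]), 0)
  # "between": min(3e5 - 1.2e5, 5e5 - 3.1e5) = 1.8e5
  expect_equal(unname(d["between"]), 1.8e5)
  expect_true(is.infinite(d["orphan"]))
})

test_that("per-cell signals smooth circularly along the trajectory", {
  ids <- sprintf("c%02d", 1:50)
  tau <- setNames((0:49) / 50, ids)
  const <- setNames(rep(2, 50), ids)
  expect_equal(unname(smooth_cell_signal(const, tau, 5)), rep(2, 50))

  ramp <- setNames(1:50, ids)
  sm <- smooth_cell_signal(ramp, tau, 5)
  oracle <- sapply(1:50, function(i) {
    idx <- ((i - 2):(i + 2) - 1) %% 50 + 1
    mean(ramp[idx])
  })
  expect_equal(unname(sm), oracle)
  expect_error(smooth_cell_signal(ramp, tau, 51), "window")
})

test_that("loop contact signal counts anchor-rectangle contacts, chromosome-normalized", {
  gb <- genome_binning(c(chr1 = 1e6, chr2 = 1e6), 1e5)
  c1 <- toy_cell(list(list("chr1", 1, 5, 4), list("chr1", 0, 3, 6),
                      list("chr2", 0, 9, 10)), gb, "c1")
  c2 <- toy_cell(list(list("chr1", 1, 5, 1)), gb, "c2")
  loop <- data.frame(chrom1 = "chr1", start1 = 1e5, end1 = 2e5,
                     chrom2 = "chr1", start2 = 5e5, end2 = 6e5,
                     name = "L", score = 1, stringsAsFactors = FALSE)
  s <- loop_contact_signal(list(c1, c2), loop)
  expect_equal(unname(s["c1"]), 4 / 10)   # chr2 contacts not in denominator
  expect_equal(unname(s["c2"]), 1)
  raw <- loop_contact_signal(list(c1, c2), loop, normalize = FALSE)
  expect_equal(unname(raw), c(4, 1))
})
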
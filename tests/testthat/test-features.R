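test_that("CDD occupies the log-distance bins given by the loc formula", {
  gb <- genome_binning(c(chr1 = 5e6), 2e4)
  cell <- toy_cell(list(list("chr1", 0, 2, 2), list("chr1", 0, 55, 1)),
                   binning = gb)
  # distances 40 kb (x2) and 1.1 Mb; expected bins from an independent
  # enumeration of loc = floor((log2(d) + s) / s)
  s <- 0.33
  v <- cdd_features(cell, steps = s, min_distance = 20e3)
  loc40 <- floor((log2(4e4) + s) / s)
  loc1100 <- floor((log2(1.1e6) + s) / s)
  expect_equal(unname(v[paste0("cdd_s0.33_loc", loc40)]), 2 / 3)
  expect_equal(unname(v[paste0("cdd_s0.33_loc", loc1100)]), 1 / 3)
  expect_equal(sum(v), 1)

  # "plain" variant uses floor(log2(d)/s)
  v2 <- cdd_features(cell, steps = s, min_distance = 20e3, variant = "plain")
  expect_equal(unname(v2[paste0("cdd_s0.33_loc", floor(log2(4e4) / s))]), 2 / 3)
})

test_that("CDD probabilities sum to 1 per step and ignore counts scaling", {
  set.seed(2)
  cell <- random_toy_cell(n = 60)
  v <- cdd_features(cell, min_distance = 1e3)
  steps <- c(0.1, 0.125, 0.2, 0.33)
  for (s in steps) {
    sel <- startsWith(names(v), sprintf("cdd_s%s_", format(s)))
    expect_equal(sum(v[sel]), 1)
    expect_true(all(v[sel] >= 0))
  }
  scaled <- cell
  scaled$contacts$count <- scaled$contacts$count * 7
  expect_equal(cdd_features(scaled, min_distance = 1e3), v)

  empty <- toy_cell(list(list("chr1", 0, 0, 5)))
  expect_error(cdd_features(empty, min_distance = 2e4), "no usable contacts")
})

test_that("PCC retains pairs above the value quantile (dense oracle)", {
  gb <- genome_binning(c(chr1 = 1e6), 1e5)
  c1 <- toy_cell(list(list("chr1", 0, 1, 4), list("chr1", 2, 3, 1),
                      list("chr1", 4, 5, 2)), gb, "a")
  c2 <- toy_cell(list(list("chr1", 0, 1, 6), list("chr1", 1, 2, 1),
                      list("chr1", 4, 5, 4)), gb, "b")
  c3 <- toy_cell(list(list("chr1", 0, 1, 2), list("chr1", 6, 7, 3),
                      list("chr1", 4, 5, 3)), gb, "c")
  cells <- list(c1, c2, c3)
  m <- pcc_features(cells, value_quantile = 0.5)
  # dense oracle: mean matrix over cells, median over observed pairs
  dm <- Reduce(`+`, lapply(cells, dense_matrix, chrom = "chr1")) / 3
  obs <- which(upper.tri(dm, diag = TRUE) &
                 Reduce(`|`, lapply(cells, function(cl)
                   dense_matrix(cl, "chr1") > 0)), arr.ind = TRUE)
  vals <- dm[obs]
  keep <- obs[vals > quantile(vals, 0.5), , drop = FALSE]
  expect_equal(ncol(m), nrow(keep))
  expect_equal(nrow(m), 3)
  for (r in seq_len(nrow(keep))) {
    cn <- sprintf("pcc_chr1_%d_%d", keep[r, 1] - 1, keep[r, 2] - 1)
    expect_true(cn %in% colnames(m))
    for (k in 1:3) {
      raw <- dense_matrix(cells[[k]], "chr1")[keep[r, 1], keep[r, 2]]
      expect_equal(m[k, cn], raw / cells[[k]]$total_contacts)
    }
  }
  # identical cells: every pair's value equals each cell's entry
  mm <- pcc_features(list(c1, c1, c1), value_quantile = 0.5)
  expect_true(all(mm[1, ] == mm[2, ]))
})

test_that("PCC selection is invariant to cell ordering", {
  set.seed(3)
  cells <- lapply(1:6, function(k) random_toy_cell(n = 40, id = paste0("c", k)))
  m1 <- pcc_features(cells, value_quantile = 0.7)
  m2 <- pcc_features(cells[c(4, 2, 6, 1, 5, 3)], value_quantile = 0.7)
  expect_equal(sort(colnames(m1)), sort(colnames(m2)))
  expect_equal(m1["c1", colnames(m1)], m2["c1", colnames(m1)])
})

test_that("insulation score matches the literal double-loop oracle", {
  gb <- genome_binning(c(chr1 = 1e6), 1e5)
  # uniform matrix: square window (2s+1)^2 terms over cross (s+1)^2 terms
  ones <- do.call(rbind, lapply(0:9, function(i)
    data.frame(chrom = "chr1", i = i, j = i:9, count = 1)))
  u <- contact_map(ones, gb, "u")
  ins <- insulation_score(u, scale = 2)$chr1
  expect_true(all(abs(ins[3:8] - 25 / 9) < 1e-12))
  expect_true(all(is.na(ins[c(1, 2, 9, 10)])))

  set.seed(9)
  for (k in 1:3) {
    cell <- random_toy_cell(binning = gb, n = 40)
    A <- dense_matrix(cell, "chr1")
    expect_equal(insulation_score(cell, scale = 2)$chr1,
                 insulation_bruteforce(A, 2))
  }
})

test_that("insulation features select bins by across-cell quantile", {
  gb <- genome_binning(c(chr1 = 2e6), 1e5)
  set.seed(4)
  cells <- lapply(1:3, function(k) {
    df <- do.call(rbind, lapply(0:19, function(i)
      data.frame(chrom = "chr1", i = i, j = i:min(19, i + 4),
                 count = sample(1:4, min(19, i + 4) - i + 1, replace = TRUE))))
    contact_map(df, gb, paste0("c", k))
  })
  m0 <- ins_features(cells, scale = 2, selection_quantile = 0)
  per_cell <- sapply(cells, function(cl) insulation_score(cl, 2)$chr1)
  defined <- rowSums(is.na(per_cell)) == 0
  expect_equal(ncol(m0), sum(defined))

  m <- ins_features(cells, scale = 2, selection_quantile = 0.8)
  means <- rowMeans(per_cell)[defined]
  expect_equal(ncol(m), sum(means > quantile(means, 0.8)))
  # ratio form: scaling all counts leaves features unchanged
  cells2 <- lapply(cells, function(cl) {
    cl$contacts$count <- cl$contacts$count * 3
    contact_map(cl$contacts, cl$binning, cl$cell_id)
  })
  expect_equal(ins_features(cells2, scale = 2, selection_quantile = 0.8), m)
})

test_that("MCM metrics match hand computation", {
  gb <- genome_binning(c(chr1 = 5e7), 1e5)
  all_near <- toy_cell(list(list("chr1", 0, 10, 5)), gb)  # d = 1 Mb
  expect_warning(v <- mcm_features(all_near), "far")
  expect_equal(unname(v["pct_near"]), 100)
  expect_equal(unname(v["pct_mitotic"]), 0)

  # 10 contacts: distances 0.5, 1, 3, 5, 8, 20 Mb with counts 2,1,3,1,2,1
  cell <- toy_cell(list(list("chr1", 0, 5, 2), list("chr1", 0, 10, 1),
                        list("chr1", 0, 30, 3), list("chr1", 0, 50, 1),
                        list("chr1", 0, 80, 2), list("chr1", 0, 200, 1)), gb)
  v <- mcm_features(cell)
  expect_equal(unname(v["pct_near"]), 100 * 3 / 10)
  expect_equal(unname(v["pct_mitotic"]), 100 * 6 / 10)
  expect_equal(unname(v["mean_far_dist"]),
               (5e6 * 1 + 8e6 * 2 + 20e6 * 1) / 4)
  expect_length(v, 3)

  # early fraction appears only with a replication-timing annotation
  rt <- genomic_intervals("chr1", 0, 2e6)
  v4 <- mcm_features(cell, replication_timing = rt)
  expect_length(v4, 4)
  # fends in [0, 2 Mb): bin 0 of every contact (10) + bins 5 and 10 (3)
  expect_equal(unname(v4["early_frac"]), 13 / 20)

  near_only <- toy_cell(list(list("chr1", 0, 1, 1)), gb)
  expect_warning(v3 <- mcm_features(near_only), "far")
  expect_equal(unname(v3["mean_far_dist"]), 4.5e6)
})

test_that("assemble_features concatenates, standardizes, and validates cells", {
  a <- matrix(1:6, 3, 2, dimnames = list(c("x", "y", "z"), c("f1", "f2")))
  b <- matrix(c(2, 2, 2, 5, 7, 9), 3, 2,
              dimnames = list(c("z", "x", "y"), c("g1", "g2")))
  plain <- assemble_features(list(A = a), standardize = FALSE)
  expect_equal(plain, a, ignore_attr = TRUE)

  m <- suppressMessages(assemble_features(list(A = a, B = b)))
  # rows aligned by cell id, constant column g1 dropped
  expect_equal(colnames(m), c("f1", "f2", "g2"))
  expect_equal(unname(colMeans(m)), rep(0, 3))
  expect_equal(unname(apply(m, 2, var)), rep(1, 3))
  expect_equal(m["x", "g2"], unname(scale(c(7, 9, 5))[1]))

  bad <- b[1:2, ]
  expect_error(assemble_features(list(A = a, B = bad)), "does not cover")
})
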
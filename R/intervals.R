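#' Genomic interval records (BED-style)
#'
#' Intervals are plain data.frames with columns `chrom`, `start`, `end`
#' (0-based half-open, `start < end`) and optional `name`, `score`.
#'
#' @param chrom,start,end,name,score interval fields.
#' @return a validated interval data.frame.
#' @export
genomic_intervals <- function(chrom, start, end,
                              name = ".", score = 0) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = rep_len(name, n),
                   score = rep_len(score, n), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  if (any(df$start < 0)) stop("negative interval start")
  df
}

#' Read / write BED3+ interval files
#'
#' @param path file path.
#' @param chrom_sizes optional named vector; when given, coordinates are
#'   checked against chromosome bounds.
#' @return `read_bed`: interval data.frame; `write_bed`: `path` invisibly.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 3) stop("BED needs >= 3 columns")
  iv <- genomic_intervals(tab[[1]], tab[[2]], tab[[3]],
                          name = if (ncol(tab) >= 4) as.character(tab[[4]]) else ".",
                          score = if (ncol(tab) >= 5) as.numeric(tab[[5]]) else 0)
  check_bounds(iv, chrom_sizes)
  iv
}

#' @rdname read_bed
#' @param intervals interval data.frame.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end", "name", "score")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_bounds <- function(iv, chrom_sizes) {
  if (is.null(chrom_sizes)) return(invisible())
  sz <- chrom_sizes[iv$chrom]
  if (anyNA(sz)) stop("unknown chromosome(s): ",
                      paste(unique(iv$chrom[is.na(sz)]), collapse = ", "))
  if (any(iv$end > sz)) stop("interval end beyond chromosome length")
  invisible()
}

#' Read / write BEDPE loop files
#'
#' Loops are data.frames with anchor columns `chrom1,start1,end1` and
#' `chrom2,start2,end2` plus optional `name`, `score`; anchor 1 must lie
#' upstream of anchor 2 on the same chromosome.
#'
#' @param path file path.
#' @param chrom_sizes optional named vector for bounds checks.
#' @return `read_bedpe`: loop data.frame; `write_bedpe`: `path` invisibly.
#' @export
read_bedpe <- function(path, chrom_sizes = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 6) stop("BEDPE needs >= 6 columns")
  lp <- data.frame(chrom1 = as.character(tab[[1]]), start1 = as.numeric(tab[[2]]),
                   end1 = as.numeric(tab[[3]]), chrom2 = as.character(tab[[4]]),
                   start2 = as.numeric(tab[[5]]), end2 = as.numeric(tab[[6]]),
                   name = if (ncol(tab) >= 7) as.character(tab[[7]]) else ".",
                   score = if (ncol(tab) >= 8) as.numeric(tab[[8]]) else 0,
                   stringsAsFactors = FALSE)
  validate_loops(lp, chrom_sizes)
  lp
}

#' @rdname read_bedpe
#' @param loops loop data.frame.
#' @export
write_bedpe <- function(loops, path) {
  utils::write.table(loops[, c("chrom1", "start1", "end1",
                               "chrom2", "start2", "end2", "name", "score")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_loops <- function(lp, chrom_sizes = NULL) {
  if (any(lp$chrom1 != lp$chrom2)) stop("loop anchors must share a chromosome")
  if (any(lp$start1 >= lp$end1 | lp$start2 >= lp$end2))
    stop("anchors must satisfy start < end")
  if (any(lp$start1 > lp$start2)) stop("anchor 1 must be upstream of anchor 2")
  check_bounds(genomic_intervals(lp$chrom1, lp$start1, lp$end1), chrom_sizes)
  check_bounds(genomic_intervals(lp$chrom2, lp$start2, lp$end2), chrom_sizes)
  invisible()
}

#' Split loops into their two anchor intervals
#'
#' @param loops loop data.frame (see [read_bedpe()]).
#' @return interval data.frame with one row per anchor.
#' @export
loop_anchors <- function(loops) {
  rbind(genomic_intervals(loops$chrom1, loops$start1, loops$end1,
                          name = paste0(loops$name, "/1")),
        genomic_intervals(loops$chrom2, loops$start2, loops$end2,
                          name = paste0(loops$name, "/2")))
}

# vector of logicals: does interval q overlap any interval in set?
# intervals are 0-based half-open; overlap means nonempty intersection.
overlaps_any <- function(q, set, slack = 0) {
  out <- logical(nrow(q))
  for (ch in unique(q$chrom)) {
    sq <- which(q$chrom == ch)
    ss <- set[set$chrom == ch, ]
    if (!nrow(ss)) next
    for (k in sq)
      out[k] <- any(q$start[k] < ss$end + slack & ss$start - slack < q$end[k])
  }
  out
}

# per-query minimum genomic distance (bp) to any interval in set (0 if overlap);
# Inf when the query's chromosome has no intervals in set.
min_distance_to_set <- function(q, set) {
  out <- rep(Inf, nrow(q))
  for (ch in unique(q$chrom)) {
    sq <- which(q$chrom == ch)
    ss <- set[set$chrom == ch, ]
    if (!nrow(ss)) next
    for (k in sq) {
      d <- pmax(0, pmax(ss$start - q$end[k], q$start[k] - ss$end))
      out[k] <- min(d)
    }
  }
  out
}
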
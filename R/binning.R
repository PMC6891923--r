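#' Genome binning scheme
#'
#' Defines fixed-width genomic bins over a set of chromosomes. Bin `b` of a
#' chromosome covers the 0-based half-open interval
#' `[b * bin_width, (b + 1) * bin_width)`; the last bin may be partial.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param bin_width bin width in bp (e.g. 25e3, 40e3, 100e3, 500e3, 1e6).
#' @return an object of class `genome_binning` with elements `chrom_sizes`,
#'   `bin_width` and `n_bins` (bins per chromosome).
#' @examples
#' gb <- genome_binning(c(chr1 = 1e6, chr2 = 5e5), 1e5)
#' gb$n_bins
#' @export
genome_binning <- function(chrom_sizes, bin_width) {
  stopifnot(is.numeric(chrom_sizes), length(chrom_sizes) >= 1,
            !is.null(names(chrom_sizes)), all(chrom_sizes > 0),
            length(bin_width) == 1, bin_width > 0)
  structure(
    list(chrom_sizes = chrom_sizes,
         bin_width = as.numeric(bin_width),
         n_bins = setNames(as.integer(ceiling(chrom_sizes / bin_width)),
                           names(chrom_sizes))),
    class = "genome_binning")
}

#' @export
print.genome_binning <- function(x, ...) {
  cat("genome_binning:", length(x$chrom_sizes), "chromosome(s),",
      "bin width", format(x$bin_width, big.mark = ","), "bp,",
      sum(x$n_bins), "bins total\n")
  invisible(x)
}

#' Map 0-based genomic positions to bin indices
#'
#' @param binning a [genome_binning()].
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s) in bp.
#' @return integer 0-based bin indices.
#' @export
bin_index <- function(binning, chrom, pos) {
  sizes <- binning$chrom_sizes[chrom]
  if (anyNA(sizes)) {
    bad <- unique(chrom[is.na(sizes)])
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  if (any(pos < 0 | pos >= sizes))
    stop("position outside chromosome bounds")
  as.integer(floor(pos / binning$bin_width))
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path file path.
#' @param bin_width bin width in bp for the returned binning.
#' @return a [genome_binning()].
#' @export
read_chrom_sizes <- function(path, bin_width) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("chrom-sizes file needs >= 2 columns")
  genome_binning(setNames(as.numeric(tab[[2]]), as.character(tab[[1]])),
                 bin_width)
}

same_binning <- function(a, b) {
  isTRUE(all.equal(a$bin_width, b$bin_width)) &&
    identical(names(a$chrom_sizes), names(b$chrom_sizes)) &&
    isTRUE(all.equal(unname(a$chrom_sizes), unname(b$chrom_sizes)))
}
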
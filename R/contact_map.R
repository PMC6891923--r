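#' Construct a per-cell binned contact map
#'
#' Sparse upper-triangular intrachromosomal contact counts for one cell.
#' Triplets `(chrom, i, j, count)` use 0-based bin indices with `i <= j`.
#'
#' @param contacts data.frame with columns `chrom`, `i`, `j`, `count`.
#' @param binning a [genome_binning()].
#' @param cell_id cell identifier.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(contacts, binning, cell_id = "cell") {
  stopifnot(inherits(binning, "genome_binning"),
            all(c("chrom", "i", "j", "count") %in% names(contacts)))
  contacts <- contacts[, c("chrom", "i", "j", "count")]
  contacts$chrom <- as.character(contacts$chrom)
  if (nrow(contacts)) {
    swap <- contacts$i > contacts$j
    if (any(swap)) {
      tmp <- contacts$i[swap]
      contacts$i[swap] <- contacts$j[swap]
      contacts$j[swap] <- tmp
    }
    if (any(contacts$count <= 0)) stop("counts must be positive")
    nb <- binning$n_bins[contacts$chrom]
    if (anyNA(nb)) stop("unknown chromosome(s): ",
                        paste(unique(contacts$chrom[is.na(nb)]), collapse = ", "))
    if (any(contacts$j >= nb)) stop("bin index outside chromosome")
    key <- paste(contacts$chrom, contacts$i, contacts$j)
    if (anyDuplicated(key)) {
      cnt <- rowsum(contacts$count, key, reorder = FALSE)
      first <- !duplicated(key)
      contacts <- contacts[first, ]
      contacts$count <- cnt[match(paste(contacts$chrom, contacts$i, contacts$j),
                                  rownames(cnt)), 1]
    }
    o <- order(contacts$chrom, contacts$i, contacts$j)
    contacts <- contacts[o, ]
    rownames(contacts) <- NULL
  }
  structure(list(cell_id = cell_id, binning = binning, contacts = contacts,
                 total_contacts = sum(contacts$count)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map '", x$cell_id, "': ", nrow(x$contacts),
      " bin pairs, ", x$total_contacts, " contacts\n", sep = "")
  invisible(x)
}

#' Read a pairs-format contact list into a binned contact map
#'
#' The pairs dialect is whitespace/tab-delimited with columns
#' `chrom1 pos1 chrom2 pos2 [count]` (0-based positions). Interchromosomal
#' records and pairs closer than `min_distance` are dropped.
#'
#' @param path pairs file.
#' @param binning a [genome_binning()].
#' @param min_distance minimum genomic distance in bp (strict; default 1 kb).
#' @param cell_id cell identifier (default: file base name).
#' @return a [contact_map()].
#' @export
read_pairs <- function(path, binning, min_distance = 1e3,
                       cell_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    return(contact_map(data.frame(chrom = character(), i = integer(),
                                  j = integer(), count = numeric()),
                       binning, cell_id))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("malformed pairs line ", which(nf < 4)[1], ": expected >= 4 columns")
  chrom1 <- vapply(fields, `[[`, "", 1)
  pos1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  chrom2 <- vapply(fields, `[[`, "", 3)
  pos2 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4)))
  count <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(vapply(fields, function(f)
                    if (length(f) >= 5) f[[5]] else "1", ""))), 1)
  bad <- which(is.na(pos1) | is.na(pos2) | is.na(count))
  if (length(bad))
    stop("malformed pairs line ", bad[1], ": non-numeric field")
  known <- names(binning$chrom_sizes)
  unk <- setdiff(unique(c(chrom1, chrom2)), known)
  if (length(unk)) stop("unknown chromosome(s): ", paste(unk, collapse = ", "))
  intra <- chrom1 == chrom2
  n_inter <- sum(!intra)
  if (n_inter) message(n_inter, " interchromosomal pair(s) dropped")
  keep <- intra & abs(pos2 - pos1) > min_distance
  contact_map(data.frame(chrom = chrom1[keep],
                         i = bin_index(binning, chrom1[keep], pos1[keep]),
                         j = bin_index(binning, chrom2[keep], pos2[keep]),
                         count = count[keep]),
              binning, cell_id)
}

#' Write a contact map back to the pairs text format
#'
#' Positions are emitted at bin starts (off-diagonal pairs) or half a bin
#' apart (diagonal pairs), so re-reading with `min_distance < bin_width / 2`
#' reproduces the map exactly.
#'
#' @param map a [contact_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(map, path) {
  ct <- map$contacts
  bw <- map$binning$bin_width
  pos1 <- ct$i * bw
  pos2 <- ifelse(ct$i == ct$j, ct$j * bw + floor(bw / 2), ct$j * bw)
  utils::write.table(
    data.frame(ct$chrom, pos1, ct$chrom, pos2, ct$count),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pool contact maps of several cells into one aggregated map
#'
#' @param cells non-empty list of [contact_map()] objects sharing one binning.
#' @param cell_id identifier for the pooled map.
#' @return a [contact_map()] with triplet-wise summed counts.
#' @export
pool_cells <- function(cells, cell_id = sprintf("pooled(n=%d)", length(cells))) {
  if (!length(cells)) stop("cannot pool an empty cell list")
  stopifnot(all(vapply(cells, inherits, TRUE, "contact_map")))
  b <- cells[[1]]$binning
  for (cl in cells[-1])
    if (!same_binning(b, cl$binning)) stop("cells do not share one binning")
  all_ct <- do.call(rbind, lapply(cells, `[[`, "contacts"))
  contact_map(all_ct, b, cell_id)
}

#' Dense symmetric contact matrix for one chromosome
#'
#' @param map a [contact_map()].
#' @param chrom chromosome name.
#' @return an `n_bins x n_bins` symmetric numeric matrix.
#' @export
dense_matrix <- function(map, chrom) {
  n <- map$binning$n_bins[[chrom]]
  if (is.null(n)) stop("unknown chromosome: ", chrom)
  A <- matrix(0, n, n)
  ct <- map$contacts[map$contacts$chrom == chrom, ]
  if (nrow(ct)) {
    A[cbind(ct$i + 1L, ct$j + 1L)] <- ct$count
    A[cbind(ct$j + 1L, ct$i + 1L)] <- ct$count
  }
  A
}

#' Genomic distances and counts of a map's contacts
#'
#' Bin-pair separations in bp, `(j - i) * bin_width`, with their counts.
#'
#' @param map a [contact_map()].
#' @return data.frame with columns `distance` (bp) and `count`.
#' @keywords internal
contact_distances <- function(map) {
  data.frame(distance = (map$contacts$j - map$contacts$i) * map$binning$bin_width,
             count = map$contacts$count)
}
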
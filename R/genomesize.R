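#' Modal genomic depth of a k-mer histogram
#'
#' The genomic-peak depth: argmax of the count over depths at or above
#' `minDepth` (the low-depth cutoff screens out the sequencing-error
#' spike). Ties are broken toward the larger depth, since heterozygosity
#' shoulders sit below the main peak.
#'
#' @param hist data.frame with columns `depth`, `count`.
#' @param minDepth smallest depth considered part of the genomic peak.
#' @return The modal depth (integer).
#' @export
peakDepth <- function(hist, minDepth = 5) {
  .check_hist(hist)
  h <- hist[hist$depth >= minDepth & hist$count > 0, ]
  if (!nrow(h)) stop("no histogram mass at depth >= ", minDepth)
  best <- h$count == max(h$count)
  max(h$depth[best])
}

#' Genome size from a k-mer depth histogram
#'
#' Applies `G = K_num / K_depth`: total k-mer count over modal genomic
#' depth. By default `K_num` sums depth x count over all depths (the
#' literal total number of k-mers); `excludeErrors = TRUE` drops depths
#' below `minDepth` from the total, which removes the error-spike
#' contribution at the cost of also dropping genuine low-depth k-mers.
#'
#' @param hist data.frame with columns `depth`, `count`.
#' @param minDepth low-depth cutoff for the peak search (and for `K_num`
#'   when `excludeErrors` is set).
#' @param excludeErrors drop depths below `minDepth` from `K_num`.
#' @return A list of class `"genomeSizeEstimate"`: `K_num`, `K_depth`,
#'   `G`, `excluded_low_depth_cutoff`.
#' @examples
#' h <- data.frame(depth = c(29, 30, 31), count = c(1e6, 4e6, 1e6))
#' estimateGenomeSize(h)$K_depth   # 30
#' @export
estimateGenomeSize <- function(hist, minDepth = 5, excludeErrors = FALSE) {
  .check_hist(hist)
  kd <- peakDepth(hist, minDepth)
  h <- if (excludeErrors) hist[hist$depth >= minDepth, ] else hist
  knum <- sum(h$depth * h$count)
  structure(list(K_num = knum, K_depth = kd, G = knum / kd,
                 excluded_low_depth_cutoff = if (excludeErrors) minDepth
                                             else NA_integer_),
            class = "genomeSizeEstimate")
}

#' @export
print.genomeSizeEstimate <- function(x, ...) {
  cat(sprintf("k-mer genome size estimate: G = %.4g (K_num = %.4g, K_depth = %d)\n",
              x$G, x$K_num, x$K_depth))
  invisible(x)
}

#' Read a two-column k-mer histogram TSV
#'
#' @param path TSV with columns depth, count (no header expected; a header
#'   line is tolerated).
#' @return data.frame(depth, count).
#' @export
readKmerHistogram <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (grepl("[A-Za-z]", first)) 1L else 0L
  df <- utils::read.table(path, sep = "\t", skip = skip,
                          col.names = c("depth", "count"))
  .check_hist(df)
  df
}

.check_hist <- function(hist) {
  if (!all(c("depth", "count") %in% names(hist)))
    stop("histogram needs 'depth' and 'count' columns")
  if (!nrow(hist)) stop("empty histogram")
  if (any(hist$depth < 1)) stop("depths must be >= 1")
  if (any(hist$count < 0)) stop("negative counts")
  invisible(TRUE)
}
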
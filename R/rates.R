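#' Tajima's relative rate test
#'
#' Counts, over columns where all three sequences carry an unambiguous
#' non-gap symbol, the sites unique to lineage 1 (`m1`: seq1 differs while
#' seq2 equals the outgroup) and unique to lineage 2 (`m2`), and tests
#' rate equality with the 1-df chi-square statistic
#' `(m1 - m2)^2 / (m1 + m2)`. Columns with a gap or ambiguity in any of
#' the three rows contribute to neither count, as do columns where all
#' three states differ.
#'
#' @param seq1,seq2,outgroupSeq aligned sequences of equal length, as
#'   character vectors of symbols or single strings.
#' @param alphabet `"nucleotide"` or `"amino_acid"` (controls which
#'   symbols count as ambiguous).
#' @return An object of class `"htest"` with `statistic` (X-squared),
#'   `parameter` (df = 1), `p.value`, and `estimate = c(m1, m2)`. When
#'   `m1 + m2 = 0` the statistic is 0, p = 1, and the `note` field flags
#'   "no informative sites".
#' @examples
#' # m1 = 2, m2 = 0
#' tajimaRRT("AACCA", "AACCT", "AACCT")
#' @export
tajimaRRT <- function(seq1, seq2, outgroupSeq,
                      alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  tochar <- function(x) {
    if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]]
    else as.character(x)
  }
  a <- toupper(tochar(seq1)); b <- toupper(tochar(seq2))
  o <- toupper(tochar(outgroupSeq))
  if (length(a) != length(b) || length(a) != length(o))
    stop("sequences must have equal length")
  bad <- c("-", .missing_symbols(alphabet))
  ok <- !(a %in% bad) & !(b %in% bad) & !(o %in% bad)
  m1 <- sum(ok & a != b & b == o)
  m2 <- sum(ok & a != b & a == o)
  chi2 <- if (m1 + m2 > 0) (m1 - m2)^2 / (m1 + m2) else 0
  p <- if (m1 + m2 > 0) pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  out <- list(
    statistic = c("X-squared" = chi2),
    parameter = c(df = 1),
    p.value = p,
    estimate = c(m1 = m1, m2 = m2),
    method = "Tajima relative rate test",
    data.name = sprintf("%d informative sites", sum(ok)),
    note = if (m1 + m2 == 0) "no informative sites" else NULL)
  class(out) <- "htest"
  out
}

#' Two-cluster relative-rate Z test
#'
#' Tests whether two taxon clusters evolve at the same average rate
#' relative to an outgroup: `delta` is the difference between the mean
#' cluster-A-to-outgroup and mean cluster-B-to-outgroup distances, its
#' standard error comes from a site bootstrap (alignment columns resampled
#' with replacement), and `z = delta/se` is referred to the standard
#' normal (two-sided).
#'
#' @param aln a [LineageAlignment-class] (`nucleotide` or `amino_acid`).
#' @param clusterA,clusterB,outgroupTaxa disjoint, non-empty taxon sets.
#' @param distance `"p"` (proportion of differing sites; default) or
#'   `"poisson"` (`-log(1 - p)` multiple-hit correction; errors on
#'   saturated pairs).
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap (recorded in the result).
#' @return An object of class `"htest"` with `statistic` (z), `p.value`,
#'   `estimate = c(delta, se)`, and `nBoot`/`seed` fields.
#' @export
twoClusterTest <- function(aln, clusterA, clusterB, outgroupTaxa,
                           distance = c("p", "poisson"), nBoot = 1000,
                           seed = NULL) {
  distance <- match.arg(distance)
  stopifnot(is(aln, "LineageAlignment"))
  groups <- list(A = clusterA, B = clusterB, O = outgroupTaxa)
  if (any(lengths(groups) == 0L)) stop("all three groups must be non-empty")
  if (anyDuplicated(unlist(groups)))
    stop("clusters and outgroup must be disjoint")
  m <- as.matrix(aln)
  missTx <- setdiff(unlist(groups), rownames(m))
  if (length(missTx))
    stop("taxa missing from alignment: ", paste(missTx, collapse = ", "))
  miss <- .is_missing(m, alphabet(aln))
  L <- ncol(m)
  pairs <- rbind(expand.grid(x = clusterA, o = outgroupTaxa,
                             stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
                 expand.grid(x = clusterB, o = outgroupTaxa,
                             stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  inA <- pairs$x %in% clusterA
  D <- t(apply(pairs, 1, function(pr)
    m[pr[["x"]], ] != m[pr[["o"]], ] & !miss[pr[["x"]], ] & !miss[pr[["o"]], ]))
  V <- t(apply(pairs, 1, function(pr)
    !miss[pr[["x"]], ] & !miss[pr[["o"]], ]))
  storage.mode(D) <- "numeric"; storage.mode(V) <- "numeric"
  informative <- colSums(V) > 0
  if (sum(informative) < 10) stop("insufficient signal: fewer than 10 ",
                                  "informative columns")
  dist_fun <- function(num, den) {
    p <- ifelse(den > 0, num / den, 0)
    if (distance == "poisson") {
      nStates <- if (alphabet(aln) == "nucleotide") 4 else 20
      if (any(p >= 1 - 1 / nStates))
        stop("saturated: p-distance at or beyond the Poisson-correctable ",
             "range for some pair")
      -log(1 - p)
    } else p
  }
  delta_of <- function(w) {
    d <- dist_fun(as.numeric(D %*% w), as.numeric(V %*% w))
    mean(d[inA]) - mean(d[!inA])
  }
  delta <- delta_of(rep(1, L))
  if (!is.null(seed)) set.seed(seed)
  W <- rmultinom(nBoot, size = L, prob = rep(1 / L, L))
  boot <- apply(W, 2, delta_of)
  se <- stats::sd(boot)
  z <- if (se > 0) delta / se else if (delta == 0) 0 else sign(delta) * Inf
  p <- 2 * pnorm(-abs(z))
  out <- list(
    statistic = c(z = z),
    p.value = p,
    estimate = c(delta = delta, se = se),
    method = sprintf(
      "Two-cluster relative-rate Z test (%s distance, %d site bootstraps)",
      distance, nBoot),
    data.name = sprintf("%d columns (%d informative)", L, sum(informative)),
    nBoot = nBoot, seed = seed)
  class(out) <- "htest"
  out
}
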
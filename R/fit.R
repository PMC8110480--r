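#' One-ratio (M0) GY94 fit
#'
#' Maximizes the GY94 likelihood over kappa, a single tree-wide omega, and a
#' global branch-length scale. Branch-length proportions are taken from the
#' input tree; only the overall scale is free. Optimization is bounded
#' quasi-Newton (`L-BFGS-B` on log parameters) from a deterministic start
#' grid (kappa in \{1,2,4\} x omega in \{0.1,0.5,1.5\}); the two best grid
#' points are polished.
#'
#' @param aln codon [LineageAlignment-class].
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param codonFreqs `"f3x4"` (default), `"equal"`, or a length-61 numeric
#'   vector.
#' @return A list with `kappa`, `omega`, `scale`, `lnL`, `converged`,
#'   `codonFreqs`.
#' @export
fitM0 <- function(aln, tree, codonFreqs = "f3x4") {
  pi <- .resolve_freqs(codonFreqs, aln)
  .check_identifiable(aln, tree)
  prep <- .loglik_prep(aln, tree)
  nll <- function(p) {
    v <- exp(p)
    -.codon_lnl(prep, kappa = v[1], omega = v[2], codonFreqs = pi,
                scale = v[3])
  }
  starts <- expand.grid(kappa = c(1, 2, 4), omega = c(0.1, 0.5, 1.5))
  sp <- lapply(seq_len(nrow(starts)),
               function(i) log(c(starts$kappa[i], starts$omega[i], 1)))
  fit <- .polish_best(nll, sp, n_polish = 2L)
  v <- exp(fit$par)
  list(kappa = v[1], omega = v[2], scale = v[3], lnL = -fit$value,
       converged = fit$convergence == 0L, codonFreqs = pi)
}

#' Two-ratio branch-model GY94 fit
#'
#' Fits the one-ratio (M0) model and the two-ratio branch model in which
#' the foreground branches (the focal clade and its stem) carry their own
#' omega0 while all remaining branches share omega1; omega2 is the M0
#' tree-wide estimate. The two-ratio optimization starts from the M0
#' optimum (so its likelihood can never fall below the nested M0
#' likelihood) plus deterministic perturbed starts.
#'
#' @param aln codon [LineageAlignment-class].
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param partition a [LineagePartition-class] naming the focal clade, or
#'   NULL if `foreground` is given directly.
#' @param foreground child-node ids of foreground edges; computed from
#'   `partition` by default.
#' @param codonFreqs as in [fitM0()].
#' @param m0 an existing [fitM0()] result to reuse (optional).
#' @return A [BranchModelFit-class].
#' @export
fitBranchModel <- function(aln, tree, partition = NULL, foreground = NULL,
                           codonFreqs = "f3x4", m0 = NULL) {
  if (is.null(foreground)) {
    if (is.null(partition)) stop("give either a partition or foreground edges")
    foreground <- foregroundEdges(tree, partition)
  }
  nEdge <- nrow(tree$edge)
  nFg <- sum(tree$edge[, 2] %in% foreground)
  if (nFg == 0L) stop("foreground branch set is empty")
  if (nFg >= nEdge) stop("foreground must be a strict subset of branches")
  pi <- .resolve_freqs(codonFreqs, aln)
  if (is.null(m0)) m0 <- fitM0(aln, tree, codonFreqs = pi)
  prep <- .loglik_prep(aln, tree)
  nll <- function(p) {
    v <- exp(p)   # kappa, omega0 (fg), omega1 (bg), scale
    -.codon_lnl(prep, kappa = v[1], omega = v[3], codonFreqs = pi,
                foreground = foreground, omegaFg = v[2], scale = v[4])
  }
  base <- log(c(m0$kappa, m0$omega, m0$omega, m0$scale))
  starts <- list(base,
                 base + c(0, log(4), 0, 0),
                 base + c(0, log(0.25), 0, 0))
  fit <- .polish_best(nll, starts, n_polish = 3L)
  v <- exp(fit$par)
  new("BranchModelFit",
      omega0 = v[2], omega1 = v[3], omega2 = m0$omega, kappa = v[1],
      lnLBranch = max(-fit$value, m0$lnL), lnLM0 = m0$lnL,
      converged = fit$convergence == 0L && m0$converged,
      nCodons = ncol(as.matrix(aln)), scale = v[4])
}

#' Classify a branch-model fit as PSG / REG / NS
#'
#' Likelihood-ratio test of the two-ratio branch model against the
#' one-ratio model (1 df chi-square). A gene is called PSG (positively
#' selected) when the test is significant, omega0 exceeds both omega1 and
#' omega2, and omega0 > 1; REG (rapidly evolving) when significant and
#' omega0 exceeds both but omega0 <= 1; otherwise NS.
#'
#' @param fit a [BranchModelFit-class].
#' @param alpha significance threshold (default 0.05).
#' @param gene gene id carried into the output.
#' @return One-row data.frame: gene, omega0, omega1, omega2, kappa,
#'   lnL_m0, lnL_branch, lrt, p, class.
#' @examples
#' fit <- new("BranchModelFit", omega0 = 2.5, omega1 = 0.3, omega2 = 0.35,
#'            kappa = 2, lnLBranch = -1000, lnLM0 = -1005.4,
#'            converged = TRUE, nCodons = 300L, scale = 1)
#' classifySelection(fit)$class   # "PSG"
#' @export
classifySelection <- function(fit, alpha = 0.05, gene = NA_character_) {
  lrt <- max(0, 2 * (fit@lnLBranch - fit@lnLM0))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  cls <- "NS"
  if (fit@converged && p < alpha &&
      fit@omega0 > max(fit@omega1, fit@omega2)) {
    cls <- if (fit@omega0 > 1) "PSG" else "REG"
  }
  data.frame(gene = gene, omega0 = fit@omega0, omega1 = fit@omega1,
             omega2 = fit@omega2, kappa = fit@kappa, lnL_m0 = fit@lnLM0,
             lnL_branch = fit@lnLBranch, lrt = lrt, p = p, class = cls,
             converged = fit@converged, stringsAsFactors = FALSE)
}

.resolve_freqs <- function(codonFreqs, aln) {
  if (is.numeric(codonFreqs)) return(codonFreqs)
  switch(match.arg(codonFreqs, c("f3x4", "equal")),
         f3x4 = codonFreqsF3x4(aln),
         equal = rep(1 / 61, 61))
}

.check_identifiable <- function(aln, tree) {
  m <- as.matrix(aln)
  miss <- .is_missing(m, "codon")
  variable <- any(vapply(seq_len(ncol(m)), function(j) {
    x <- m[!miss[, j], j]
    length(unique(x)) > 1L
  }, logical(1)))
  if (!variable) stop("omega unidentifiable: no variable codon columns")
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0)
    stop("no information: all branch lengths are zero")
}

## evaluate nll at all starts, polish the n best with L-BFGS-B
.polish_best <- function(nll, starts, n_polish = 2L,
                         lower = log(c(1e-2, 1e-4, 1e-4, 1e-3)),
                         upper = log(c(100, 50, 50, 1e3))) {
  k <- length(starts[[1]])
  lower <- lower[seq_len(k)]; upper <- upper[seq_len(k)]
  vals <- vapply(starts, nll, numeric(1))
  ord <- order(vals)[seq_len(min(n_polish, length(starts)))]
  fits <- lapply(ord, function(i) {
    tryCatch(
      optim(starts[[i]], nll, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = 1e8, maxit = 200)),
      error = function(e) list(par = starts[[i]], value = vals[i],
                               convergence = 52L))
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
}
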
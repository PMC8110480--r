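#' GY94 codon substitution rate matrix
#'
#' Builds the 61x61 Goldman-Yang codon rate matrix. Codons differing at
#' more than one nucleotide position have rate 0; single-nucleotide changes
#' get rate `pi_j * kappa^transition * omega^nonsynonymous`. The matrix is
#' scaled so the expected number of substitutions per unit branch length is
#' one (`-sum(pi_i * q_ii) = 1`). Zero target frequencies simply produce
#' structural zero rates.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS, >= 0).
#' @param codonFreqs length-61 equilibrium codon frequencies in
#'   [senseCodons()] order, summing to 1; default equal (1/61).
#' @return 61x61 matrix with rows/columns named by codon; rows sum to 0.
#' @examples
#' Q <- buildGY94(kappa = 2, omega = 0.5)
#' range(rowSums(Q))   # ~0
#' @export
buildGY94 <- function(kappa, omega, codonFreqs = rep(1 / 61, 61)) {
  stopifnot(kappa > 0, omega >= 0)
  if (length(codonFreqs) != .GC$n)
    stop("codonFreqs must have length ", .GC$n)
  if (abs(sum(codonFreqs) - 1) > 1e-9)
    stop("codon frequencies must sum to 1 (got ", sum(codonFreqs), ")")
  if (any(codonFreqs < 0)) stop("negative codon frequencies")
  n <- .GC$n
  R <- matrix(0, n, n, dimnames = list(.GC$codons, .GC$codons))
  R[.GC$neighbor] <- 1
  R[.GC$transition] <- kappa
  R[.GC$neighbor & .GC$nonsyn] <- R[.GC$neighbor & .GC$nonsyn] * omega
  Q <- R * rep(codonFreqs, each = n)    # q_ij = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(codonFreqs * diag(Q))
  if (mu > 0) Q <- Q / mu
  Q
}

## Spectral decomposition of the reversible GY94 generator:
## with D = diag(pi), B = D^{1/2} Q D^{-1/2} is symmetric, so
## P(t) = D^{-1/2} V exp(Lt) V' D^{1/2}.  Requires all pi > 0.
.gy94_eigen <- function(kappa, omega, codonFreqs) {
  if (any(codonFreqs <= 0))
    stop("spectral path needs strictly positive codon frequencies; ",
         "apply a small floor (see codonFreqsF3x4)")
  Q <- buildGY94(kappa, omega, codonFreqs)
  s <- sqrt(codonFreqs)
  B <- Q * (s / rep(s, each = length(s)))   # diag(s) Q diag(1/s), row-major
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / s,                   # D^{-1/2} V
       Uinv = t(e$vectors) * rep(s, each = length(s)),  # V' D^{1/2}
       lambda = e$values)
}

## transition probability matrix from a spectral decomposition
.pmat <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Empirical F3x4 codon frequencies
#'
#' Codon equilibrium frequencies from the nucleotide composition at each
#' codon position of an alignment (the codeml `CodonFreq = 2` convention),
#' renormalized over the 61 sense codons. A small floor (1e-6) keeps all
#' frequencies strictly positive so the spectral likelihood path is defined
#' even when a nucleotide is unobserved at some position.
#'
#' @param aln a codon [LineageAlignment-class].
#' @param floor minimum codon frequency before renormalization.
#' @return Length-61 numeric vector in [senseCodons()] order.
#' @export
codonFreqsF3x4 <- function(aln, floor = 1e-6) {
  stopifnot(is(aln, "LineageAlignment"), alphabet(aln) == "codon")
  m <- as.matrix(aln)
  cod <- m[!.is_missing(m, "codon")]
  if (!length(cod)) stop("no unambiguous codons in alignment")
  ntfreq <- sapply(1:3, function(p) {
    x <- substr(cod, p, p)
    tab <- table(factor(x, levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(x)
  })                                        # 4 x 3
  rownames(ntfreq) <- c("A", "C", "G", "T")
  f <- ntfreq[substr(.GC$codons, 1, 1), 1] *
       ntfreq[substr(.GC$codons, 2, 2), 2] *
       ntfreq[substr(.GC$codons, 3, 3), 3]
  f <- pmax(f, floor)
  f / sum(f)
}
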
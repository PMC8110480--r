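# Independent oracles: brute-force enumeration over internal-node state
# assignments, with transition matrices obtained by matrix exponential
# (Matrix::expm), i.e. neither the closed-form equal-rate P nor the
# spectral GY94 path used by the implementation.

# Equal-rate (Jukes-Cantor type) generator over nStates, 1 sub/site scaling
oracle_jc_pmat <- function(t, nStates) {
  Q <- matrix(1 / (nStates - 1), nStates, nStates)
  diag(Q) <- -1
  as.matrix(Matrix::expm(Q * t))
}

# Full enumeration of internal-state assignments for one column on a rooted
# tree. tipStates: integer states (1..nS) in tree tip order, NA = missing.
# Returns list(lik, post = internal nodes x states posterior matrix).
oracle_column <- function(tree, Pedge, tipStates, pi) {
  nTip <- ape::Ntip(tree)
  nNode <- nTip + tree$Nnode
  internals <- (nTip + 1L):nNode
  root <- internals[!internals %in% tree$edge[, 2]]
  nS <- length(pi)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nS)), length(internals))))
  total <- 0
  post <- matrix(0, length(internals), nS,
                 dimnames = list(as.character(internals), NULL))
  for (g in seq_len(nrow(grid))) {
    a <- grid[g, ]
    state <- c(tipStates, a)          # node id -> state
    lik <- pi[a[match(root, internals)]]
    for (e in seq_len(nrow(tree$edge))) {
      sc <- state[tree$edge[e, 2]]
      if (is.na(sc)) next             # missing tip sums out (rows of P sum 1)
      lik <- lik * Pedge[[e]][state[tree$edge[e, 1]], sc]
    }
    total <- total + lik
    for (k in seq_along(internals)) post[k, a[k]] <- post[k, a[k]] + lik
  }
  list(lik = total, post = post / total)
}

# GY94 transition matrix via matrix exponential of buildGY94 (no spectral
# shortcut); used for the direct-summation likelihood oracle.
oracle_gy94_pmat <- function(kappa, omega, pi, t) {
  as.matrix(Matrix::expm(buildGY94(kappa, omega, pi) * t))
}

# random small nucleotide alignment as a character matrix
random_nt_matrix <- function(taxa, nCol) {
  matrix(sample(c("A", "C", "G", "T"), length(taxa) * nCol, replace = TRUE),
         nrow = length(taxa), dimnames = list(taxa, NULL))
}

# alignment in which every column is invariant (shared random symbols)
invariant_aa_alignment <- function(taxa, nCol) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  row <- sample(aas, nCol, replace = TRUE)
  LineageAlignment(matrix(rep(row, each = length(taxa)), nrow = length(taxa),
                          dimnames = list(taxa, NULL)), "amino_acid")
}

# write a small FASTA from named sequences
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}
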
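## Universal genetic code tables and GY94 structural masks, built once at
## load. State space = the 61 sense codons; stops are structurally excluded.
.GC <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  code <- Biostrings::GENETIC_CODE
  codons <- sort(names(code)[code != "*"])        # 61, lexicographic
  aa <- unname(code[codons])
  n <- length(codons)
  splitc <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  ## pairwise structure: number of differing positions, transition flag
  ndiff <- matrix(0L, n, n)
  trans <- matrix(FALSE, n, n)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (p in 1:3) {
    d <- outer(splitc[, p], splitc[, p], "!=")
    ndiff <- ndiff + d
    tr <- outer(purine[splitc[, p]], purine[splitc[, p]], "==") & d
    trans <- trans | tr
  }
  neighbor <- ndiff == 1L
  nonsyn <- outer(aa, aa, "!=")
  .GC$code <- code
  .GC$codons <- codons
  .GC$aa <- aa
  .GC$n <- n
  .GC$neighbor <- neighbor
  .GC$transition <- trans & neighbor
  .GC$nonsyn <- nonsyn
  invisible(NULL)
}

#' The 61 sense codons of the universal genetic code
#'
#' Codon order (lexicographic) used by [buildGY94()] rows/columns and by the
#' codon-frequency vectors throughout the package.
#'
#' @return Character vector of length 61.
#' @export
senseCodons <- function() .GC$codons

#' Translate codon strings
#'
#' @param codons character vector of codon strings (e.g. `"ATG"`); gaps and
#'   ambiguous codons give `NA`.
#' @return Character vector of one-letter amino acids.
#' @export
translateCodons <- function(codons) {
  out <- unname(.GC$code[toupper(codons)])
  out[is.na(out)] <- NA_character_
  out
}
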
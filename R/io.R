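#' Read a FASTA multiple sequence alignment
#'
#' Reads an aligned FASTA file into a [LineageAlignment-class]. Input taxon
#' order is preserved. For `alphabet = "codon"` the nucleotide records are
#' split into in-frame codon columns; the total length must be divisible by
#' three, gaps must come in whole-codon units and internal stop codons are
#' rejected.
#'
#' @param path FASTA file of equal-length aligned records.
#' @param alphabet `"nucleotide"`, `"amino_acid"`, or `"codon"`.
#' @return A [LineageAlignment-class].
#' @export
readAlignment <- function(path, alphabet = c("nucleotide", "amino_acid",
                                             "codon")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no records in ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate taxon ids in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L)
    stop("ragged alignment in ", path, ": record '",
         nm[which(w != w[1])[1]], "' has length ", w[which(w != w[1])[1]],
         " (expected ", w[1], ")")
  chars <- toupper(as.character(ss))
  m <- do.call(rbind, strsplit(chars, "", fixed = TRUE))
  rownames(m) <- nm
  .check_symbols(m, alphabet, path)
  if (alphabet == "codon") m <- .to_codon_matrix(m)
  LineageAlignment(m, alphabet)
}

.check_symbols <- function(m, alphabet, path) {
  allowed <- switch(alphabet,
    nucleotide = c("A", "C", "G", "T", "-", .NT_AMBIG),
    amino_acid = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-", .AA_AMBIG),
    codon      = c("A", "C", "G", "T", "N", "-", "?"))
  bad <- matrix(!(m %in% allowed), nrow = nrow(m))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("symbol '%s' outside %s alphabet in record '%s' of %s",
                 m[bad][1], alphabet, rownames(m)[i[1]], path))
  }
}

.to_codon_matrix <- function(nt) {
  if (ncol(nt) %% 3L != 0L)
    stop("codon alignment length ", ncol(nt), " not divisible by 3")
  nc <- ncol(nt) %/% 3L
  cod <- matrix("", nrow = nrow(nt), ncol = nc, dimnames = list(rownames(nt)))
  for (j in seq_len(nc)) {
    cod[, j] <- paste0(nt[, 3L * j - 2L], nt[, 3L * j - 1L], nt[, 3L * j])
  }
  partial <- grepl("-", cod) & cod != "---"
  if (any(partial)) {
    i <- which(partial, arr.ind = TRUE)[1, ]
    stop(sprintf("gap not in whole-codon units at codon %d of '%s'",
                 i[2], rownames(cod)[i[1]]))
  }
  aa <- .GC$code[cod]
  if (any(aa == "*" & col(cod) < ncol(cod), na.rm = TRUE)) {
    i <- which(aa == "*" & col(cod) < ncol(cod), arr.ind = TRUE)[1, ]
    stop(sprintf("internal stop codon at codon %d of '%s'",
                 i[2], rownames(cod)[i[1]]))
  }
  ## a terminal stop is trimmed for everyone if all rows end in stop/gap
  last <- cod[, ncol(cod)]
  if (all(.GC$code[last] %in% "*" | last == "---")) cod <- cod[, -ncol(cod)]
  cod
}

#' Write a LineageAlignment to FASTA
#'
#' @param aln a [LineageAlignment-class].
#' @param path output file.
#' @export
writeAlignment <- function(aln, path) {
  m <- as.matrix(aln)
  seqs <- apply(m, 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' @param x a Newick string or a path to a Newick file.
#' @return An [ape::phylo] tree. Missing branch lengths default to 0 and set
#'   the attribute `missingLengths = TRUE` (with a warning).
#' @examples
#' tr <- readNewickTree("((a:1,b:1):1,c:2);")
#' @export
readNewickTree <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    paste(x, collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: could not read a tree from input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
    attr(tr, "missingLengths") <- TRUE
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths; defaulting to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
    attr(tr, "missingLengths") <- TRUE
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

#' Read MAF alignment blocks
#'
#' Parses the 's' lines of a MAF (multiple alignment format) file into
#' [AlignmentBlock-class] objects. Row coordinates are converted to
#' forward-strand 0-based half-open starts (for a `-` strand row at MAF
#' start `s` with ungapped size `l` on a source of length `L`, the forward
#' start is `L - s - l`). The taxon id of a row is the part of the MAF
#' source field before the first `.`; blocks with fewer than two rows are
#' skipped with a warning.
#'
#' @param path MAF file.
#' @param ref taxon id to anchor each block on; default: the first row.
#' @return A list of [AlignmentBlock-class].
#' @export
readMaf <- function(path, ref = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur <- list()
  flush <- function(cur, blocks) {
    if (length(cur) == 0L) return(blocks)
    if (length(cur) < 2L) {
      warning("skipping MAF block with fewer than 2 rows")
      return(blocks)
    }
    df <- do.call(rbind, lapply(cur, as.data.frame))
    alen <- nchar(df$text)
    if (length(unique(alen)) != 1L)
      stop("rows of unequal aligned length within a MAF block")
    m <- do.call(rbind, strsplit(toupper(df$text), "", fixed = TRUE))
    rownames(m) <- df$taxon
    info <- df[, c("src", "start", "size", "strand", "srcSize")]
    rownames(info) <- df$taxon
    r <- if (is.null(ref)) df$taxon[1] else ref
    blocks[[length(blocks) + 1L]] <-
      new("AlignmentBlock", aln = m, info = info, ref = r)
    blocks
  }
  for (ln in lines) {
    if (grepl("^a", ln)) {
      blocks <- flush(cur, blocks)
      cur <- list()
    } else if (grepl("^s\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7L) stop("malformed MAF 's' line: ", ln)
      start <- as.numeric(f[3]); size <- as.numeric(f[4])
      srcSize <- as.numeric(f[6])
      fwd <- if (f[5] == "-") srcSize - start - size else start
      cur[[length(cur) + 1L]] <- list(
        taxon = sub("\\..*$", "", f[2]), src = f[2], start = fwd,
        size = size, strand = f[5], srcSize = srcSize, text = f[7])
    }
  }
  flush(cur, blocks)
}

#' Write alignment blocks as MAF
#'
#' Inverse of [readMaf()]: forward-strand starts are converted back to the
#' MAF on-strand convention.
#'
#' @param blocks list of [AlignmentBlock-class].
#' @param path output file.
#' @export
writeMaf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a", con)
    for (i in seq_len(nrow(b@aln))) {
      inf <- b@info[i, ]
      s <- if (inf$strand == "-") inf$srcSize - inf$start - inf$size
           else inf$start
      writeLines(sprintf("s %s %d %d %s %d %s", inf$src, as.integer(s),
                         as.integer(inf$size), inf$strand,
                         as.integer(inf$srcSize),
                         paste(b@aln[i, ], collapse = "")), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read genomic intervals from BED or GFF
#'
#' BED input is 0-based half-open, GFF 1-based closed; both are returned as
#' a `GRanges` (1-based closed internally; the shift happens only here, at
#' the I/O boundary).
#'
#' @param path input file.
#' @param dialect `"BED"` or `"GFF"`; default guessed from the extension.
#' @return A [GenomicRanges::GRanges].
#' @export
readIntervals <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "GFF" else "BED"
  }
  dialect <- match.arg(toupper(dialect), c("BED", "GFF"))
  gr <- if (dialect == "BED") .read_bed(path) else
    rtracklayer::import(path, format = "gff")
  if (any(GenomicRanges::start(gr) < 1))
    stop("negative or zero coordinates in ", path)
  gr
}

## rtracklayer's BED reader is used for well-formed files, but we validate
## start < end ourselves first to give the contract's error.
.read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#", quote = "")
  if (ncol(df) < 3L) stop("BED needs >= 3 columns in ", path)
  if (any(df[[2]] < 0)) stop("negative coordinates in ", path)
  if (any(df[[2]] >= df[[3]]))
    stop("start >= end in ", path, " (line ",
         which(df[[2]] >= df[[3]])[1], ")")
  rtracklayer::import(path, format = "bed")
}

#' Write intervals as BED
#'
#' Emits 0-based half-open BED lines from a 1-based closed `GRanges`, with
#' `name` and `score` metadata columns when present.
#'
#' @param gr a `GRanges`.
#' @param path output file.
#' @export
writeBed <- function(gr, path) {
  ## keep only BED-representable metadata; GFF imports carry extra columns
  mc <- S4Vectors::mcols(gr)
  clean <- GenomicRanges::granges(gr)
  if (!is.null(mc$name) && !anyNA(mc$name)) clean$name <- mc$name
  if (!is.null(mc$score) && !anyNA(mc$score))
    clean$score <- as.numeric(mc$score)
  rtracklayer::export(clean, path, format = "bed")
  invisible(path)
}
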
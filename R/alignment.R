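## Codon alignments: integer codon states per taxon x site.

#' Build a codon alignment
#'
#' Converts nucleotide sequences into an integer matrix of codon states
#' (taxa x codon sites) indexing `genetic_code()$codons`.  Codons
#' containing gaps (`-`) or ambiguous bases (`N`) are masked as `NA` and
#' treated as missing data in all likelihood computations.  In-frame stop
#' codons are an error.
#'
#' @param x named character vector of equal-length nucleotide sequences
#'   (length divisible by 3), or a character matrix of codons
#'   (taxa x sites, with rownames), or an `ape::DNAbin` alignment.
#' @return object of class `codon_alignment`: integer matrix with taxa as
#'   rows (rownames = labels) and codon sites as columns.
#' @export
codon_alignment <- function(x) {
  if (inherits(x, "DNAbin"))
    x <- vapply(as.character(as.list(x)), paste, character(1), collapse = "")
  if (is.matrix(x)) {
    cods <- toupper(x)
  } else {
    x <- toupper(unlist(x))
    if (is.null(names(x))) stop("sequences must be named")
    n <- unique(nchar(x))
    if (length(n) != 1) stop("sequences must have equal length")
    if (n %% 3 != 0) stop("sequence length must be divisible by 3")
    cods <- t(vapply(x, function(s)
      substring(s, seq(1, n, 3), seq(3, n, 3)), character(n / 3)))
  }
  gc <- genetic_code()
  idx <- match(cods, gc$codons)
  bad <- is.na(idx) & !grepl("[-N]", cods)
  if (any(cods[bad] %in% gc$stops))
    stop("in-frame stop codon in alignment")
  out <- matrix(idx, nrow = nrow(cods), dimnames = dimnames(cods))
  class(out) <- c("codon_alignment", "matrix")
  out
}

#' Drop gappy alignment columns
#'
#' Removes codon sites where the fraction of missing states (gaps or
#' masked codons) across taxa exceeds `max_gap`; applied before profile
#' estimation and opportunity counting.
#'
#' @param aln a [codon_alignment()].
#' @param max_gap maximum tolerated fraction of missing taxa per site.
#' @return the filtered alignment, with attribute `kept` giving the
#'   retained site indices.
#' @export
filter_gap_sites <- function(aln, max_gap = 0.1) {
  frac <- colMeans(is.na(unclass(aln)))
  keep <- frac <= max_gap
  out <- aln[, keep, drop = FALSE]
  class(out) <- c("codon_alignment", "matrix")
  attr(out, "kept") <- which(keep)
  out
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", nrow(x), "taxa x", ncol(x), "sites;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(unclass(x)))))
  invisible(x)
}
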
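## Standard genetic code tables and codon bookkeeping.
##
## Everything downstream (rate matrices, opportunity counting, simulation)
## indexes codons as integers 1..61 over the sense codons sorted
## alphabetically, and amino acids as integers 1..20 over the one-letter
## codes sorted alphabetically (ACDEFGHIKLMNPQRSTVWY).

#' Nucleotide and amino-acid alphabets
#'
#' The fixed orderings used throughout the package: bases `A C G T` and
#' the 20 amino-acid one-letter codes in alphabetical order.
#'
#' @format Character vectors of length 4 (`BASES`) and 20 (`AA_LETTERS`).
#' @export
BASES <- c("A", "C", "G", "T")

#' @rdname BASES
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.code_cache <- new.env(parent = emptyenv())

.build_genetic_code <- function() {
  ## NCBI standard code, codon order T/C/A/G nested (pos 1 slowest)
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  tcag <- c("T", "C", "A", "G")
  codons64 <- as.vector(t(outer(
    as.vector(t(outer(tcag, tcag, paste0))), tcag, paste0)))
  names(aas) <- codons64
  ord <- order(codons64)
  codons64 <- codons64[ord]
  aas <- aas[ord]

  stops <- codons64[aas == "*"]
  sense <- codons64[aas != "*"]
  aa <- unname(aas[sense])
  stopifnot(length(sense) == 61L, length(stops) == 3L)

  codon_base <- t(vapply(strsplit(sense, ""),
                         function(x) match(x, BASES), integer(3)))
  aa_idx <- match(aa, AA_LETTERS)

  ## all 9 single-nucleotide changes per sense codon
  nb <- vector("list", 61L)
  for (a in seq_len(61L)) {
    rows <- vector("list", 9L)
    k <- 1L
    for (pos in 1:3) {
      fb <- codon_base[a, pos]
      for (tb in seq_len(4L)[-fb]) {
        tri <- codon_base[a, ]
        tri[pos] <- tb
        target <- paste(BASES[tri], collapse = "")
        b <- match(target, sense)       # NA if stop codon
        rows[[k]] <- data.frame(
          from = a, pos = pos, from_base = fb, to_base = tb,
          to = if (is.na(b)) NA_integer_ else b,
          stop_gain = is.na(b),
          syn = if (is.na(b)) NA else aa_idx[a] == aa_idx[b],
          aa_from = aa_idx[a],
          aa_to = if (is.na(b)) NA_integer_ else aa_idx[b])
        k <- k + 1L
      }
    }
    nb[[a]] <- do.call(rbind, rows)
  }
  neighbors <- do.call(rbind, nb)
  rownames(neighbors) <- NULL

  list(codons = sense, aa = aa, aa_index = aa_idx, stops = stops,
       codon_base = codon_base, neighbors = neighbors)
}

#' Standard genetic code tables
#'
#' Returns the codon bookkeeping used throughout the package: the 61 sense
#' codons of the standard genetic code (alphabetical order), their amino
#' acids, the three stop codons, and the table of all single-nucleotide
#' codon changes (9 per codon, 549 rows) with stop-gain flags.
#'
#' @return A list with components `codons` (character, 61), `aa` (one-letter
#'   amino acid per codon), `aa_index` (integer 1-20 into the alphabetical
#'   amino-acid order), `stops`, `codon_base` (61 x 3 integer matrix of base
#'   indices, A=1, C=2, G=3, T=4), and `neighbors` (data frame of all
#'   single-nucleotide changes with columns `from`, `pos`, `from_base`,
#'   `to_base`, `to`, `stop_gain`, `syn`, `aa_from`, `aa_to`).
#' @export
#' @examples
#' gc <- genetic_code()
#' gc$codons[gc$aa == "M"]   # "ATG"
genetic_code <- function() {
  if (is.null(.code_cache$code))
    .code_cache$code <- .build_genetic_code()
  .code_cache$code
}

#' Convert codon strings to internal indices and back
#'
#' @param x character vector of codons (e.g. `"ATG"`); codons containing
#'   anything outside ACGT (e.g. `N`) or stop codons give `NA`.
#' @return `codon_index`: integer vector of indices into
#'   `genetic_code()$codons`; `index_codon`: character vector.
#' @export
codon_index <- function(x) match(toupper(x), genetic_code()$codons)

#' @rdname codon_index
#' @param i integer vector of codon indices (1-61).
#' @export
index_codon <- function(i) genetic_code()$codons[i]
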
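## Terminal-branch divergence: ancestral reconstruction at the base of the
## branch, substitution mapping, class-conditional dN/dS and the
## inflation statistic delta(dN/dS).

#' Reconstruct the exome at the base of the terminal branch
#'
#' Joint maximum-likelihood (max-product) ancestral codon states at the
#' parent node of the focal tip, under the neutral (all-fitnesses-equal)
#' codon model on the 4-taxon tree.  Site-rate variation is not modeled.
#'
#' @param aln a [codon_alignment()] containing the focal taxon and three
#'   outgroups.
#' @param tree rooted 4-taxon `ape::phylo`.
#' @param model a reversible [mutation_model()].
#' @param focal focal tip label.
#' @return integer vector of codon states at the base of the focal
#'   terminal branch (`NA` where no data informs the site).
#' @export
reconstruct_branch_base <- function(aln, tree, model, focal = "focal") {
  td <- .tree_data(tree)
  if (!focal %in% td$labels) stop("missing taxon: ", focal)
  states <- .aln_states(aln, td$labels)     # -1 = missing
  m <- codon_rate_matrix(model, rep(0, 20))
  pi <- stationary_distribution(m)
  Plist <- lapply(td$blen, function(t) {
    e <- eigen(diag(sqrt(pi)) %*% m$Q %*% diag(1 / sqrt(pi)),
               symmetric = TRUE)
    P <- diag(1 / sqrt(pi)) %*% e$vectors %*% diag(exp(e$values * t)) %*%
      t(e$vectors) %*% diag(sqrt(pi))
    pmax(P, 1e-300)
  })
  focal_tip <- which(td$labels == focal)
  target <- td$edges[td$edges[, 2] == focal_tip - 1L, 1] + 1L  # parent node

  key <- apply(states, 2, paste, collapse = ",")
  uk <- which(!duplicated(key))
  idx <- match(key, key[uk])
  anc_u <- integer(length(uk))
  for (ui in seq_along(uk)) {
    s <- states[, uk[ui]]
    M <- matrix(1, 61, td$nnode)            # max-product partials
    for (i in seq_len(td$ntip)) if (s[i] >= 0) {
      M[, i] <- 0
      M[s[i] + 1L, i] <- 1
    }
    arg <- vector("list", nrow(td$edges))
    for (e in seq_len(nrow(td$edges))) {
      par <- td$edges[e, 1] + 1L
      ch <- td$edges[e, 2] + 1L
      W <- Plist[[e]] * rep(M[, ch], each = 61)
      am <- max.col(W, "first")
      arg[[e]] <- am
      M[, par] <- M[, par] * W[cbind(1:61, am)]
      mx <- max(M[, par])
      if (mx > 0) M[, par] <- M[, par] / mx
    }
    root <- td$edges[nrow(td$edges), 1] + 1L
    best <- integer(td$nnode)
    best[root] <- which.max(pi * M[, root])
    for (e in rev(seq_len(nrow(td$edges)))) {  # preorder backtrack
      par <- td$edges[e, 1] + 1L
      ch <- td$edges[e, 2] + 1L
      best[ch] <- arg[[e]][best[par]]
    }
    anc_u[ui] <- best[target]
  }
  anc <- anc_u[idx]
  allmiss <- colSums(states >= 0) == 0
  anc[allmiss] <- NA_integer_
  anc
}

#' Map substitutions along the terminal branch
#'
#' Compares the base-of-branch exome with the population's ancestral
#' exome.  Sites segregating in the population are skipped; single
#' nucleotide codon differences are classified as synonymous or by their
#' \eqn{S_0} class with the base-of-branch codon as source (direction
#' matters); multi-nucleotide differences are excluded from counts (and
#' their sites reported, so opportunities can be adjusted).
#'
#' @param base_exome integer codon states at the base of the branch.
#' @param anc_exome integer codon states of the population ancestral
#'   exome.
#' @param profiles L x 20 fitness matrix.
#' @param segregating_sites 1-based sites carrying SNPs (skipped).
#' @return list with `D_syn`, `D_x` (named D0/N0/B0 counts),
#'   `substitutions` (data frame: `site`, `from`, `to`, `S0`, `class`),
#'   `multihit_sites`, and `skipped_sites`.
#' @export
map_substitutions <- function(base_exome, anc_exome, profiles,
                              segregating_sites = integer(0)) {
  if (length(base_exome) != length(anc_exome))
    stop("exomes must be aligned site-for-site")
  gc <- genetic_code()
  L <- length(base_exome)
  usable <- !is.na(base_exome) & !is.na(anc_exome)
  skip <- seq_len(L) %in% segregating_sites
  diff <- usable & !skip & base_exome != anc_exome
  sites <- which(diff)
  ndiff <- rowSums(gc$codon_base[base_exome[sites], , drop = FALSE] !=
                     gc$codon_base[anc_exome[sites], , drop = FALSE])
  multi <- sites[ndiff > 1]
  one <- sites[ndiff == 1]
  a <- base_exome[one]
  b <- anc_exome[one]
  syn <- gc$aa_index[a] == gc$aa_index[b]
  S0 <- ifelse(syn, 0,
               profiles[cbind(one, gc$aa_index[b])] -
                 profiles[cbind(one, gc$aa_index[a])])
  cls <- classify_s0(S0, syn)
  D_x <- c(D0 = sum(cls == "D0"), N0 = sum(cls == "N0"),
           B0 = sum(cls == "B0"))
  list(D_syn = sum(cls == "SYN"), D_x = D_x,
       substitutions = data.frame(site = one, from = a, to = b,
                                  S0 = S0, class = cls),
       multihit_sites = multi,
       skipped_sites = which(skip))
}

#' Class-conditional divergence rates
#'
#' \eqn{d_N(x) = D(x)/L(x)} per selection class and
#' \eqn{d_S = D_{syn}/L_{syn}}, with the per-class ratios
#' \eqn{d_N(x)/d_S}.
#'
#' @param counts result of [map_substitutions()] (or a list with `D_syn`
#'   and `D_x`).
#' @param opportunities an `opportunity_table`.
#' @return object of class `divergence_table`: data frame with one row
#'   per class (D, L, dN, dN/dS) plus attributes `dS` and `D_syn`.
#' @export
dnds_by_class <- function(counts, opportunities) {
  op <- opportunities
  if (op$L_syn <= 0) stop("synonymous opportunity must be positive")
  dS <- counts$D_syn / op$L_syn
  dN <- ifelse(op$L_x > 0, counts$D_x / op$L_x, 0)
  if (any(op$L_x <= 0 & counts$D_x > 0))
    stop("substitutions observed in a class with zero opportunity")
  tab <- data.frame(class = names(counts$D_x),
                    D = as.numeric(counts$D_x),
                    L = as.numeric(op$L_x),
                    dN = as.numeric(dN),
                    dNdS = if (dS > 0) as.numeric(dN / dS) else NA_real_)
  if (counts$D_syn == 0)
    warning("no synonymous substitutions: dN/dS undefined")
  attr(tab, "dS") <- dS
  attr(tab, "D_syn") <- counts$D_syn
  attr(tab, "L_syn") <- op$L_syn
  class(tab) <- c("divergence_table", "data.frame")
  tab
}

#' Inflation of dN/dS by beneficial non-adaptive substitutions
#'
#' \eqn{\delta = (d_N - d_N(S_0 < 1)) / d_N}, the relative drop in the
#' non-synonymous rate when B0 substitutions are removed from the counts
#' (the opportunity denominator is shared, so \eqn{\delta} is also the B0
#' share of non-synonymous substitutions).  Identical whether computed on
#' \eqn{d_N/d_S} ratios or on \eqn{d_N} alone, since \eqn{d_S} cancels.
#'
#' @param tab a [dnds_by_class()] table.
#' @return the fraction \eqn{\delta} (scalar).
#' @export
delta_dnds <- function(tab) {
  stopifnot(inherits(tab, "divergence_table"))
  D <- sum(tab$D)
  L <- sum(tab$L)
  if (D == 0) stop("no non-synonymous substitutions: delta undefined")
  dN <- D / L
  dN_nb <- sum(tab$D[tab$class != "B0"]) / L
  (dN - dN_nb) / dN
}

#' @export
print.divergence_table <- function(x, ...) {
  cat(sprintf("Divergence: D_syn = %d, dS = %.3g\n",
              attr(x, "D_syn"), attr(x, "dS")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Invert the fixation-rate relation
#'
#' Solves \eqn{\omega(S) = S/(1 - e^{-S}) = \omega} for the scaled
#' selection coefficient \eqn{S} by bracketed root finding
#' ([fixation_rate()] is strictly increasing).  A class of substitutions
#' fixing at `omega` times the neutral rate behaves as if it had scaled
#' coefficient `invert_omega(omega)`.
#'
#' @param omega observed relative fixation rate (> 0).
#' @param tol root-finding tolerance.
#' @return scaled selection coefficient.
#' @export
#' @examples
#' invert_omega(1.17)   # ~0.32
#' invert_omega(1.75)   # ~1.24
invert_omega <- function(omega, tol = 1e-10) {
  if (any(omega <= 0)) stop("omega must be positive")
  vapply(omega, function(w) {
    if (abs(w - 1) < 1e-12) return(0)
    lo <- -1; hi <- 1
    while (fixation_rate(lo) > w) lo <- lo * 2
    while (fixation_rate(hi) < w) hi <- hi * 2
    uniroot(function(S) fixation_rate(S) - w, c(lo, hi), tol = tol)$root
  }, numeric(1))
}
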
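## Population-scale pipeline: polarization against outgroups, ancestral
## exome reconstruction, mutational opportunities, class-stratified SFS,
## and diversity summaries.

## 4x4 transition matrices for a nucleotide model
.nuc_P <- function(model, t) {
  e <- eigen(diag(sqrt(model$pi)) %*% model$rates %*%
               diag(1 / sqrt(model$pi)), symmetric = TRUE)
  P <- diag(1 / sqrt(model$pi)) %*% e$vectors %*%
    diag(exp(e$values * t)) %*% t(e$vectors) %*% diag(sqrt(model$pi))
  pmax(P, 0)
}

## nucleotide pruning vectorized over site patterns
## states: ntip x npat matrix of base indices (NA = missing)
.prune_nuc_patterns <- function(tree, model, states) {
  td <- .tree_data(tree)
  npat <- ncol(states)
  part <- array(1, c(4, npat, td$nnode))
  for (i in seq_len(td$ntip)) {
    s <- states[td$labels[i], ]
    known <- !is.na(s)
    part[, known, i] <- 0
    part[cbind(s[known], which(known), i)] <- 1
  }
  logscale <- numeric(npat)
  for (e in seq_len(nrow(td$edges))) {
    P <- .nuc_P(model, td$blen[e])
    par <- td$edges[e, 1] + 1L
    ch <- td$edges[e, 2] + 1L
    part[, , par] <- part[, , par] * (P %*% part[, , ch])
    mx <- apply(part[, , par, drop = FALSE], 2, max)
    mx[mx <= 0] <- 1
    part[, , par] <- sweep(part[, , par, drop = FALSE], 2, mx, "/")[, , 1]
    logscale <- logscale + log(mx)
  }
  root <- td$edges[nrow(td$edges), 1] + 1L
  pr <- array(part[, , root, drop = FALSE], c(4, npat))
  log(colSums(model$pi * pr)) + logscale
}

#' Polarize SNPs against three outgroups
#'
#' For each SNP, the posterior probability that each of its two alleles is
#' ancestral is computed by nucleotide-level pruning over the 4-taxon tree
#' (focal + three outgroups): the focal terminal branch is contracted to
#' zero, the candidate allele is placed at the focal tip, and the two
#' candidate likelihoods are normalized.  SNPs whose best allele has
#' posterior below `threshold` are dropped, as are SNPs with no outgroup
#' information.
#'
#' @param alleles 2-column character matrix of the SNP's two nucleotides
#'   (first column = putative ancestral, e.g. the reference).
#' @param outgroups 3-column character matrix of outgroup bases at the
#'   SNP position (`N`/`-` = missing).
#' @param tree rooted 4-taxon `ape::phylo` containing `focal` and the
#'   outgroup tips (same labels as `colnames(outgroups)`, or taken in
#'   order).
#' @param model a [mutation_model()] (neutral nucleotide model).
#' @param focal focal tip label.
#' @param threshold minimum posterior for the inferred ancestral allele
#'   (default 0.99).
#' @param counts optional 2-column matrix of ingroup allele counts
#'   (same column order as `alleles`).  When given, each candidate
#'   polarization is additionally weighted by the neutral unfolded SFS
#'   shape (a derived allele at count i has prior weight 1/i), which is
#'   what frequency-aware polarizers exploit.
#' @return data frame: `ancestral` (inferred allele or `NA`),
#'   `prob` (posterior of the inferred ancestral state), `kept`, `reason`
#'   (`"ok"`, `"low_probability"`, `"no_outgroup"`).
#' @export
polarize <- function(alleles, outgroups, tree, model, focal = "focal",
                     threshold = 0.99, counts = NULL) {
  alleles <- as.matrix(alleles)
  outgroups <- as.matrix(outgroups)
  stopifnot(ncol(alleles) == 2, ncol(outgroups) == 3,
            nrow(alleles) == nrow(outgroups))
  outs <- setdiff(tree$tip.label, focal)
  if (is.null(colnames(outgroups))) colnames(outgroups) <- outs
  a1 <- match(toupper(alleles[, 1]), BASES)
  a2 <- match(toupper(alleles[, 2]), BASES)
  ob <- matrix(match(toupper(outgroups), BASES), nrow(outgroups))
  colnames(ob) <- colnames(outgroups)

  tree0 <- tree
  tree0$edge.length[tree0$edge[, 2] ==
                      which(tree0$tip.label == focal)] <- 0
  ## dedupe (allele, outgroup states) patterns
  key <- paste(a1, a2, ob[, 1], ob[, 2], ob[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  w1 <- which(uk)
  states <- function(foc) {
    m <- rbind(foc, t(ob[w1, outs, drop = FALSE]))
    rownames(m) <- c(focal, outs)
    m
  }
  ll1 <- .prune_nuc_patterns(tree0, model, states(a1[w1]))
  ll2 <- .prune_nuc_patterns(tree0, model, states(a2[w1]))
  d <- (ll2 - ll1)[idx]
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(ncol(counts) == 2, nrow(counts) == nrow(alleles))
    ## anc = allele 1 => allele 2 is derived at count c2: weight 1/c2
    d <- d + log(counts[, 2]) - log(counts[, 1])
  }
  p1 <- 1 / (1 + exp(d))
  no_out <- rowSums(!is.na(ob)) == 0
  anc_is_1 <- p1 >= 0.5
  prob <- pmax(p1, 1 - p1)
  kept <- !no_out & prob >= threshold
  reason <- ifelse(no_out, "no_outgroup",
                   ifelse(prob < threshold, "low_probability", "ok"))
  data.frame(ancestral = ifelse(kept, BASES[ifelse(anc_is_1, a1, a2)],
                                NA_character_),
             prob = prob, kept = kept, reason = reason)
}

#' Reconstruct the ancestral exome of a population
#'
#' Replaces the reference codon by the inferred ancestral allele at every
#' polarized SNP site where the reference carries the derived state.
#'
#' @param reference integer codon states of the species reference exome.
#' @param sites 1-based codon site of each polarized SNP.
#' @param anc_codon,der_codon codon states (strings or indices) of the
#'   ancestral and derived alleles at each SNP.
#' @return integer codon vector of the ancestral exome.
#' @export
reconstruct_ancestral_exome <- function(reference, sites, anc_codon,
                                        der_codon) {
  if (is.character(anc_codon)) anc_codon <- codon_index(anc_codon)
  if (is.character(der_codon)) der_codon <- codon_index(der_codon)
  stopifnot(length(sites) == length(anc_codon),
            length(sites) == length(der_codon),
            all(sites >= 1), all(sites <= length(reference)))
  dup <- duplicated(sites)
  if (any(dup)) {
    conflict <- tapply(anc_codon, sites, function(x) length(unique(x)) > 1)
    if (any(conflict)) stop("conflicting ancestral states at site(s) ",
                            paste(names(conflict)[conflict], collapse = ", "))
  }
  out <- reference
  hit <- out[sites] == der_codon
  out[sites[hit]] <- anc_codon[hit]
  out
}

#' Mutational opportunities by selection class
#'
#' Enumerates all single-nucleotide changes away from the ancestral exome
#' (9 per codon site), drops stop-gaining changes, and accumulates
#' mutation-rate weights \eqn{\mu_{a\to b}} into the synonymous total
#' \eqn{\mu_{syn}} and per-class totals \eqn{\mu(x)} according to the
#' change's \eqn{S_0} class on the fitness landscape.  Opportunities are
#' \eqn{L_{syn} = L_{tot}\,\mu_{syn}/\mu_{tot}} and
#' \eqn{L(x) = L_{tot}\,\mu(x)/\mu_{tot}}, with
#' \eqn{L_{tot}} the number of nucleotide sites (3 per codon), and
#' \eqn{P[x] = L(x)/\sum_y L(y)}.
#'
#' @param exome integer codon states of the ancestral exome.
#' @param model a [mutation_model()].
#' @param profiles L x 20 fitness matrix covering every exome site.
#' @param cpg_flags optional logical per-site flags; flagged sites get
#'   `cpg_multiplier` on their rates, or are excluded entirely when
#'   `exclude_cpg = TRUE` (the filtering control).
#' @param cpg_multiplier rate multiplier at flagged sites.
#' @param exclude_cpg drop flagged sites from all totals.
#' @param chunk sites per chunk.
#' @return object of class `opportunity_table`: list with `L_tot`,
#'   `mu_tot`, `mu_syn`, `mu_x`, `L_syn`, `L_x`, `P_x` (classes D0, N0,
#'   B0).
#' @export
mutational_opportunities <- function(exome, model, profiles,
                                     cpg_flags = NULL, cpg_multiplier = 1,
                                     exclude_cpg = FALSE,
                                     chunk = 100000L) {
  L <- length(exome)
  stopifnot(nrow(profiles) == L)
  if (is.null(cpg_flags)) cpg_flags <- rep(FALSE, L)
  keep <- if (exclude_cpg) !cpg_flags else rep(TRUE, L)
  mult <- ifelse(cpg_flags & !exclude_cpg, cpg_multiplier, 1)
  tb <- .sim_tables(model)
  mu_syn <- 0
  mu_x <- c(D0 = 0, N0 = 0, B0 = 0)
  sites_all <- which(keep)
  for (lo in seq(1, length(sites_all), chunk)) {
    sites <- sites_all[lo:min(lo + chunk - 1, length(sites_all))]
    cur <- exome[sites]
    to <- tb$to[cur, , drop = FALSE]
    valid <- as.vector(to > 0L)
    rs <- rep(sites, 9)
    aaf <- as.vector(tb$aaf[cur, , drop = FALSE])
    aat <- as.vector(tb$aat[cur, , drop = FALSE])
    syn <- aaf == aat
    w <- as.vector(tb$mu[cur, , drop = FALSE]) * rep(mult[sites], 9)
    S0 <- ifelse(syn, 0, profiles[cbind(rs, aat)] - profiles[cbind(rs, aaf)])
    cls <- classify_s0(S0, syn)
    ok <- valid
    mu_syn <- mu_syn + sum(w[ok & syn])
    for (x in names(mu_x))
      mu_x[x] <- mu_x[x] + sum(w[ok & cls == x])
  }
  mu_tot <- mu_syn + sum(mu_x)
  L_tot <- 3 * length(sites_all)
  L_syn <- L_tot * mu_syn / mu_tot
  L_x <- L_tot * mu_x / mu_tot
  structure(list(L_tot = L_tot, mu_tot = mu_tot, mu_syn = mu_syn,
                 mu_x = mu_x, L_syn = L_syn, L_x = L_x,
                 P_x = L_x / sum(L_x)),
            class = "opportunity_table")
}

#' @export
print.opportunity_table <- function(x, ...) {
  cat("Mutational opportunities (L_tot =", x$L_tot, "nucleotide sites)\n")
  m <- rbind(`L` = c(syn = x$L_syn, x$L_x),
             `P[x]` = c(NA, x$P_x))
  print(round(m, 4))
  invisible(x)
}

#' Classify SNPs by their phylogenetic selection coefficient
#'
#' Adds `S0` and `class` columns: \eqn{S_0} is the fitness difference of
#' the ancestral-to-derived amino-acid change at the SNP's site.
#'
#' @param snps data frame with columns `site` (0-based codon site),
#'   `ancestral_codon`, `derived_codon`.
#' @param profiles L x 20 fitness matrix.
#' @return `snps` with `S0` and `class` appended.
#' @export
classify_snps <- function(snps, profiles) {
  gc <- genetic_code()
  a <- codon_index(snps$ancestral_codon)
  b <- codon_index(snps$derived_codon)
  if (anyNA(a) || anyNA(b)) stop("SNP codons must be sense codons")
  site <- snps$site + 1L
  stopifnot(all(site >= 1), all(site <= nrow(profiles)))
  syn <- gc$aa_index[a] == gc$aa_index[b]
  S0 <- ifelse(syn, 0,
               profiles[cbind(site, gc$aa_index[b])] -
                 profiles[cbind(site, gc$aa_index[a])])
  snps$S0 <- S0
  snps$class <- classify_s0(S0, syn)
  snps
}

#' Site-frequency spectrum container
#'
#' @param xi counts of SNPs with derived-allele count 1..n-1.
#' @param n sample size (chromosomes).
#' @param L mutational opportunity (sites) of the SFS's class; zero is
#'   tolerated only for an empty spectrum (a class with no opportunity).
#' @param class class label (`SYN`, `D0`, `N0`, `B0`).
#' @return object of class `sfs`.
#' @export
sfs <- function(xi, n, L, class = "SYN") {
  stopifnot(length(xi) == n - 1, all(xi >= 0), L >= 0)
  if (L == 0 && sum(xi) > 0) stop("SNPs observed in a class with zero opportunity")
  structure(list(xi = as.numeric(xi), n = as.integer(n), L = L,
                 class = class), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("SFS [%s]: n = %d, L = %.1f, %g segregating sites\n",
              x$class, x$n, x$L, sum(x$xi)))
  invisible(x)
}

#' Build class-stratified site-frequency spectra
#'
#' Aggregates classified SNPs into one unfolded SFS per selection class
#' plus the synonymous SFS, with opportunities from the
#' [mutational_opportunities()] table.  With `exclude_cpg = TRUE` both the
#' counts and the opportunities must come from the CpG-filtered view
#' (pass the matching table).
#'
#' @param snps classified SNP table (see [classify_snps()]); all rows must
#'   share the same `n`.
#' @param opportunities an `opportunity_table`.
#' @param exclude_cpg drop SNPs with `cpg_flag`.
#' @return named list of [sfs()] objects: `SYN`, `D0`, `N0`, `B0`.
#' @export
build_sfs <- function(snps, opportunities, exclude_cpg = FALSE) {
  if (exclude_cpg && "cpg_flag" %in% names(snps))
    snps <- snps[!snps$cpg_flag, , drop = FALSE]
  n <- unique(snps$n)
  if (length(n) > 1) stop("SNPs have mixed sample sizes; subsample first")
  if (length(n) == 0) stop("empty SNP table: sample size unknown")
  out <- list()
  for (cl in c("SYN", "D0", "N0", "B0")) {
    rows <- snps$class == cl
    xi <- tabulate(snps$derived_count[rows], n - 1)
    Lc <- if (cl == "SYN") opportunities$L_syn else opportunities$L_x[[cl]]
    out[[cl]] <- sfs(xi, n, Lc, cl)
  }
  out
}

#' Subsample an SFS to a smaller number of chromosomes
#'
#' Projects counts from sample size n down to m by hypergeometric
#' sampling without replacement; outcomes that become monomorphic (0 or
#' m derived copies) are dropped.  The default deterministic variant
#' distributes each count by the exact hypergeometric probabilities; the
#' sampling variant draws.
#'
#' @param x an [sfs()].
#' @param m target number of chromosomes (2 <= m <= n).
#' @param method `"expected"` (deterministic, default) or `"sample"`.
#' @return an [sfs()] at sample size `m`.
#' @export
subsample_sfs <- function(x, m, method = c("expected", "sample")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "sfs"))
  if (m < 2) stop("m must be at least 2")
  if (m > x$n) stop("m exceeds the sample size")
  if (m == x$n) return(x)
  n <- x$n
  if (method == "expected") {
    xi2 <- numeric(m - 1)
    for (i in seq_len(n - 1)) {
      if (x$xi[i] == 0) next
      p <- dhyper(seq_len(m - 1), i, n - i, m)
      xi2 <- xi2 + x$xi[i] * p
    }
  } else {
    xi2 <- numeric(m - 1)
    for (i in seq_len(n - 1)) {
      if (x$xi[i] == 0) next
      d <- stats::rhyper(x$xi[i], i, n - i, m)
      d <- d[d > 0 & d < m]
      if (length(d)) xi2 <- xi2 + tabulate(d, m - 1)
    }
  }
  sfs(xi2, m, x$L, x$class)
}

#' Watterson's diversity estimator and effective population size
#'
#' \eqn{\theta_S = \sum_i \xi_i / (a_{n-1} L)} from the synonymous SFS,
#' with \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i}; and \eqn{N_e = \theta_S/(4u)}.
#'
#' @param x a synonymous [sfs()].
#' @return `watterson_theta`: per-site diversity estimate.
#' @export
#' @examples
#' watterson_theta(sfs(c(5), n = 2, L = 1000))   # 0.005
watterson_theta <- function(x) {
  stopifnot(inherits(x, "sfs"), x$n >= 2)
  if (x$L <= 0) stop("L must be positive")
  sum(x$xi) / (sum(1 / seq_len(x$n - 1)) * x$L)
}

#' @rdname watterson_theta
#' @param theta per-site diversity.
#' @param u mutation rate per site per generation.
#' @export
ne_estimate <- function(theta, u) theta / (4 * u)
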
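## Phylogenetic likelihood: pruning, branch-scale fitting, and per-site
## penalized ML estimation of amino-acid fitness profiles.

## Postorder edge bookkeeping for a rooted ape::phylo tree.
.tree_data <- function(tree, tip_order = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree <- stats::reorder(tree, "postorder")
  list(edges = tree$edge - 1L,          # 0-based for the kernel
       blen = tree$edge.length,
       ntip = length(tree$tip.label),
       nnode = length(tree$tip.label) + tree$Nnode,
       labels = tree$tip.label)
}

## states: named codon strings/indices -> integer vector in tree tip order
## (-1 = missing) for the kernel.
.states_for_tree <- function(states, labels) {
  if (is.character(states)) states <- codon_index(states) |>
      stats::setNames(names(states))
  if (is.null(names(states))) stop("states must be named by tip label")
  miss <- setdiff(labels, names(states))
  if (length(miss)) stop("unknown leaf label(s): no state for ",
                         paste(miss, collapse = ", "))
  s <- states[labels]
  s[is.na(s)] <- 0L
  as.integer(s) - 1L                    # NA -> -1 (missing)
}

#' Log-likelihood of one alignment column under a codon model
#'
#' Felsenstein pruning over a rooted tree with the site's 61 x 61
#' generator; the root is weighted by the model's stationary distribution
#' (mutation-selection balance).  Gaps/ambiguities (`NA` states) are
#' missing data.
#'
#' @param tree rooted `ape::phylo` with branch lengths in expected
#'   substitutions per site.
#' @param m a [codon_rate_matrix()].
#' @param states per-leaf codon states: named character vector of codons
#'   or integer codon indices, `NA` for missing.
#' @return log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, m, states) {
  stopifnot(inherits(m, "codon_rate_matrix"))
  td <- .tree_data(tree)
  s <- .states_for_tree(states, td$labels)
  pi <- stationary_distribution(m)
  if (m$model$reversible) {
    cpp_prune_site(m$Q, pi, td$edges, td$blen, s, td$nnode)
  } else {
    .prune_site_expm(m$Q, pi, td, s)
  }
}

## expm fallback for non-reversible generators (no symmetric eigendecomp.)
.prune_site_expm <- function(Q, pi, td, s) {
  part <- matrix(1, 61, td$nnode)
  for (i in seq_len(td$ntip)) if (s[i] >= 0) {
    part[, i] <- 0
    part[s[i] + 1L, i] <- 1
  }
  logscale <- 0
  for (e in seq_len(nrow(td$edges))) {
    P <- as.matrix(Matrix::expm(Q * td$blen[e]))
    par <- td$edges[e, 1] + 1L
    ch <- td$edges[e, 2] + 1L
    part[, par] <- part[, par] * (P %*% part[, ch])
    mx <- max(part[, par])
    if (mx <= 0) return(-Inf)
    part[, par] <- part[, par] / mx
    logscale <- logscale + log(mx)
  }
  root <- td$edges[nrow(td$edges), 1] + 1L
  log(sum(pi * part[, root])) + logscale
}

## kernel states matrix (ntip x S) from a codon alignment
.aln_states <- function(aln, labels) {
  miss <- setdiff(labels, rownames(aln))
  if (length(miss)) stop("alignment lacks taxa: ",
                         paste(miss, collapse = ", "))
  s <- unclass(aln)[labels, , drop = FALSE]
  s[is.na(s)] <- 0L
  storage.mode(s) <- "integer"
  s - 1L
}

#' Fit a single branch-length scale under a neutral codon model
#'
#' Maximizes the alignment likelihood over one multiplicative factor on
#' all branch lengths, under the all-fitnesses-equal (neutral) codon
#' matrix: synonymous and neutral variation carry the branch-length
#' signal.  An alignment with no variation makes the scale unidentifiable
#' and is an error.
#'
#' @param aln a [codon_alignment()].
#' @param tree rooted `ape::phylo`.
#' @param model a [mutation_model()].
#' @param interval log-scale search interval.
#' @return list with `scale`, the rescaled `tree`, and `loglik`.
#' @export
fit_branch_scale <- function(aln, tree, model, interval = c(-7, 7)) {
  td <- .tree_data(tree)
  states <- .aln_states(aln, td$labels)
  nlev <- apply(states, 2, function(x) length(unique(x[x >= 0])))
  if (all(nlev <= 1) && ncol(states) > 0 &&
      all(apply(states, 2, function(x) all(x >= 0) || all(x < 0))))
    if (max(nlev) <= 1) stop("alignment has no variation: ",
                             "branch scale is unidentifiable")
  m <- codon_rate_matrix(model, rep(0, 20))
  pi <- stationary_distribution(m)
  obj <- function(ls) {
    -sum(cpp_prune_alignment(m$Q, pi, td$edges, td$blen * exp(ls),
                             states, td$nnode))
  }
  opt <- stats::optimize(obj, interval)
  scale <- exp(opt$minimum)
  tree$edge.length <- tree$edge.length * scale
  list(scale = scale, tree = tree, loglik = -opt$objective)
}

#' Estimate site-specific amino-acid fitness profiles by penalized ML
#'
#' For each alignment column, maximizes the pruning log-likelihood of the
#' mutation-selection codon model over the 20 scaled amino-acid fitnesses,
#' minus a ridge penalty \eqn{\lambda \sum_{aa} F_{aa}^2} shrinking toward
#' neutrality (all fitnesses equal).  This is a deliberately simple
#' per-site replacement for Bayesian profile estimation with pooling
#' across sites: each site is fitted independently with a shared penalty.
#' Bounded quasi-Newton (`L-BFGS-B`) with multiple starts.
#'
#' @param aln a [codon_alignment()] (gap-filtered; see
#'   [filter_gap_sites()]).
#' @param tree rooted `ape::phylo` with branch lengths on the substitution
#'   scale (see [fit_branch_scale()]).
#' @param model a reversible [mutation_model()].
#' @param penalty ridge penalty weight \eqn{\lambda} (default 0.1).
#' @param starts number of optimization starts (first from neutrality,
#'   the rest random).
#' @param seed integer seed for the random starts.
#' @param bound box bound on each fitness (|F| <= bound).
#' @return list with `profiles` (L x 20 gauge-normalized matrix),
#'   `loglik`, `convergence` (optim codes, per site) and `uninformative`
#'   (all-gap sites, profile fixed at 0).
#' @export
estimate_site_profiles <- function(aln, tree, model, penalty = 0.1,
                                   starts = 3, seed = 1, bound = 25) {
  stopifnot(inherits(model, "nuc_model"), model$reversible)
  td <- .tree_data(tree)
  states <- .aln_states(aln, td$labels)
  gc <- genetic_code()
  nb <- gc$neighbors[!gc$neighbors$stop_gain, ]
  nbm <- as.matrix(nb[c("from", "to", "from_base", "to_base",
                        "syn", "aa_from", "aa_to")])
  storage.mode(nbm) <- "integer"
  nbm[, c("from", "to", "from_base", "to_base",
          "aa_from", "aa_to")] <-
    nbm[, c("from", "to", "from_base", "to_base",
            "aa_from", "aa_to")] - 1L
  psi <- model$pi[gc$codon_base[, 1]] * model$pi[gc$codon_base[, 2]] *
    model$pi[gc$codon_base[, 3]]
  aa0 <- gc$aa_index - 1L

  L <- ncol(states)
  prof <- matrix(0, L, 20, dimnames = list(NULL, AA_LETTERS))
  ll <- numeric(L)
  conv <- integer(L)
  uninf <- logical(L)
  rng <- .substream_rng(seed, "profile-starts")
  for (s in seq_len(L)) {
    st <- states[, s]
    if (all(st < 0)) {
      uninf[s] <- TRUE
      ll[s] <- 0
      next
    }
    fn <- function(F) cpp_profile_negloglik(F, model$rates, psi, aa0, nbm,
                                            td$edges, td$blen, st,
                                            td$nnode, penalty)
    best <- NULL
    for (k in seq_len(starts)) {
      F0 <- if (k == 1) rep(0, 20) else rng(20, sd = 2)
      o <- stats::optim(F0, fn, method = "L-BFGS-B",
                        lower = -bound, upper = bound,
                        control = list(maxit = 200))
      if (is.null(best) || o$value < best$value) best <- o
    }
    prof[s, ] <- gauge_normalize(best$par)
    conv[s] <- best$convergence
    ll[s] <- -(best$value) + penalty * sum(gauge_normalize(best$par)^2)
  }
  list(profiles = prof, loglik = ll, convergence = conv,
       uninformative = uninf)
}
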
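## Synthetic data with known ground truth: site fitness landscapes, codon
## evolution along a tree, terminal-branch substitutions with an optional
## adaptive (landscape-shift) component, and PRF polymorphism.

#' Simulation scenario
#'
#' Bundles every knob of the synthetic world.  Defaults describe a
#' mammal-like exome: a 4-taxon tree (focal population plus three
#' outgroups), an HKY mutation model, strongly heterogeneous site
#' constraint (concentration 0.04, which places ~1% of the
#' non-synonymous mutation-rate mass in class B0 at stationarity, the
#' share observed in mammalian exomes), and human-scale population
#' parameters
#' (\eqn{u = 7.24\times 10^{-9}} per site per generation,
#' \eqn{N_e = 10^5}, \eqn{\theta = 4 N_e u}).  The adaptive component is a
#' fraction of sites whose fitness landscape is redrawn at the present
#' (`shift_fraction`); mutations that are beneficial on the new landscape
#' but not predicted so by the old one are adaptive rather than
#' restorative.
#'
#' @param n_sites number of codon sites.
#' @param tree rooted 4-taxon `ape::phylo`; tip `focal` is the population
#'   under study, the remaining tips are outgroups (closest first).
#' @param focal tip label of the focal population.
#' @param model a reversible [mutation_model()].
#' @param concentration symmetric-Dirichlet concentration of the fitness
#'   landscape draw; small = strongly constrained sites.
#' @param Ne effective population size (individuals).
#' @param u mutation rate per site per generation.
#' @param n sample size in chromosomes.
#' @param shift_fraction fraction of sites whose landscape is redrawn
#'   (the adaptive component).
#' @param shift_concentration concentration of the redraw.
#' @param mispolarization_rate probability that a SNP's derived and
#'   ancestral alleles are swapped in the emitted table.
#' @param cpg_fraction fraction of sites flagged as CpG-like
#'   hypermutable.
#' @param cpg_multiplier mutation-rate multiplier at flagged sites.
#' @param seed master seed; all randomness flows from it through named
#'   substreams.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_sites = 1000,
                         tree = ape::read.tree(text =
                           "(((focal:0.05,out1:0.05):0.05,out2:0.1):0.05,out3:0.15);"),
                         focal = "focal",
                         model = hky_model(),
                         concentration = 0.04,
                         Ne = 1e5, u = 7.24e-9, n = 16,
                         shift_fraction = 0,
                         shift_concentration = concentration,
                         mispolarization_rate = 0,
                         cpg_fraction = 0, cpg_multiplier = 8,
                         seed = 1) {
  stopifnot(n_sites > 0, concentration > 0, Ne > 0, u > 0, n >= 2,
            shift_fraction >= 0, shift_fraction <= 1,
            mispolarization_rate >= 0, mispolarization_rate <= 0.5,
            cpg_fraction >= 0, cpg_fraction <= 1, cpg_multiplier >= 0,
            focal %in% tree$tip.label)
  structure(list(n_sites = as.integer(n_sites), tree = tree, focal = focal,
                 model = model, concentration = concentration,
                 Ne = Ne, u = u, theta = 4 * Ne * u, n = as.integer(n),
                 shift_fraction = shift_fraction,
                 shift_concentration = shift_concentration,
                 mispolarization_rate = mispolarization_rate,
                 cpg_fraction = cpg_fraction,
                 cpg_multiplier = cpg_multiplier,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario:", x$n_sites, "codon sites,",
      length(x$tree$tip.label), "taxa\n")
  cat(sprintf("  Ne = %g, u = %g, theta = %g, n = %d chromosomes\n",
              x$Ne, x$u, x$theta, x$n))
  cat(sprintf("  shift_fraction = %g, mispolarization = %g, CpG = %g x%g\n",
              x$shift_fraction, x$mispolarization_rate,
              x$cpg_fraction, x$cpg_multiplier))
  invisible(x)
}

#' Draw site-specific amino-acid fitness landscapes
#'
#' Per-site fitness profiles are the log of symmetric-Dirichlet draws
#' (gauge-normalized to mean zero): small concentration gives strongly
#' constrained sites where one or a few amino acids dominate, large
#' concentration approaches neutrality (all fitnesses equal).
#'
#' @param n_sites number of sites.
#' @param concentration Dirichlet concentration (> 0).
#' @param seed integer seed (substream-derived by callers).
#' @return `n_sites` x 20 matrix of scaled log fitnesses.
#' @export
sample_fitness_landscape <- function(n_sites, concentration, seed = NULL) {
  stopifnot(n_sites > 0, concentration > 0)
  draw <- function() {
    g <- matrix(rgamma(n_sites * 20, shape = concentration), n_sites, 20)
    ## guard against gamma underflow at tiny concentration
    g <- pmax(g, 1e-280)
    F <- log(g / rowSums(g))
    colnames(F) <- AA_LETTERS
    gauge_normalize(F)
  }
  if (is.null(seed)) draw() else .with_substream(seed, "landscape", draw())
}

## Per-codon gather tables for vectorized simulation: 61 x 9 matrices of
## target codon (0 = stop), mutation rate, and source/target amino acid.
.sim_tables <- function(model) {
  gc <- genetic_code()
  nb <- gc$neighbors
  ord <- order(nb$from)
  nb <- nb[ord, ]
  to <- matrix(ifelse(nb$stop_gain, 0L, nb$to), 61, 9, byrow = TRUE)
  mu <- matrix(model$rates[cbind(nb$from_base, nb$to_base)],
               61, 9, byrow = TRUE)
  aaf <- matrix(nb$aa_from, 61, 9, byrow = TRUE)
  aat <- matrix(ifelse(nb$stop_gain, nb$aa_from, nb$aa_to),
                61, 9, byrow = TRUE)
  list(to = to, mu = mu, aaf = aaf, aat = aat)
}

## rates of the 9 single-nucleotide changes for each listed site
.site_rates <- function(cur, sites, prof, tb, mult) {
  m <- length(cur)
  aat <- tb$aat[cur, , drop = FALSE]
  aaf <- tb$aaf[cur, , drop = FALSE]
  dF <- prof[cbind(rep(sites, 9), as.vector(aat))] -
    prof[cbind(rep(sites, 9), as.vector(aaf))]
  r <- tb$mu[cur, , drop = FALSE] *
    matrix(fixation_rate(dF), m, 9) * mult[sites]
  r[tb$to[cur, , drop = FALSE] == 0L] <- 0
  r
}

## Vectorized Gillespie along one branch for all sites at once.
.sim_branch <- function(states, len, prof, tb, mult = NULL) {
  L <- length(states)
  if (is.null(mult)) mult <- rep(1, L)
  ev_site <- integer(0); ev_t <- numeric(0)
  ev_from <- integer(0); ev_to <- integer(0)
  if (len <= 0) return(list(states = states,
                            events = data.frame(site = ev_site, time = ev_t,
                                                from = ev_from, to = ev_to)))
  active <- seq_len(L)
  trem <- rep(len, L)
  while (length(active)) {
    r <- .site_rates(states[active], active, prof, tb, mult)
    tot <- rowSums(r)
    dt <- ifelse(tot > 0, rexp(length(active), pmax(tot, 1e-300)), Inf)
    hit <- dt < trem[active]
    if (!any(hit)) break
    idx <- active[hit]
    rh <- r[hit, , drop = FALSE]
    cum <- rh
    for (k in 2:9) cum[, k] <- cum[, k] + cum[, k - 1]
    u <- runif(length(idx)) * tot[hit]
    choice <- max.col(cum >= u, "first")
    to <- tb$to[cbind(states[idx], choice)]
    ev_site <- c(ev_site, idx)
    ev_t <- c(ev_t, len - (trem[idx] - dt[hit]))
    ev_from <- c(ev_from, states[idx])
    ev_to <- c(ev_to, to)
    states[idx] <- to
    trem[idx] <- trem[idx] - dt[hit]
    active <- idx
  }
  list(states = states,
       events = data.frame(site = ev_site, time = ev_t,
                           from = ev_from, to = ev_to))
}

#' Sample an exome from site stationary distributions
#'
#' Draws one codon per site from \eqn{\pi_c \propto \psi_c e^{F_{aa(c)}}}
#' (mutation-selection balance), chunked so that exome-scale site counts
#' do not materialize a 61 x L matrix.
#'
#' @param profiles L x 20 fitness matrix.
#' @param model a reversible [mutation_model()].
#' @param chunk sites per chunk.
#' @return integer vector of codon states (1-61).
#' @export
sample_stationary_exome <- function(profiles, model, chunk = 50000L) {
  gc <- genetic_code()
  psi <- model$pi[gc$codon_base[, 1]] * model$pi[gc$codon_base[, 2]] *
    model$pi[gc$codon_base[, 3]]
  L <- nrow(profiles)
  out <- integer(L)
  for (lo in seq(1, L, chunk)) {
    hi <- min(lo + chunk - 1, L)
    E <- exp(profiles[lo:hi, , drop = FALSE])
    W <- E[, gc$aa_index, drop = FALSE] *
      matrix(psi, hi - lo + 1, 61, byrow = TRUE)
    tot <- rowSums(W)
    u <- runif(hi - lo + 1) * tot
    acc <- numeric(hi - lo + 1)
    pick <- integer(hi - lo + 1)
    for (c in 1:61) {
      acc <- acc + W[, c]
      hitnow <- pick == 0L & acc >= u
      pick[hitnow] <- c
    }
    pick[pick == 0L] <- 61L
    out[lo:hi] <- pick
  }
  out
}

#' Simulate codon evolution along a tree
#'
#' Continuous-time (Gillespie) simulation of every site along every branch
#' under the site's mutation-selection rate matrix; the root is drawn from
#' each site's stationary distribution.  The full event log is returned,
#' which is the substitution-level ground truth.
#'
#' @param tree rooted `ape::phylo`.
#' @param profiles L x 20 fitness matrix.
#' @param model a reversible [mutation_model()].
#' @param cpg_mult optional per-site mutation-rate multiplier.
#' @param root_states optional integer vector of root codons (otherwise
#'   stationary draw).
#' @return list with `alignment` (a [codon_alignment()] over the tips),
#'   `node_states` (nnode x L integer matrix), and `events` (data frame:
#'   `site`, `edge`, `time`, `from`, `to`).
#' @export
simulate_alignment <- function(tree, profiles, model, cpg_mult = NULL,
                               root_states = NULL) {
  td <- .tree_data(tree)
  tb <- .sim_tables(model)
  L <- nrow(profiles)
  if (is.null(root_states)) root_states <- sample_stationary_exome(profiles, model)
  node_states <- matrix(0L, td$nnode, L)
  root <- td$edges[nrow(td$edges), 1] + 1L
  node_states[root, ] <- root_states
  ev <- vector("list", nrow(td$edges))
  for (e in rev(seq_len(nrow(td$edges)))) {      # preorder
    par <- td$edges[e, 1] + 1L
    ch <- td$edges[e, 2] + 1L
    res <- .sim_branch(node_states[par, ], td$blen[e], profiles, tb, cpg_mult)
    node_states[ch, ] <- res$states
    if (nrow(res$events)) res$events$edge <- e
    ev[[e]] <- res$events
  }
  events <- do.call(rbind, ev[vapply(ev, nrow, 1L) > 0])
  if (is.null(events))
    events <- data.frame(site = integer(0), time = numeric(0),
                         from = integer(0), to = integer(0),
                         edge = integer(0))
  aln <- node_states[seq_len(td$ntip), , drop = FALSE]
  rownames(aln) <- td$labels
  class(aln) <- c("codon_alignment", "matrix")
  list(alignment = aln, node_states = node_states, events = events)
}

#' Simulate the focal terminal branch with an optional landscape shift
#'
#' A fraction `shift_fraction` of sites has its fitness landscape redrawn
#' before the branch is simulated: this is the adaptive component, defined
#' as evolution under a changed landscape.  Each substitution is recorded
#' with its true scaled coefficient `S` (on the current, possibly shifted
#' landscape) and its predicted `S0` (on the original landscape, which is
#' what a phylogenetic fit of the stable-landscape model would see).
#'
#' @param scenario a [sim_scenario()].
#' @param anc_exome integer codon states at the base of the branch.
#' @param profiles original (pre-shift) L x 20 fitness matrix.
#' @param cpg_mult optional per-site rate multiplier.
#' @param branch_length terminal branch length; default from the
#'   scenario's tree.
#' @return list with `exome` (end-of-branch states), `profiles_true`
#'   (post-shift), `shifted` (logical mask), and `substitutions` (data
#'   frame with `site`, `time`, `from`, `to`, `S_true`, `S0`, `class_true`,
#'   `class_s0`).
#' @export
simulate_terminal_branch <- function(scenario, anc_exome, profiles,
                                     cpg_mult = NULL, branch_length = NULL) {
  stopifnot(length(anc_exome) == nrow(profiles))
  L <- nrow(profiles)
  if (is.null(branch_length)) {
    te <- which(scenario$tree$tip.label == scenario$focal)
    branch_length <-
      scenario$tree$edge.length[scenario$tree$edge[, 2] == te]
  }
  shifted <- .with_substream(scenario$seed, "landscape-shift",
                             runif(L) < scenario$shift_fraction)
  profiles_true <- profiles
  if (any(shifted)) {
    profiles_true[shifted, ] <- .with_substream(
      scenario$seed, "landscape-shift-redraw",
      sample_fitness_landscape(sum(shifted), scenario$shift_concentration))
  }
  tb <- .sim_tables(scenario$model)
  res <- .with_substream(scenario$seed, "branch-sim",
                         .sim_branch(anc_exome, branch_length,
                                     profiles_true, tb, cpg_mult))
  sub <- res$events
  gc <- genetic_code()
  if (nrow(sub)) {
    aaf <- gc$aa_index[sub$from]
    aat <- gc$aa_index[sub$to]
    syn <- aaf == aat
    sub$S_true <- ifelse(syn, 0,
                         profiles_true[cbind(sub$site, aat)] -
                           profiles_true[cbind(sub$site, aaf)])
    sub$S0 <- ifelse(syn, 0, profiles[cbind(sub$site, aat)] -
                       profiles[cbind(sub$site, aaf)])
    sub$class_true <- classify_s0(sub$S_true, syn)
    sub$class_s0 <- classify_s0(sub$S0, syn)
  } else {
    sub$S_true <- sub$S0 <- numeric(0)
    sub$class_true <- sub$class_s0 <- character(0)
  }
  list(exome = res$states, profiles_true = profiles_true,
       shifted = shifted, substitutions = sub)
}

#' Simulate population polymorphism from PRF sojourn densities
#'
#' For every possible single-nucleotide change away from the extant exome
#' (stop-gaining changes excluded, as nonsense variants are discarded
#' upstream), segregating sites arise as a Poisson field with expectation
#' \eqn{\theta_{a\to b}\, \sum_i H_i(S)} where \eqn{S} is the change's true
#' scaled coefficient on the current landscape and \eqn{H_i} the sampled
#' PRF shape ([prf_expected_shape()]).  Derived-allele counts are drawn
#' from the normalized \eqn{H_i(S)}; mispolarization swaps ancestral and
#' derived with the configured rate.
#'
#' @param scenario a [sim_scenario()].
#' @param exome integer codon states of the (true) ancestral exome.
#' @param profiles_true current (post-shift) L x 20 fitness matrix.
#' @param profiles_s0 original landscape used for the `S0` truth labels.
#' @param cpg_flags logical per-site CpG-like flags.
#' @param chunk sites per enumeration chunk.
#' @return list with `snps` (data frame in the exchange dialect: `gene`,
#'   `site`, `ancestral_codon`, `derived_codon`, `derived_count`, `n`,
#'   `cpg_flag`) and `truth` (parallel rows: `S_true`, `S0`, `class_true`,
#'   `class_s0`, `polarization_correct`).
#' @export
simulate_polymorphism <- function(scenario, exome, profiles_true,
                                  profiles_s0 = profiles_true,
                                  cpg_flags = NULL, chunk = 100000L) {
  if (scenario$n < 2) stop("sample size n must be at least 2")
  L <- length(exome)
  stopifnot(nrow(profiles_true) == L, nrow(profiles_s0) == L)
  if (is.null(cpg_flags)) cpg_flags <- rep(FALSE, L)
  mult <- ifelse(cpg_flags, scenario$cpg_multiplier, 1)
  tb <- .sim_tables(scenario$model)
  n <- scenario$n
  basis <- .prf_basis(n)
  htot <- .prf_total_interp(n)
  gc <- genetic_code()

  .with_substream(scenario$seed, "polymorphism", {
    parts <- list()
    for (lo in seq(1, L, chunk)) {
      hi <- min(lo + chunk - 1, L)
      sites <- lo:hi
      cur <- exome[sites]
      m <- length(sites)
      to <- tb$to[cur, , drop = FALSE]
      valid <- to > 0L
      aaf <- tb$aaf[cur, , drop = FALSE]
      aat <- tb$aat[cur, , drop = FALSE]
      rs <- rep(sites, 9)
      syn <- as.vector(aaf == aat)
      S_true <- ifelse(syn, 0,
                       profiles_true[cbind(rs, as.vector(aat))] -
                         profiles_true[cbind(rs, as.vector(aaf))])
      w <- scenario$theta * as.vector(tb$mu[cur, , drop = FALSE]) *
        rep(mult[sites], 9)
      lam <- w * htot(S_true)
      lam[!as.vector(valid)] <- 0
      k <- rpois(length(lam), lam)
      sel <- which(k > 0)
      if (!length(sel)) next
      rep_idx <- rep(sel, k[sel])
      S0 <- ifelse(syn[rep_idx], 0,
                   profiles_s0[cbind(rs[rep_idx],
                                     as.vector(aat)[rep_idx])] -
                     profiles_s0[cbind(rs[rep_idx],
                                       as.vector(aaf)[rep_idx])])
      H <- .prf_H(S_true[rep_idx], basis)
      i_draw <- .sample_rows(H)
      parts[[length(parts) + 1L]] <- data.frame(
        site = rs[rep_idx],
        anc = rep(cur, 9)[rep_idx],
        der = as.vector(to)[rep_idx],
        i = i_draw,
        S_true = S_true[rep_idx],
        S0 = S0,
        syn = syn[rep_idx])
    }
    if (!length(parts)) {
      snp <- data.frame(site = integer(0), anc = integer(0),
                        der = integer(0), i = integer(0),
                        S_true = numeric(0), S0 = numeric(0),
                        syn = logical(0))
    } else snp <- do.call(rbind, parts)
    flip <- runif(nrow(snp)) < scenario$mispolarization_rate
    anc_seen <- ifelse(flip, snp$der, snp$anc)
    der_seen <- ifelse(flip, snp$anc, snp$der)
    i_seen <- ifelse(flip, n - snp$i, snp$i)
    list(snps = data.frame(
           gene = rep("synthetic", nrow(snp)),
           site = snp$site - 1L,                 # 0-based exchange dialect
           ancestral_codon = index_codon(anc_seen),
           derived_codon = index_codon(der_seen),
           derived_count = as.integer(i_seen),
           n = rep(n, nrow(snp)),
           cpg_flag = cpg_flags[snp$site]),
         truth = data.frame(
           site = snp$site,
           S_true = snp$S_true,
           S0 = snp$S0,
           class_true = classify_s0(snp$S_true, snp$syn),
           class_s0 = classify_s0(snp$S0, snp$syn),
           polarization_correct = !flip))
  })
}

## sample one column index per row, probabilities proportional to row values
.sample_rows <- function(P) {
  tot <- rowSums(P)
  u <- runif(nrow(P)) * tot
  acc <- numeric(nrow(P))
  pick <- integer(nrow(P))
  for (j in seq_len(ncol(P))) {
    acc <- acc + P[, j]
    pick[pick == 0L & acc >= u] <- j
  }
  pick[pick == 0L] <- ncol(P)
  pick
}

#' Generate a complete synthetic dataset with ground truth
#'
#' One call emits everything the two-scale pipeline consumes, plus the
#' generative truth needed to score it: fitness landscapes (pre- and
#' post-shift), the 4-taxon alignment (optional), the true ancestral and
#' extant exomes, terminal-branch substitution records, the SNP table, and
#' per-SNP truth.  Byte-reproducible for a fixed scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @param mode `"phylo"` simulates the full 4-taxon alignment plus the
#'   focal terminal branch; `"terminal"` skips the outgroups (the
#'   ancestral exome is a stationary draw) but simulates the terminal
#'   branch, so divergence data exist; `"population"` also skips the
#'   branch (polymorphism only, the extant exome is the ancestral one).
#' @param phylo deprecated logical alias (`TRUE` = `"phylo"`,
#'   `FALSE` = `"population"`).
#' @return object of class `scenario_bundle`.
#' @export
make_scenario_bundle <- function(scenario,
                                 mode = c("phylo", "terminal",
                                          "population"),
                                 phylo = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(phylo)) mode <- if (phylo) "phylo" else "population"
  else mode <- match.arg(mode)
  L <- scenario$n_sites
  profiles <- sample_fitness_landscape(L, scenario$concentration,
                                       seed = scenario$seed)
  cpg <- .with_substream(scenario$seed, "cpg",
                         runif(L) < scenario$cpg_fraction)
  mult <- ifelse(cpg, scenario$cpg_multiplier, 1)

  if (mode == "phylo") {
    tree0 <- scenario$tree
    te <- which(tree0$tip.label == scenario$focal)
    focal_edge <- which(tree0$edge[, 2] == te)
    branch_length <- tree0$edge.length[focal_edge]
    tree0$edge.length[focal_edge] <- 0
    sim <- .with_substream(scenario$seed, "tree-sim",
                           simulate_alignment(tree0, profiles,
                                              scenario$model, mult))
    anc_exome <- unclass(sim$alignment)[scenario$focal, ]
    term <- simulate_terminal_branch(scenario, anc_exome, profiles,
                                     mult, branch_length)
    alignment <- sim$alignment
    alignment[scenario$focal, ] <- term$exome
    tree_events <- sim$events
  } else if (mode == "terminal") {
    anc_exome <- .with_substream(scenario$seed, "tree-sim",
                                 sample_stationary_exome(profiles,
                                                         scenario$model))
    term <- simulate_terminal_branch(scenario, anc_exome, profiles, mult)
    alignment <- NULL
    tree_events <- NULL
  } else {
    anc_exome <- .with_substream(scenario$seed, "tree-sim",
                                 sample_stationary_exome(profiles,
                                                         scenario$model))
    shifted <- .with_substream(scenario$seed, "landscape-shift",
                               runif(L) < scenario$shift_fraction)
    profiles_true <- profiles
    if (any(shifted))
      profiles_true[shifted, ] <- .with_substream(
        scenario$seed, "landscape-shift-redraw",
        sample_fitness_landscape(sum(shifted),
                                 scenario$shift_concentration))
    term <- list(exome = anc_exome, profiles_true = profiles_true,
                 shifted = shifted,
                 substitutions = data.frame(site = integer(0)))
    alignment <- NULL
    tree_events <- NULL
  }

  poly <- simulate_polymorphism(scenario, term$exome, term$profiles_true,
                                profiles, cpg)
  structure(list(scenario = scenario,
                 profiles = profiles,
                 profiles_true = term$profiles_true,
                 shifted = term$shifted,
                 cpg_flags = cpg,
                 alignment = alignment,
                 tree_events = tree_events,
                 anc_exome = anc_exome,
                 exome = term$exome,
                 substitutions = term$substitutions,
                 snps = poly$snps,
                 snp_truth = poly$truth),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("Synthetic scenario bundle:", x$scenario$n_sites, "sites,",
      nrow(x$snps), "SNPs,",
      if (!is.null(x$substitutions)) nrow(x$substitutions) else 0,
      "terminal-branch substitutions\n")
  invisible(x)
}
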
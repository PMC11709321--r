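## Combining the two scales: class posteriors x opportunities ->
## precision/recall (including P[B0|B]), pipeline orchestration, and
## scoring against synthetic ground truth.

#' Marginal probability of a population-scale class
#'
#' Law of total probability over the phylogenetic classes:
#' \eqn{P[B] = \sum_x P[B|x] P[x]} (same for D and N).
#'
#' @param posteriors named list (`D0`, `N0`, `B0`) of class-posterior
#'   vectors as returned by [class_probabilities()].
#' @param opportunities an `opportunity_table` (supplies `P[x]`).
#' @param target population-scale class: `"D"`, `"N"` or `"B"`.
#' @return probability.
#' @export
marginal_probability <- function(posteriors, opportunities, target = "B") {
  Px <- opportunities$P_x
  stopifnot(abs(sum(Px) - 1) < 1e-8)
  sum(vapply(names(Px), function(x) posteriors[[x]][[target]] * Px[[x]],
             numeric(1)))
}

#' Precision and recall of the phylogenetic classification
#'
#' Precision is read directly from the class posteriors
#' (\eqn{P[B|B0]}, etc.); recall follows by Bayes' rule,
#' \eqn{P[B0|B] = P[B|B0] P[B0] / P[B]} with \eqn{P[B]} from
#' [marginal_probability()].  \eqn{P[B0|B]} is the proportion of
#' beneficial mutations that are non-adaptive.
#'
#' @inheritParams marginal_probability
#' @return list with `precision` (named D0/N0/B0), `recall` (named
#'   D/N/B), and `marginal` (named D/N/B).
#' @export
precision_recall <- function(posteriors, opportunities) {
  Px <- opportunities$P_x
  classes <- c(D0 = "D", N0 = "N", B0 = "B")
  marg <- vapply(classes, function(y)
    marginal_probability(posteriors, opportunities, y), numeric(1))
  names(marg) <- classes
  precision <- vapply(names(classes), function(x)
    posteriors[[x]][[classes[[x]]]], numeric(1))
  recall <- vapply(names(classes), function(x) {
    y <- classes[[x]]
    if (marg[[y]] <= 0) return(NA_real_)
    posteriors[[x]][[y]] * Px[[x]] / marg[[y]]
  }, numeric(1))
  names(recall) <- classes
  if (anyNA(recall))
    warning("zero marginal probability: recall undefined for ",
            paste(classes[is.na(recall)], collapse = ", "))
  list(precision = precision, recall = recall, marginal = marg)
}

#' Run the two-scale selection pipeline on a dataset
#'
#' Orchestrates, in order: classification of every possible mutation on
#' the fitness landscape, mutational opportunities, SNP classification,
#' class-stratified SFS (with optional subsampling and CpG filtering),
#' per-class DFE fits against the synonymous spectrum (optionally with
#' terminal-branch divergence), class posteriors, precision/recall, and
#' diversity summaries.  Deterministic given `seed`.
#'
#' @param bundle a [make_scenario_bundle()] result, or a list with the
#'   same fields (`snps`, `exome`, `profiles`, and for divergence
#'   `anc_exome`/`substitutions`) for real data.
#' @param subsample subsample each SFS to this many chromosomes when the
#'   data's n exceeds it (default 16).
#' @param cpg_filter exclude CpG-flagged sites and SNPs.
#' @param with_divergence add terminal-branch substitution counts to the
#'   DFE fits (requires a phylo-mode bundle).
#' @param dfe_form `"parametric"` or `"discrete"`.
#' @param epsilon mispolarization nuisance passed to [fit_dfe()].
#' @param seed seed for fit multi-starts.
#' @param starts optimization starts per DFE fit.
#' @param bias_correct number of parametric-bootstrap replicates used to
#'   bias-correct the precision/recall summaries (0 = off).  The true
#'   class-conditional DFEs sit on the boundary of the model space (e.g.
#'   the B0 class has no mass below \eqn{S = 1} when the landscape is
#'   stable), so sampling noise can only push fitted mass off the corner;
#'   the first-order correction `2*est - mean(boot)` counters that.
#' @return object of class `selection_report`.
#' @export
run_pipeline <- function(bundle, subsample = 16, cpg_filter = FALSE,
                         with_divergence = FALSE,
                         dfe_form = c("parametric", "discrete"),
                         epsilon = 0, seed = 1, starts = 8,
                         bias_correct = 0) {
  dfe_form <- match.arg(dfe_form)
  scen <- bundle$scenario
  model <- scen$model
  profiles <- bundle$profiles
  snps <- bundle$snps

  ## analyst's ancestral exome: reference corrected by the (possibly
  ## mispolarized) ancestral alleles seen in the SNP table
  exome <- bundle$exome
  if (nrow(snps)) {
    first <- !duplicated(snps$site)
    exome[snps$site[first] + 1L] <- codon_index(snps$ancestral_codon[first])
  }

  opp <- mutational_opportunities(exome, model, profiles,
                                  cpg_flags = bundle$cpg_flags,
                                  cpg_multiplier = scen$cpg_multiplier,
                                  exclude_cpg = cpg_filter)
  snps <- classify_snps(snps, profiles)
  spectra <- build_sfs(snps, opp, exclude_cpg = cpg_filter)
  n_obs <- spectra$SYN$n
  if (n_obs > subsample)
    spectra <- lapply(spectra, subsample_sfs, m = subsample)

  divergence <- NULL
  div_table <- NULL
  if (with_divergence) {
    if (is.null(bundle$substitutions) || !nrow(bundle$substitutions))
      stop("bundle has no terminal-branch substitutions")
    seg <- unique(snps$site + 1L)
    counts <- map_substitutions(bundle$anc_exome, exome, profiles,
                                segregating_sites = seg)
    div_table <- dnds_by_class(counts, opp)
    divergence <- counts
  }

  fits <- list()
  posteriors <- list()
  for (x in c("D0", "N0", "B0")) {
    div_x <- if (!is.null(divergence))
      list(D_x = unname(divergence$D_x[x]), D_syn = divergence$D_syn)
    fits[[x]] <- fit_dfe(spectra[[x]], spectra$SYN, divergence = div_x,
                         form = dfe_form, epsilon = epsilon,
                         seed = .substream_seed(seed, paste0("fit-", x)),
                         starts = starts)
    posteriors[[x]] <- as.list(class_probabilities(fits[[x]]))
  }
  pr <- precision_recall(posteriors, opp)
  boot <- NULL
  if (bias_correct > 0 && is.null(divergence)) {
    n_fit <- spectra$SYN$n
    ii <- seq_len(n_fit - 1)
    th <- mean(vapply(fits, function(f) f$theta, numeric(1)))
    Esyn <- th * spectra$SYN$L / ii
    Ex <- lapply(fits, function(f)
      expected_sfs(f$model, f$theta, n_fit, f$data$sfs_x$L))
    stat <- function(p) unlist(precision_recall(p, opp)[c("precision",
                                                          "recall")])
    reps <- .with_substream(seed, "bias-correct", {
      vapply(seq_len(bias_correct), function(k) {
        spsyn <- sfs(rpois(n_fit - 1, Esyn), n_fit, spectra$SYN$L, "SYN")
        pk <- list()
        for (x in names(fits)) {
          spx <- sfs(rpois(n_fit - 1, Ex[[x]]), n_fit,
                     fits[[x]]$data$sfs_x$L, x)
          fk <- fit_dfe(spx, spsyn, form = dfe_form, epsilon = epsilon,
                        seed = .substream_seed(seed, paste0("bc-", x)),
                        starts = starts)
          pk[[x]] <- as.list(class_probabilities(fk))
        }
        stat(pk)
      }, numeric(6))
    })
    raw <- stat(posteriors)
    corrected <- pmin(pmax(2 * raw - rowMeans(reps), 0), 1)
    boot <- list(raw = raw, boot_mean = rowMeans(reps), K = bias_correct)
    pr$precision[] <- corrected[1:3]
    pr$recall[] <- corrected[4:6]
  }
  theta_S <- watterson_theta(spectra$SYN)
  structure(list(opportunities = opp, spectra = spectra, fits = fits,
                 posteriors = posteriors,
                 precision = pr$precision, recall = pr$recall,
                 marginal = pr$marginal,
                 divergence = div_table,
                 bias_correction = boot,
                 theta_S = theta_S,
                 Ne = ne_estimate(theta_S, scen$u),
                 meta = list(seed = seed, subsample = subsample,
                             cpg_filter = cpg_filter,
                             with_divergence = with_divergence,
                             dfe_form = dfe_form, epsilon = epsilon,
                             n_snps = nrow(snps),
                             scenario_seed = scen$seed)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Two-scale selection report\n")
  cat(sprintf("  theta_S = %.4g, Ne = %.4g, SNPs = %d\n",
              x$theta_S, x$Ne, x$meta$n_snps))
  m <- rbind(`P[x]` = x$opportunities$P_x,
             precision = x$precision,
             recall = x$recall[c("D", "N", "B")])
  colnames(m) <- c("D0", "N0", "B0")
  print(round(m, 3))
  cat(sprintf("  P[B0|B] = %.3f  (beneficial mutations that are non-adaptive)\n",
              x$recall[["B"]]))
  invisible(x)
}

#' @export
summary.selection_report <- function(object, ...) {
  cat("Class posteriors P[. | x]:\n")
  print(round(do.call(rbind, lapply(object$posteriors, unlist)), 3))
  print(object)
  if (!is.null(object$divergence)) {
    print(object$divergence)
    cat(sprintf("  delta(dN/dS) = %.3f\n", delta_dnds(object$divergence)))
  }
  invisible(object)
}

#' Exact generative class table of a synthetic bundle
#'
#' Enumerates every possible single-nucleotide change away from the
#' bundle's true ancestral exome and accumulates mutation-rate weights
#' into the joint table of (phylogenetic class x true population class),
#' using the original landscape for \eqn{S_0} and the current (post-shift)
#' landscape for the true \eqn{S}.  This is the exact, simulation-free
#' oracle for precision, recall and \eqn{P[B_0|B]}.
#'
#' @param bundle a [make_scenario_bundle()] result.
#' @param chunk sites per chunk.
#' @return list with `joint` (3 x 3 matrix of mutation-rate mass,
#'   rows = S0 class, cols = true class), `precision`, `recall`,
#'   `P_x`, and `P_B0_given_B`.
#' @export
oracle_class_table <- function(bundle, chunk = 100000L) {
  scen <- bundle$scenario
  tb <- .sim_tables(scen$model)
  mult <- ifelse(bundle$cpg_flags, scen$cpg_multiplier, 1)
  exome <- bundle$exome
  L <- length(exome)
  joint <- matrix(0, 3, 3, dimnames = list(c("D0", "N0", "B0"),
                                           c("D", "N", "B")))
  for (lo in seq(1, L, chunk)) {
    sites <- lo:min(lo + chunk - 1, L)
    cur <- exome[sites]
    valid <- as.vector(tb$to[cur, , drop = FALSE] > 0L)
    rs <- rep(sites, 9)
    aaf <- as.vector(tb$aaf[cur, , drop = FALSE])
    aat <- as.vector(tb$aat[cur, , drop = FALSE])
    syn <- aaf == aat
    w <- as.vector(tb$mu[cur, , drop = FALSE]) * rep(mult[sites], 9)
    keep <- valid & !syn
    S0 <- bundle$profiles[cbind(rs, aat)] - bundle$profiles[cbind(rs, aaf)]
    St <- bundle$profiles_true[cbind(rs, aat)] -
      bundle$profiles_true[cbind(rs, aaf)]
    c0 <- classify_s0(S0)[keep]
    ct <- sub("0", "", classify_s0(St)[keep])
    wk <- w[keep]
    for (x in rownames(joint)) for (y in colnames(joint))
      joint[x, y] <- joint[x, y] + sum(wk[c0 == x & ct == y])
  }
  P_x <- rowSums(joint) / sum(joint)
  precision <- diag(joint / rowSums(joint))
  names(precision) <- rownames(joint)
  marg <- colSums(joint)
  recall <- diag(t(joint) / marg)
  names(recall) <- colnames(joint)
  list(joint = joint, precision = precision, recall = recall, P_x = P_x,
       P_B0_given_B = joint["B0", "B"] / marg[["B"]])
}

#' Score a pipeline report against ground truth
#'
#' Absolute errors of the report's headline quantities against the exact
#' generative oracle of the synthetic bundle.
#'
#' @param report a [run_pipeline()] result.
#' @param bundle the [make_scenario_bundle()] it was run on.
#' @return list with `oracle` (see [oracle_class_table()]) and `errors`
#'   (absolute errors for `P_B0_given_B`, per-class precision, `theta_S`).
#' @export
score_against_truth <- function(report, bundle) {
  oracle <- oracle_class_table(bundle)
  errs <- list(
    P_B0_given_B = abs(report$recall[["B"]] - oracle$P_B0_given_B),
    precision = abs(report$precision - oracle$precision),
    theta_S = abs(report$theta_S - bundle$scenario$theta))
  list(oracle = oracle, errors = errs)
}

#' Calibrate the landscape-shift fraction to a target P[B0|B]
#'
#' Under the generative model, the oracle \eqn{P[B_0|B]} decreases
#' monotonically in the shift fraction f:
#' \deqn{P[B_0|B](f) = ((1-f) A + f c_{B0}) / ((1-f) A + f c_B),}
#' where A is the expected beneficial mutation-rate mass per stable site
#' (all of it B0, since S = S0 there) and \eqn{c_B}, \eqn{c_{B0}} are the
#' expected beneficial and beneficial-and-B0 masses per shifted site.
#' The three constants are estimated once by Monte Carlo on `mc_sites`
#' fresh sites from the scenario's landscape distribution, and f solves
#' the target equation in closed form.
#'
#' @param scenario a [sim_scenario()].
#' @param target desired oracle \eqn{P[B_0|B]}.
#' @param mc_sites Monte Carlo sites for the constants.
#' @return list with `shift_fraction` and the constants `A`, `c_B`,
#'   `c_B0`.
#' @export
calibrate_shift_fraction <- function(scenario, target, mc_sites = 200000L) {
  stopifnot(target > 0, target <= 1)
  tb <- .sim_tables(scenario$model)
  .with_substream(scenario$seed, "shift-calibration", {
    prof <- sample_fitness_landscape(mc_sites, scenario$concentration)
    prof_new <- sample_fitness_landscape(mc_sites,
                                         scenario$shift_concentration)
    exome <- sample_stationary_exome(prof, scenario$model)
    cur <- exome
    valid <- as.vector(tb$to[cur, , drop = FALSE] > 0L)
    rs <- rep(seq_len(mc_sites), 9)
    aaf <- as.vector(tb$aaf[cur, , drop = FALSE])
    aat <- as.vector(tb$aat[cur, , drop = FALSE])
    syn <- aaf == aat
    w <- as.vector(tb$mu[cur, , drop = FALSE])
    keep <- valid & !syn
    S0 <- prof[cbind(rs, aat)] - prof[cbind(rs, aaf)]
    St <- prof_new[cbind(rs, aat)] - prof_new[cbind(rs, aaf)]
    A <- sum(w[keep & S0 > 1]) / mc_sites
    c_B <- sum(w[keep & St > 1]) / mc_sites
    c_B0 <- sum(w[keep & St > 1 & S0 > 1]) / mc_sites
    f <- A * (1 - target) / (A * (1 - target) + target * c_B - c_B0)
    if (f < 0 || f > 1)
      stop("target P[B0|B] is not reachable for this scenario")
    list(shift_fraction = f, A = A, c_B = c_B, c_B0 = c_B0)
  })
}
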
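test_that("polarization resolves concordant and ambiguous outgroups", {
  mod <- hky_model()
  tr <- sim_scenario()$tree
  # concordant outgroups, short branches: ancestral with high confidence
  pol <- polarize(alleles = cbind("A", "G"),
                  outgroups = cbind(out1 = "A", out2 = "A", out3 = "A"),
                  tree = tr, model = mod)
  expect_true(pol$kept)
  expect_equal(pol$ancestral, "A")
  expect_gt(pol$prob, 0.99)
  # uninformative outgroups (all missing): posterior 1/2, dropped
  pol_n <- polarize(cbind("A", "G"),
                    cbind(out1 = "N", out2 = "N", out3 = "N"), tr, mod)
  expect_false(pol_n$kept)
  expect_equal(pol_n$reason, "no_outgroup")
  # discordant outgroups on long branches: below threshold, dropped
  tr_long <- tr; tr_long$edge.length <- tr$edge.length * 20
  pol_d <- polarize(cbind("A", "G"),
                    cbind(out1 = "G", out2 = "A", out3 = "G"),
                    tr_long, mod)
  expect_false(pol_d$kept)
  expect_equal(pol_d$reason, "low_probability")
  # exhaustive two-state check: posterior matches a brute-force sum over
  # internal nucleotide states of the 4-taxon tree
  P <- function(t) expm_oracle(mod$rates, t)
  bl <- tr$edge.length   # (((focal,out1):b, out2):b, out3) layout
  lik <- function(anc, o) {
    n2 <- P(0.05); o1 <- P(0.05); o2 <- P(0.1)
    n3 <- P(0.05); o3 <- P(0.15)
    s <- 0
    for (x2 in 1:4) for (x3 in 1:4)
      s <- s + n2[anc, x2] * o2[x2, o[2]] * n3[x2, x3] * o3[x3, o[3]]
    mod$pi[anc] * o1[anc, o[1]] * s
  }
  o <- c(1, 3, 1)   # out1 = A, out2 = G, out3 = A
  brute <- lik(1, o) / (lik(1, o) + lik(3, o))
  pol_b <- polarize(cbind("A", "G"),
                    cbind(out1 = "A", out2 = "G", out3 = "A"), tr, mod,
                    threshold = 0)
  expect_equal(pol_b$prob, max(brute, 1 - brute), tolerance = 1e-6)
})

test_that("polarization on synthetic bundles is near-perfect at defaults", {
  scen <- sim_scenario(n_sites = 60000, seed = 21)
  b <- make_scenario_bundle(scen, mode = "phylo")
  sx <- snp_outgroup_states(b)
  pol <- polarize(sx$alleles, sx$outgroups, scen$tree, scen$model,
                  counts = sx$counts)
  acc <- mean(pol$ancestral[pol$kept] == sx$alleles[pol$kept, 1])
  expect_gte(acc, 0.99)
  expect_gt(mean(pol$kept), 0.75)
})

test_that("ancestral exome reconstruction applies polarized SNPs", {
  ref <- codon_index(c("ATG", "CCT", "GGA", "TTT"))
  # no SNPs: unchanged
  expect_equal(reconstruct_ancestral_exome(ref, integer(0), integer(0),
                                           integer(0)), ref)
  # reference carries the derived allele at site 2: reverted
  out <- reconstruct_ancestral_exome(ref, sites = 2,
                                     anc_codon = "CCA", der_codon = "CCT")
  expect_equal(index_codon(out[2]), "CCA")
  expect_equal(out[-2], ref[-2])
  # conflicting ancestral states at one site: error
  expect_error(reconstruct_ancestral_exome(ref, sites = c(2, 2),
                                           anc_codon = c("CCA", "CCG"),
                                           der_codon = c("CCT", "CCT")),
               "conflicting")
})

test_that("mutational opportunities follow the rate-weighted enumeration", {
  mod <- mutation_model()   # uniform rates
  # flat fitness: everything non-synonymous is nearly neutral
  exome <- codon_index(c("ATG", "CCT", "GGA"))
  opp <- mutational_opportunities(exome, mod, matrix(0, 3, 20))
  expect_equal(unname(opp$P_x), c(0, 1, 0))
  expect_equal(opp$L_syn + sum(opp$L_x), opp$L_tot)
  # single-codon pencil-and-paper oracle: TGG (Trp) under uniform rates.
  # 9 changes: TAG/TGA (stop, dropped), AGG/CGG (Arg), GGG (Gly),
  # TCG (Ser), TTG (Leu), TGC/TGT (Cys) -- no synonymous change exists.
  F <- rep(0, 20)
  F[15] <- 2                     # Arg lifted by 2: B0 (2 changes)
  F[10] <- -9; F[2] <- -9        # Leu, Cys depressed: D0 (3 changes)
  F[16] <- 0.5                   # Ser: N0; Gly stays 0: N0
  opp1 <- mutational_opportunities(codon_index("TGG"), mod,
                                   matrix(F, 1, 20, byrow = TRUE))
  # uniform rates: equal weight per change; shares D0 3/7, N0 2/7, B0 2/7
  expect_equal(unname(opp1$P_x), c(3, 2, 2) / 7)
  expect_equal(opp1$L_syn, 0)
  expect_equal(sum(opp1$P_x), 1)
})

test_that("SNP classification and SFS assembly match ground truth", {
  scen <- sim_scenario(n_sites = 3000, seed = 13, cpg_fraction = 0.25)
  b <- make_scenario_bundle(scen, mode = "population")
  snps <- classify_snps(b$snps, b$profiles)
  # with perfect polarization the classes match the generative labels
  expect_equal(snps$class, b$snp_truth$class_s0)
  opp <- mutational_opportunities(b$exome, scen$model, b$profiles,
                                  cpg_flags = b$cpg_flags,
                                  cpg_multiplier = scen$cpg_multiplier)
  sp <- build_sfs(snps, opp)
  for (cl in c("SYN", "D0", "N0", "B0"))
    expect_equal(sum(sp[[cl]]$xi), sum(snps$class == cl))
  # every SNP lands in exactly one class
  expect_equal(sum(sapply(sp, function(x) sum(x$xi))), nrow(snps))
  # CpG filtering removes exactly the flagged SNPs
  sp_f <- build_sfs(snps, opp, exclude_cpg = TRUE)
  expect_equal(sum(sapply(sp, function(x) sum(x$xi))) -
                 sum(sapply(sp_f, function(x) sum(x$xi))),
               sum(snps$cpg_flag))
  # empty SNP table: all-zero spectra would need an explicit n
  expect_error(build_sfs(snps[0, ], opp), "empty")
  snps2 <- snps; snps2$n[1] <- 12
  expect_error(build_sfs(snps2, opp), "mixed")
})

test_that("hypergeometric subsampling is exact and unbiased", {
  x <- sfs(c(10, 0, 6, 0, 0, 0, 0), n = 8, L = 100, class = "SYN")
  expect_identical(subsample_sfs(x, 8), x)              # m = n identity
  expect_error(subsample_sfs(x, 1), "at least 2")
  # single SNP at i = n/2, m = 2: retained mass P[exactly 1 of 2 derived]
  y <- sfs(c(0, 0, 0, 1, 0, 0, 0), n = 8, L = 10, class = "SYN")
  y2 <- subsample_sfs(y, 2)
  expect_equal(y2$xi, dhyper(1, 4, 4, 2))
  # sampling variant is unbiased for the deterministic one
  set.seed(1)
  acc <- numeric(3)
  for (r in 1:400) acc <- acc + subsample_sfs(x, 4, "sample")$xi
  expect_equal(acc / 400, subsample_sfs(x, 4)$xi, tolerance = 0.06)
})

test_that("Watterson's theta and Ne follow the Achaz formulas", {
  expect_equal(watterson_theta(sfs(5, n = 2, L = 1000)), 0.005)
  expect_equal(ne_estimate(4e-4, 1e-8), 1e4)
  # neutral bundles: theta_S unbiased for its generative expectation
  scen <- sim_scenario(n_sites = 2000, Ne = 5e5, seed = 1)
  prof <- matrix(0, 2000, 20)
  exome <- sample_stationary_exome(prof, scen$model)
  opp <- mutational_opportunities(exome, scen$model, prof)
  # mu_tot excludes stop-gaining changes, so the synonymous-anchored
  # estimator targets theta * mu_tot / L_tot, not raw theta
  target <- scen$theta * opp$mu_tot / opp$L_tot
  est <- replicate(40, {
    scen$seed <- sample.int(1e6, 1)
    poly <- simulate_polymorphism(scen, exome, prof)
    snps <- classify_snps(poly$snps, prof)
    watterson_theta(build_sfs(snps, opp)$SYN)
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - target), 3 * se)
})
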
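test_that("fitness landscape draws behave across concentrations", {
  F1 <- sample_fitness_landscape(200, 0.1, seed = 4)
  F1b <- sample_fitness_landscape(200, 0.1, seed = 4)
  expect_identical(F1, F1b)                       # determinism
  expect_equal(rowMeans(F1), rep(0, 200), tolerance = 1e-12)
  # large concentration approaches neutrality
  Fflat <- sample_fitness_landscape(200, 1e6, seed = 4)
  expect_lt(max(abs(Fflat)), 0.05)
  # small concentration has strictly larger per-site variance
  F10 <- sample_fitness_landscape(1000, 10, seed = 5)
  F01 <- sample_fitness_landscape(1000, 0.1, seed = 5)
  expect_gt(mean(apply(F01, 1, var)), mean(apply(F10, 1, var)))
  expect_error(sample_fitness_landscape(0, 1), "n_sites")
})

test_that("codon evolution is stationary and internally consistent", {
  set.seed(2)
  mod <- hky_model()
  prof <- sample_fitness_landscape(300, 0.5, seed = 2)
  # zero-length tree: leaves identical to the root
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  sim0 <- simulate_alignment(tr0, prof, mod)
  expect_equal(nrow(sim0$events), 0L)
  expect_equal(unclass(sim0$alignment)["a", ],
               unclass(sim0$alignment)["c", ])
  # long single branch: leaf frequencies match the stationary law
  prof1 <- matrix(rep(random_F(3, sd = 1.5), each = 4000), 4000, 20)
  tr1 <- ape::read.tree(text = "(a:8,b:0);")
  sim1 <- simulate_alignment(tr1, prof1, mod)
  pi <- stationary_distribution(codon_rate_matrix(mod, prof1[1, ]))
  freq <- tabulate(unclass(sim1$alignment)["a", ], 61) / 4000
  expect_lt(max(abs(freq - pi)), 4 * sqrt(max(pi * (1 - pi)) / 4000) + 0.01)
  # event log end states reproduce the alignment (internal consistency)
  sim <- simulate_alignment(tiny_tree(), prof, mod)
  ev <- sim$events
  if (nrow(ev)) {
    # every event is a single-nucleotide change between sense codons
    gc <- genetic_code()
    nd <- rowSums(gc$codon_base[ev$from, , drop = FALSE] !=
                    gc$codon_base[ev$to, , drop = FALSE])
    expect_true(all(nd == 1))
  }
})

test_that("terminal branch honors the landscape shift semantics", {
  scen <- sim_scenario(n_sites = 800, seed = 3, shift_fraction = 0)
  prof <- sample_fitness_landscape(800, scen$concentration, seed = 3)
  anc <- sample_stationary_exome(prof, scen$model)
  term <- simulate_terminal_branch(scen, anc, prof, branch_length = 0.3)
  # stable landscape: every substitution's true S equals its S0
  expect_equal(term$substitutions$S_true, term$substitutions$S0)
  expect_false(any(term$shifted))
  # zero branch: nothing happens
  term0 <- simulate_terminal_branch(scen, anc, prof, branch_length = 0)
  expect_equal(nrow(term0$substitutions), 0L)
  expect_equal(term0$exome, anc)
  # full shift with a long branch inflates dN/dS over the stable value
  scen1 <- sim_scenario(n_sites = 5000, seed = 4, shift_fraction = 1)
  prof1 <- sample_fitness_landscape(5000, scen1$concentration, seed = 4)
  anc1 <- sample_stationary_exome(prof1, scen1$model)
  shifted <- simulate_terminal_branch(scen1, anc1, prof1,
                                      branch_length = 0.5)
  scen0 <- scen1; scen0$shift_fraction <- 0
  stable <- simulate_terminal_branch(scen0, anc1, prof1,
                                     branch_length = 0.5)
  dn_ds <- function(term, prof_cls) {
    cnt <- map_substitutions(anc1, term$exome, prof_cls)
    opp <- mutational_opportunities(anc1, scen1$model, prof_cls)
    tab <- dnds_by_class(cnt, opp)
    (sum(tab$D) / sum(tab$L)) / attr(tab, "dS")
  }
  expect_gt(dn_ds(shifted, prof1), dn_ds(stable, prof1))
})

test_that("polymorphism mispolarization and CpG flags are bookkept", {
  scen <- sim_scenario(n_sites = 4000, Ne = 5e5, seed = 6,
                       mispolarization_rate = 0.5)
  prof <- matrix(0, 4000, 20)
  exome <- sample_stationary_exome(prof, scen$model)
  poly <- simulate_polymorphism(scen, exome, prof)
  # epsilon = 0.5 on neutral data: SFS symmetric about n/2 in expectation
  xi <- tabulate(poly$snps$derived_count, scen$n - 1)
  lo <- sum(xi[1:5]); hi <- sum(xi[11:15])
  expect_lt(abs(lo - hi) / sqrt(lo + hi), 4)
  expect_equal(mean(!poly$truth$polarization_correct), 0.5,
               tolerance = 0.06)
  expect_error(simulate_polymorphism(sim_scenario(n = 1), exome, prof))
})

test_that("scenario bundles are reproducible and truth-consistent", {
  scen <- sim_scenario(n_sites = 1500, seed = 11, shift_fraction = 0.3,
                       cpg_fraction = 0.2)
  b1 <- make_scenario_bundle(scen, mode = "phylo")
  b2 <- make_scenario_bundle(scen, mode = "phylo")
  expect_identical(b1, b2)                        # byte-reproducible
  # truth labels recompute from the emitted codons and profiles
  snps <- b1$snps; tru <- b1$snp_truth
  ok <- tru$polarization_correct
  gc <- genetic_code()
  a <- codon_index(snps$ancestral_codon[ok])
  d <- codon_index(snps$derived_codon[ok])
  syn <- gc$aa_index[a] == gc$aa_index[d]
  S0 <- ifelse(syn, 0,
               b1$profiles[cbind(tru$site[ok], gc$aa_index[d])] -
                 b1$profiles[cbind(tru$site[ok], gc$aa_index[a])])
  expect_equal(S0, tru$S0[ok])
  expect_equal(classify_s0(S0, syn), tru$class_s0[ok])
  # stable sites in a shifted bundle keep S_true == S0
  stable_rows <- !b1$shifted[tru$site]
  expect_equal(tru$S_true[stable_rows], tru$S0[stable_rows])
  # shift_fraction 0: every beneficial mutation is non-adaptive
  scen0 <- sim_scenario(n_sites = 1500, seed = 12)
  b0 <- make_scenario_bundle(scen0, mode = "population")
  oc <- oracle_class_table(b0)
  expect_equal(oc$P_B0_given_B, 1)
  expect_equal(unname(oc$precision), rep(1, 3))
})
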
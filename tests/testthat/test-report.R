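make_opp <- function(P = c(D0 = 0.2, N0 = 0.5, B0 = 0.3)) {
  structure(list(L_tot = 300, mu_tot = 3, mu_syn = 0.75,
                 mu_x = P * 2, L_syn = 75, L_x = P * 200, P_x = P),
            class = "opportunity_table")
}

test_that("marginals follow the law of total probability", {
  opp <- make_opp()
  post <- list(D0 = list(D = .8, N = .15, B = .05),
               N0 = list(D = .2, N = .7, B = .1),
               B0 = list(D = .1, N = .4, B = .5))
  expect_equal(marginal_probability(post, opp, "B"),
               .05 * .2 + .1 * .5 + .5 * .3)
  # identical posteriors: marginal equals the shared value
  same <- list(D0 = list(D = .3, N = .5, B = .2),
               N0 = list(D = .3, N = .5, B = .2),
               B0 = list(D = .3, N = .5, B = .2))
  expect_equal(marginal_probability(same, opp, "B"), 0.2)
  # marginals over D/N/B sum to 1
  pr <- precision_recall(post, opp)
  expect_equal(sum(pr$marginal), 1)
})

test_that("precision and recall follow Bayes' rule", {
  opp <- make_opp(c(D0 = 0.5, N0 = 0.3, B0 = 0.2))
  # P[B|B0] = .5, P[B0] = .2, others contribute 0.05 -> check arithmetic
  post <- list(D0 = list(D = 1, N = 0, B = 0),
               N0 = list(D = 0, N = 1, B = 0),
               B0 = list(D = 0, N = .5, B = .5))
  pr <- precision_recall(post, opp)
  expect_equal(unname(pr$recall[["B"]]), .5 * .2 / (.5 * .2))
  # textbook numbers: P[B|B0]=0.5, P[B0]=0.2, P[B]=0.25 -> 0.4
  post2 <- list(D0 = list(D = 1, N = 0, B = .1875),
                N0 = list(D = 0, N = 1, B = .1875),
                B0 = list(D = 0, N = .5, B = .5))
  opp2 <- make_opp(c(D0 = 0.4, N0 = 0.4, B0 = 0.2))
  pr2 <- precision_recall(post2, opp2)
  expect_equal(unname(pr2$marginal[["B"]]), 0.25)
  expect_equal(unname(pr2$recall[["B"]]), 0.4)
  # perfect prediction: all precisions and recalls are 1
  perfect <- list(D0 = list(D = 1, N = 0, B = 0),
                  N0 = list(D = 0, N = 1, B = 0),
                  B0 = list(D = 0, N = 0, B = 1))
  prp <- precision_recall(perfect, make_opp())
  expect_equal(unname(prp$precision), rep(1, 3))
  expect_equal(unname(prp$recall), rep(1, 3))
  # joint-table consistency: sum_x sum_y P[y|x] P[x] = 1
  post3 <- list(D0 = list(D = .6, N = .3, B = .1),
                N0 = list(D = .25, N = .55, B = .2),
                B0 = list(D = .05, N = .45, B = .5))
  opp3 <- make_opp()
  joint <- sum(vapply(names(opp3$P_x), function(x)
    sum(unlist(post3[[x]])) * opp3$P_x[[x]], numeric(1)))
  expect_equal(joint, 1)
  # zero marginal flags the recall
  zero <- list(D0 = list(D = 1, N = 0, B = 0),
               N0 = list(D = 0, N = 1, B = 0),
               B0 = list(D = 0, N = 1, B = 0))
  expect_warning(prz <- precision_recall(zero, make_opp()), "undefined")
  expect_true(is.na(prz$recall[["B"]]))
})

test_that("the generative oracle agrees with brute-force enumeration", {
  scen <- sim_scenario(n_sites = 40, seed = 17, shift_fraction = 0.4)
  b <- make_scenario_bundle(scen, mode = "population")
  oc <- oracle_class_table(b)
  # brute force over every codon change of every site
  gc <- genetic_code()
  joint <- matrix(0, 3, 3, dimnames = dimnames(oc$joint))
  for (s in seq_along(b$exome)) {
    a <- b$exome[s]
    for (pos in 1:3) for (nb in setdiff(1:4, gc$codon_base[a, pos])) {
      tri <- gc$codon_base[a, ]; tri[pos] <- nb
      bb <- match(paste(BASES[tri], collapse = ""), gc$codons)
      if (is.na(bb)) next
      if (gc$aa_index[a] == gc$aa_index[bb]) next
      w <- scen$model$rates[gc$codon_base[a, pos], nb]
      S0 <- b$profiles[s, gc$aa_index[bb]] - b$profiles[s, gc$aa_index[a]]
      St <- b$profiles_true[s, gc$aa_index[bb]] -
        b$profiles_true[s, gc$aa_index[a]]
      joint[classify_s0(S0), sub("0", "", classify_s0(St))] <-
        joint[classify_s0(S0), sub("0", "", classify_s0(St))] + w
    }
  }
  expect_equal(oc$joint, joint, tolerance = 1e-10)
  expect_equal(oc$P_B0_given_B, joint["B0", "B"] / sum(joint[, "B"]))
})

test_that("oracle P[B0|B] decreases monotonically in the shift fraction", {
  vals <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    scen <- sim_scenario(n_sites = 20000, seed = 23, shift_fraction = f)
    oracle_class_table(make_scenario_bundle(scen, mode = "population"))$P_B0_given_B
  })
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
})

test_that("shift-fraction calibration hits its target", {
  scen <- sim_scenario(n_sites = 1000, seed = 31)
  cal <- calibrate_shift_fraction(scen, 0.3, mc_sites = 100000)
  scen2 <- sim_scenario(n_sites = 300000, seed = 32,
                        shift_fraction = cal$shift_fraction)
  oc <- oracle_class_table(make_scenario_bundle(scen2, mode = "population"))
  expect_equal(oc$P_B0_given_B, 0.3, tolerance = 0.02)
})

test_that("the pipeline is deterministic and scores against truth", {
  scen <- sim_scenario(n_sites = 50000, Ne = 3e5, seed = 41)
  b <- make_scenario_bundle(scen, mode = "population")
  r1 <- run_pipeline(b, seed = 5, dfe_form = "discrete")
  r2 <- run_pipeline(b, seed = 5, dfe_form = "discrete")
  expect_identical(r1, r2)
  sc <- score_against_truth(r1, b)
  expect_equal(sc$oracle$P_B0_given_B, 1)     # stable landscape
  expect_true(all(unlist(sc$errors) >= 0))
  # report serialization round-trips through the JSON mirror
  tmp <- tempfile()
  write_report(r1, tmp)
  j <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(j$theta_S, r1$theta_S, tolerance = 1e-9)
  expect_equal(j$recall$B, unname(r1$recall[["B"]]), tolerance = 1e-9)
})
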
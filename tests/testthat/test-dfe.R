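test_that("DFE density respects bounds, mixture weights and shapes", {
  expect_error(dfe_model(beta_d = -0.5), "beta_d")
  expect_error(dfe_model(b = 0.1), "b must")
  expect_error(dfe_model(p_b = 1.2), "p_b")
  expect_error(dfe_model(beta_b = 0.5), "beta_b")
  expect_error(dfe_model(epsilon = 0.6), "epsilon")
  # p_b = 0: no density above zero
  m0 <- dfe_model(p_b = 0)
  expect_equal(dfe_density(m0, c(0.5, 2, 10)), rep(0, 3))
  # b = 1 reduces the deleterious branch to an exponential
  m1 <- dfe_model(beta_d = -5, b = 1, p_b = 0)
  S <- seq(-20, 0, by = 0.5)
  expect_equal(dfe_density(m1, S), dexp(-S, 1 / 5), tolerance = 1e-12)
  # density integrates to 1 for random valid parameters
  set.seed(2)
  for (r in 1:5) {
    m <- dfe_model(beta_d = -exp(runif(1, 0, 5)), b = runif(1, 0.2, 2),
                   p_b = runif(1), beta_b = exp(runif(1, 0, 3)))
    I <- integrate(function(s) dfe_density(m, s), -Inf, 0,
                   rel.tol = 1e-9)$value +
      integrate(function(s) dfe_density(m, s), 0, Inf,
                rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
})

test_that("expected SFS reproduces the neutral law and epsilon mixing", {
  neutral <- discrete_dfe(masses = 1, edges = c(-1, 1), reps = 0)
  E <- expected_sfs(neutral, theta = 1, n = 4, L = 100)
  expect_equal(E, c(100, 50, 100 / 3), tolerance = 1e-10)
  # epsilon = 0.5 symmetrizes
  half <- discrete_dfe(masses = 1, edges = c(-1, 1), reps = 0,
                       epsilon = 0.5)
  Eh <- expected_sfs(half, theta = 1, n = 16, L = 100)
  expect_equal(Eh, rev(Eh), tolerance = 1e-12)
  # matches the simulator's mean over replicates at a selected value
  scen <- sim_scenario(n_sites = 2000, Ne = 5e5, seed = 1)
  prof <- matrix(0, 2000, 20); prof[, 4] <- -2   # every Glu change... keep flat
  prof <- matrix(0, 2000, 20)
  exome <- sample_stationary_exome(prof, scen$model)
  tb <- mutselpop:::.sim_tables(scen$model)
  w <- sum(scen$theta * tb$mu[exome, ][tb$to[exome, ] > 0])
  acc <- numeric(scen$n - 1)
  for (r in 1:25) {
    scen$seed <- r
    acc <- acc + tabulate(
      simulate_polymorphism(scen, exome, prof)$snps$derived_count,
      scen$n - 1)
  }
  E2 <- expected_sfs(neutral, theta = w / 100, n = 16, L = 100)
  expect_equal(acc / 25, E2, tolerance = 0.06)
})

test_that("expected divergence weights fixation rates correctly", {
  point <- function(s) discrete_dfe(masses = 1, edges = c(s - 1, s + 1),
                                    reps = s)
  expect_equal(expected_divergence(point(0), 0.01, 1000), 10)
  # S = 1.24 fixes 1.745 times the neutral rate
  expect_equal(expected_divergence(point(1.24), 0.01, 1000), 17.45,
               tolerance = 0.01)
  expect_lt(expected_divergence(point(-20), 0.01, 1000), 1e-5)
})

test_that("class posteriors have the closed forms and partition", {
  expect_equal(unname(class_probabilities(dfe_model(p_b = 0))[["B"]]), 0)
  # p_b = 1, beta_b = 1: P[B] = e^{-1}; quadrature confirms
  m <- dfe_model(p_b = 1, beta_b = 1)
  p <- class_probabilities(m)
  expect_equal(unname(p[["B"]]), exp(-1), tolerance = 1e-12)
  quad <- integrate(function(s) dfe_density(m, s), 1, Inf)$value
  expect_equal(unname(p[["B"]]), quad, tolerance = 1e-6)
  set.seed(3)
  for (r in 1:10) {
    mr <- dfe_model(beta_d = -exp(runif(1, 0, 4)), b = runif(1, 0.2, 3),
                    p_b = runif(1), beta_b = exp(runif(1, 0, 3)))
    pr <- class_probabilities(mr)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    quad_D <- integrate(function(s) dfe_density(mr, s), -Inf, -1,
                        rel.tol = 1e-9)$value
    expect_equal(unname(pr[["D"]]), quad_D, tolerance = 1e-5)
  }
  # discrete: masses aggregate by bins straddling the thresholds
  d <- discrete_dfe(masses = c(.1, .2, .3, .1, .1, .15, .05))
  pd <- class_probabilities(d)
  expect_equal(unname(pd), c(.6, .2, .2))
})

test_that("likelihood is invariant to rescaling absorbed by theta", {
  true <- dfe_model(-30, 1, 0.2, 2)
  set.seed(7)
  Ex <- expected_sfs(true, 0.01, 16, 1e5)
  Es <- 0.01 * 1e5 / (1:15)
  xi_x <- rpois(15, Ex); xi_s <- rpois(15, Es)
  f1 <- fit_dfe(sfs(xi_x, 16, 1e5, "NS"), sfs(xi_s, 16, 1e5, "SYN"),
                starts = 2, seed = 1)
  f2 <- fit_dfe(sfs(xi_x, 16, 1e7, "NS"), sfs(xi_s, 16, 1e7, "SYN"),
                starts = 2, seed = 1)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$theta / f2$theta, 100, tolerance = 1e-4)
  expect_equal(coef(f1)[1:4], coef(f2)[1:4], tolerance = 1e-3)
})

test_that("fitting is self-consistent and degrades gracefully", {
  true <- dfe_model(-30, 1, 0.2, 2)
  Ex <- expected_sfs(true, 0.01, 16, 1e6)
  Es <- 0.01 * 1e6 / (1:15)
  # noise-free expected data: the truth is an optimum; refitting the
  # fitted model's expectation reproduces the same optimum
  f <- fit_dfe(sfs(Ex, 16, 1e6, "NS"), sfs(Es, 16, 1e6, "SYN"),
               starts = 4, seed = 1)
  E2 <- predict(f, "sfs")
  f2 <- fit_dfe(sfs(E2, 16, 1e6, "NS"), sfs(Es, 16, 1e6, "SYN"),
                starts = 4, seed = 2)
  expect_equal(coef(f2)[1:4], coef(f)[1:4], tolerance = 0.05)
  expect_equal(class_probabilities(f2), class_probabilities(f),
               tolerance = 0.01)
  # neutral-only data under the full model: fitted mass concentrates
  # around zero.  The family's bounds (deleterious mean <= -1, beneficial
  # mean >= 1) forbid a point mass at 0, so the best it can do is pile up
  # against the bounds: N is the dominant class and nearly all density
  # sits within a few units of zero, but P[N] cannot reach 1.
  En <- 0.01 * 1e6 / (1:15)
  fn <- fit_dfe(sfs(En, 16, 1e6, "NS"), sfs(En, 16, 1e6, "SYN"),
                starts = 4, seed = 1)
  pn <- class_probabilities(fn)
  expect_gt(pn[["N"]], pn[["D"]])
  expect_gt(pn[["N"]], pn[["B"]])
  near0 <- integrate(function(s) dfe_density(fn$model, s), -4, 0)$value +
    integrate(function(s) dfe_density(fn$model, s), 0, 4)$value
  expect_gt(near0, 0.8)
  # all-zero selected SFS: degenerate, p_b pinned at 0
  fz <- fit_dfe(sfs(rep(0, 15), 16, 1e6, "NS"), sfs(Es, 16, 1e6, "SYN"),
                starts = 2, seed = 1)
  expect_true(fz$degenerate)
  expect_equal(fz$model$p_b, 0)
  expect_error(fit_dfe(sfs(Ex, 16, 1e6, "NS"),
                       sfs(Es[1:11], 12, 1e6, "SYN")),
               "share n")
})

test_that("discrete and parametric fits agree on parametric data", {
  # robustness property: class probabilities within +-0.05 when the data
  # really come from the parametric family
  true <- dfe_model(-30, 1, 0.2, 2)
  Ex <- expected_sfs(true, 0.01, 16, 1e6)
  Es <- 0.01 * 1e6 / (1:15)
  set.seed(11)
  spx <- sfs(rpois(15, Ex), 16, 1e6, "NS")
  sps <- sfs(rpois(15, Es), 16, 1e6, "SYN")
  fp <- fit_dfe(spx, sps, form = "parametric", seed = 1)
  fd <- fit_dfe(spx, sps, form = "discrete", seed = 1)
  pp <- class_probabilities(fp); pd <- class_probabilities(fd)
  # the two forms agree to within the discrete grid's bin resolution:
  # the class thresholds are bin edges, so each class mass carries a
  # one-bin quantization of order 0.05-0.1
  expect_lt(max(abs(pp - pd)), 0.10)
  expect_equal(which.max(pp), which.max(pd))
})

test_that("the mispolarization nuisance is estimable", {
  true <- dfe_model(-30, 1, 0.2, 2, epsilon = 0.15)
  Ex <- expected_sfs(true, 0.01, 16, 1e6)
  Es <- (1 - 0.15) * 0.01 * 1e6 / (1:15) + 0.15 * 0.01 * 1e6 / (15:1)
  set.seed(12)
  f <- fit_dfe(sfs(rpois(15, Ex), 16, 1e6, "NS"),
               sfs(rpois(15, Es), 16, 1e6, "SYN"),
               epsilon = NA, starts = 6, seed = 3)
  expect_equal(f$model$epsilon, 0.15, tolerance = 0.05)
})
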
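## Distribution of fitness effects: the gamma + exponential mixture,
## its expected SFS / divergence under PRF sampling, maximum-likelihood
## fitting to class-stratified spectra, and class posteriors.

#' Parametric DFE model (reflected gamma + exponential mixture)
#'
#' The density of the scaled selection coefficient S of a new mutation:
#' with probability \eqn{1 - p_b}, \eqn{-S} is gamma distributed with mean
#' \eqn{-\beta_d} and shape \eqn{b} (the deleterious branch,
#' \eqn{S \le 0}); with probability \eqn{p_b}, S is exponential with mean
#' \eqn{\beta_b} (the beneficial branch, \eqn{S > 0}).  An optional
#' mispolarization nuisance \eqn{\epsilon} mixes each frequency class i
#' with its mirror n-i in the expected SFS.
#'
#' @param beta_d mean of the S <= 0 branch (<= -1).
#' @param b gamma shape (>= 0.2).
#' @param p_b probability that S > 0 (in `[0, 1]`).
#' @param beta_b mean of the S > 0 branch (>= 1).
#' @param epsilon mispolarization probability (in `[0, 0.5]`).
#' @return object of class `dfe_model` (form `"parametric"`).
#' @export
dfe_model <- function(beta_d = -100, b = 0.5, p_b = 0.05, beta_b = 2,
                      epsilon = 0) {
  if (beta_d > -1) stop("beta_d must be <= -1")
  if (b < 0.2) stop("b must be >= 0.2")
  if (p_b < 0 || p_b > 1) stop("p_b must be in [0, 1]")
  if (beta_b < 1) stop("beta_b must be >= 1")
  if (epsilon < 0 || epsilon > 0.5) stop("epsilon must be in [0, 0.5]")
  structure(list(form = "parametric", beta_d = beta_d, b = b, p_b = p_b,
                 beta_b = beta_b, epsilon = epsilon),
            class = "dfe_model")
}

#' Discretized DFE on a fixed S grid
#'
#' A non-parametric alternative: probability masses on bins whose edges
#' straddle the class thresholds at -1 and 1, each bin represented by a
#' point mass at a fixed representative coefficient.
#'
#' @param masses non-negative bin masses (normalized internally).
#' @param edges bin edges (default `c(-Inf,-100,-10,-1,0,1,10,Inf)`).
#' @param reps representative S per bin (defaults to geometric/arithmetic
#'   midpoints).
#' @param epsilon mispolarization probability.
#' @return object of class `dfe_model` (form `"discrete"`).
#' @export
discrete_dfe <- function(masses = NULL,
                         edges = c(-Inf, -100, -10, -1, 0, 1, 10, Inf),
                         reps = NULL, epsilon = 0) {
  k <- length(edges) - 1
  if (is.null(masses)) masses <- rep(1 / k, k)
  if (length(masses) != k) stop("need one mass per bin")
  if (any(masses < 0)) stop("masses must be non-negative")
  if (is.null(reps)) {
    reps <- numeric(k)
    for (j in seq_len(k)) {
      lo <- edges[j]; hi <- edges[j + 1]
      reps[j] <- if (is.infinite(lo)) -sqrt(abs(hi) * 10 * abs(hi))
      else if (is.infinite(hi)) sqrt(lo * 10 * lo)
      else if (lo * hi > 0) sign(lo) * sqrt(abs(lo * hi))
      else (lo + hi) / 2
    }
    zero <- reps == 0
    reps[zero] <- (edges[which(zero)] + edges[which(zero) + 1]) / 2
  }
  structure(list(form = "discrete", masses = masses / sum(masses),
                 edges = edges, reps = reps, epsilon = epsilon),
            class = "dfe_model")
}

#' Density of the parametric DFE
#'
#' @param model a parametric [dfe_model()].
#' @param S numeric vector.
#' @return density values (the discrete form has no density; use
#'   `model$masses`).
#' @export
dfe_density <- function(model, S) {
  stopifnot(inherits(model, "dfe_model"))
  if (model$form != "parametric")
    stop("the discrete DFE has no density; use model$masses")
  out <- numeric(length(S))
  neg <- S <= 0
  out[neg] <- (1 - model$p_b) *
    stats::dgamma(-S[neg], shape = model$b,
                  scale = -model$beta_d / model$b)
  out[!neg] <- model$p_b * stats::dexp(S[!neg], rate = 1 / model$beta_b)
  out
}

## quadrature nodes and weights for E_phi[f(S)]
.dfe_nodes <- function(model, nodes = 64) {
  if (model$form == "discrete")
    return(list(S = model$reps, w = model$masses))
  gl <- gauss_legendre(nodes)
  u <- gl$nodes
  Sg <- -qgamma(u, shape = model$b, scale = -model$beta_d / model$b)
  Se <- qexp(u, rate = 1 / model$beta_b)
  list(S = c(Sg, Se),
       w = c((1 - model$p_b) * gl$weights, model$p_b * gl$weights))
}

## epsilon-mixing of an expected SFS vector
.mix_eps <- function(E, eps) {
  if (eps == 0) return(E)
  (1 - eps) * E + eps * rev(E)
}

#' Expected site-frequency spectrum under a DFE
#'
#' PRF expectation \eqn{\hat E_i = L\theta \int \phi(S) H_i(S)\, dS} for
#' \eqn{i = 1..n-1}, with Gauss-Legendre quadrature in frequency space and
#' quantile-based quadrature over each mixture component of the DFE;
#' mispolarization mixes \eqn{\hat E_i} with \eqn{\hat E_{n-i}}.
#'
#' @param model a [dfe_model()].
#' @param theta scaled mutation rate per site.
#' @param n sample size (chromosomes).
#' @param L opportunity (sites).
#' @param nodes quadrature nodes.
#' @return numeric vector of expected counts, length `n - 1`.
#' @export
#' @examples
#' ## neutral point mass: L*theta/i
#' m <- discrete_dfe(masses = 1, edges = c(-1, 1), reps = 0)
#' expected_sfs(m, theta = 1, n = 4, L = 100)   # 100, 50, 33.3
expected_sfs <- function(model, theta, n, L, nodes = 64) {
  stopifnot(n >= 2, theta > 0, L > 0)
  nd <- .dfe_nodes(model, nodes)
  H <- prf_expected_shape(nd$S, n, nodes)
  E <- L * theta * as.numeric(nd$w %*% H)
  .mix_eps(E, model$epsilon)
}

#' Expected substitution count under a DFE
#'
#' \eqn{E[D] = L\, d_{neutral} \int \phi(S)\, \omega(S)\, dS}: the
#' class's expected divergence given the observed neutral rate, weighting
#' each coefficient by its relative fixation rate.
#'
#' @param model a [dfe_model()].
#' @param d_neutral observed neutral divergence per site
#'   (\eqn{D_{syn}/L_{syn}}).
#' @param L opportunity (sites).
#' @param nodes quadrature nodes.
#' @return expected substitution count.
#' @export
expected_divergence <- function(model, d_neutral, L, nodes = 64) {
  stopifnot(d_neutral >= 0, L > 0)
  nd <- .dfe_nodes(model, nodes)
  L * d_neutral * sum(nd$w * fixation_rate(nd$S))
}

#' Class posteriors of a DFE
#'
#' The probabilities that a mutation drawn from the fitted DFE is
#' deleterious at the population scale (\eqn{S < -1}), nearly neutral
#' (\eqn{-1 < S < 1}) or beneficial (\eqn{S > 1}).  Closed forms for the
#' parametric mixture: \eqn{P[B] = p_b e^{-1/\beta_b}} and \eqn{P[D]}
#' from the upper tail of the gamma at 1.
#'
#' @param model a [dfe_model()] or [fit_dfe()] result.
#' @return named numeric vector `c(D =, N =, B =)` summing to 1.
#' @export
class_probabilities <- function(model) {
  if (inherits(model, "dfe_fit")) model <- model$model
  stopifnot(inherits(model, "dfe_model"))
  if (model$form == "parametric") {
    PD <- (1 - model$p_b) *
      pgamma(1, shape = model$b, scale = -model$beta_d / model$b,
             lower.tail = FALSE)
    PB <- model$p_b * exp(-1 / model$beta_b)
  } else {
    PD <- sum(model$masses[model$reps < -1])
    PB <- sum(model$masses[model$reps > 1])
  }
  c(D = PD, N = 1 - PD - PB, B = PB)
}

## Halton quasi-random sequence (for seeded multi-starts)
.halton <- function(i, base) {
  f <- 1; r <- 0
  while (i > 0) {
    f <- f / base
    r <- r + f * (i %% base)
    i <- i %/% base
  }
  r
}

#' Fit a DFE to a selected and a neutral site-frequency spectrum
#'
#' Maximum likelihood under independent Poisson counts per frequency
#' class: the synonymous SFS anchors the per-site mutation rate
#' \eqn{\theta} (profiled analytically, as both spectra are linear in it)
#' and the selected SFS informs the DFE.  Optionally, observed
#' substitution counts add two Poisson divergence terms whose neutral
#' rate is likewise profiled.  Bounded quasi-Newton optimization from
#' multiple quasi-random starts.
#'
#' @param sfs_x selected-class [sfs()].
#' @param sfs_syn synonymous [sfs()] (same `n`).
#' @param divergence optional list with `D_x`, `D_syn` (substitution
#'   counts; opportunities are taken from the two SFS objects) to fit
#'   polymorphism + divergence jointly.
#' @param form `"parametric"` (gamma + exponential mixture) or
#'   `"discrete"` (masses on a fixed S grid).
#' @param epsilon `NA` to estimate the mispolarization nuisance, or a
#'   fixed value in `[0, 0.5]` (default 0).
#' @param starts number of optimization starts.
#' @param seed seed for the quasi-random start shift.
#' @param nodes quadrature nodes.
#' @param edges,reps bin layout for the discrete form (see
#'   [discrete_dfe()]).
#' @return object of class `dfe_fit`: the fitted `model`, profiled
#'   `theta` (and `d_neutral` when divergence is used), `loglik`,
#'   `convergence`, per-start log-likelihoods, and the data.
#' @export
fit_dfe <- function(sfs_x, sfs_syn, divergence = NULL,
                    form = c("parametric", "discrete"),
                    epsilon = 0, starts = 8, seed = 1, nodes = 64,
                    edges = c(-Inf, -100, -10, -1, 0, 1, 10, Inf),
                    reps = NULL) {
  form <- match.arg(form)
  stopifnot(inherits(sfs_x, "sfs"), inherits(sfs_syn, "sfs"))
  if (sfs_x$L <= 0 || sfs_syn$L <= 0)
    stop("both spectra need positive opportunity L")
  if (sfs_x$n != sfs_syn$n) stop("selected and neutral SFS must share n")
  n <- sfs_x$n
  i <- seq_len(n - 1)
  basis_H <- function(S) prf_expected_shape(S, n, nodes)
  est_eps <- is.na(epsilon)
  degenerate <- sum(sfs_x$xi) == 0

  ## unit-theta expectations and profiled-likelihood evaluator
  neutral_shape <- 1 / i
  if (form == "discrete")
    return(.fit_dfe_discrete(sfs_x, sfs_syn, divergence, epsilon, edges,
                             reps, nodes, starts, seed))
  make_model <- function(p) {
    eps <- if (est_eps) p[5] else epsilon
    dfe_model(beta_d = -exp(p[1]), b = p[2],
              p_b = if (degenerate) 0 else p[3],
              beta_b = exp(p[4]), epsilon = eps)
  }
  negll <- function(p) {
    mod <- tryCatch(make_model(p), error = function(e) NULL)
    if (is.null(mod)) return(1e10)
    nd <- .dfe_nodes(mod, nodes)
    H <- basis_H(nd$S)
    ux <- sfs_x$L * .mix_eps(as.numeric(nd$w %*% H), mod$epsilon)
    us <- sfs_syn$L * .mix_eps(neutral_shape, mod$epsilon)
    ll <- 0
    if (!is.null(divergence)) {
      Iw <- sum(nd$w * fixation_rate(nd$S))
      dhat <- (divergence$D_syn + divergence$D_x) /
        (sfs_syn$L + sfs_x$L * Iw)
      ll <- ll + dpois(divergence$D_syn, dhat * sfs_syn$L, log = TRUE) +
        dpois(divergence$D_x, pmax(dhat * sfs_x$L * Iw, 1e-300),
              log = TRUE)
    }
    th <- (sum(sfs_x$xi) + sum(sfs_syn$xi)) / (sum(ux) + sum(us))
    ll <- ll + sum(dpois(round(sfs_syn$xi), pmax(th * us, 1e-300),
                         log = TRUE)) +
      sum(dpois(round(sfs_x$xi), pmax(th * ux, 1e-300), log = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  lower <- c(0, 0.2, 0, 0, if (est_eps) 0)
  upper <- c(log(1e6), 10, 1, log(1e4), if (est_eps) 0.5)
  np <- length(lower)
  shift <- .substream_seed(seed, "dfe-starts") / 2147483647
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)[seq_len(np)]
  start_ll <- numeric(starts)
  best <- NULL
  for (k2 in seq_len(starts)) {
    u <- vapply(bases, function(bb) (.halton(k2, bb) + shift) %% 1,
                numeric(1))
    p0 <- lower + u * (upper - lower)
    if (k2 == 1 && form == "parametric")
      p0 <- pmin(pmax(c(log(100), 0.5, 0.05, log(2),
                        if (est_eps) 0.01), lower), upper)
    o <- tryCatch(
      optim(p0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300)),
      error = function(e) list(value = Inf, convergence = 99L))
    start_ll[k2] <- -o$value
    if (is.null(best) || o$value < best$value) best <- o
  }
  model <- make_model(best$par)
  nd <- .dfe_nodes(model, nodes)
  H <- basis_H(nd$S)
  ux <- sfs_x$L * .mix_eps(as.numeric(nd$w %*% H), model$epsilon)
  us <- sfs_syn$L * .mix_eps(neutral_shape, model$epsilon)
  th <- (sum(sfs_x$xi) + sum(sfs_syn$xi)) / (sum(ux) + sum(us))
  dhat <- if (!is.null(divergence)) {
    Iw <- sum(nd$w * fixation_rate(nd$S))
    (divergence$D_syn + divergence$D_x) / (sfs_syn$L + sfs_x$L * Iw)
  } else NA_real_
  structure(list(model = model, theta = th, d_neutral = dhat,
                 loglik = -best$value, convergence = best$convergence,
                 start_loglik = start_ll, form = form, n = n,
                 degenerate = degenerate,
                 data = list(sfs_x = sfs_x, sfs_syn = sfs_syn,
                             divergence = divergence)),
            class = "dfe_fit")
}

## Discrete-DFE maximum likelihood.
##
## In the rate parameterization c_j = theta * m_j >= 0 the Poisson means
## of both spectra are linear in c, so the (no-divergence) log-likelihood
## is concave and a single gradient run finds the global optimum.  The
## frequency response of nearby S bins is nearly collinear, which leaves
## flat ridges in the likelihood; a small negative-entropy penalty on the
## masses picks the maximum-entropy point of the optimal set so the fit
## is reproducible and does not park mass in arbitrary corners.
.fit_dfe_discrete <- function(sfs_x, sfs_syn, divergence, epsilon, edges,
                              reps, nodes, starts, seed,
                              entropy_penalty = 1) {
  n <- sfs_x$n
  i <- seq_len(n - 1)
  proto <- discrete_dfe(edges = edges, reps = reps)
  k <- length(proto$masses)
  U <- t(prf_expected_shape(proto$reps, n, nodes))    # (n-1) x k
  om <- fixation_rate(proto$reps)
  h0 <- 1 / i
  est_eps <- is.na(epsilon)

  fit_for_eps <- function(eps) {
    Ue <- (1 - eps) * U + eps * U[rev(i), , drop = FALSE]
    he <- (1 - eps) * h0 + eps * rev(h0)
    negll <- function(c) {
      th <- sum(c)
      if (th <= 0) return(1e10)
      Ax <- pmax(sfs_x$L * as.numeric(Ue %*% c), 1e-300)
      As <- pmax(sfs_syn$L * th * he, 1e-300)
      ll <- sum(sfs_x$xi * log(Ax) - Ax) + sum(sfs_syn$xi * log(As) - As)
      if (!is.null(divergence)) {
        m <- c / th
        Iw <- sum(m * om)
        dh <- (divergence$D_syn + divergence$D_x) /
          (sfs_syn$L + sfs_x$L * Iw)
        ll <- ll + divergence$D_syn * log(max(dh * sfs_syn$L, 1e-300)) -
          dh * sfs_syn$L +
          divergence$D_x * log(max(dh * sfs_x$L * Iw, 1e-300)) -
          dh * sfs_x$L * Iw
      }
      m <- c / th
      pen <- entropy_penalty * sum(ifelse(m > 0, m * log(m), 0))
      if (!is.finite(ll)) return(1e10)
      -(ll - pen)
    }
    grad <- if (is.null(divergence)) function(c) {
      th <- sum(c)
      Ax <- pmax(sfs_x$L * as.numeric(Ue %*% c), 1e-300)
      As <- pmax(sfs_syn$L * th * he, 1e-300)
      g <- as.numeric(t(Ue) %*% ((sfs_x$xi / Ax - 1) * sfs_x$L)) +
        sum((sfs_syn$xi / As - 1) * sfs_syn$L * he)
      m <- c / th
      ent <- sum(ifelse(m > 0, m * log(m), 0))
      gpen <- entropy_penalty * (ifelse(m > 0, log(m), 0) - ent) / th
      -(g - gpen)
    } else NULL
    c0 <- rep(max(sum(sfs_syn$xi) /
                    (sfs_syn$L * sum(h0)), 1e-8) / k, k)
    o <- optim(c0, negll, grad, method = "L-BFGS-B",
               lower = rep(1e-12, k),
               control = list(maxit = 500, factr = 1e4))
    o
  }

  if (est_eps) {
    oe <- optimize(function(e) fit_for_eps(e)$value, c(0, 0.5), tol = 1e-4)
    eps <- oe$minimum
    o <- fit_for_eps(eps)
  } else {
    eps <- epsilon
    o <- fit_for_eps(eps)
  }
  cc <- o$par
  th <- sum(cc)
  model <- discrete_dfe(cc / th, edges = edges, reps = reps, epsilon = eps)
  dhat <- if (!is.null(divergence)) {
    Iw <- sum(model$masses * om)
    (divergence$D_syn + divergence$D_x) / (sfs_syn$L + sfs_x$L * Iw)
  } else NA_real_
  structure(list(model = model, theta = th, d_neutral = dhat,
                 loglik = -o$value, convergence = o$convergence,
                 start_loglik = -o$value, form = "discrete", n = n,
                 degenerate = sum(sfs_x$xi) == 0,
                 data = list(sfs_x = sfs_x, sfs_syn = sfs_syn,
                             divergence = divergence)),
            class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat("DFE fit (", x$form, "), class ", x$data$sfs_x$class,
      if (x$degenerate) " [degenerate: empty selected SFS]", "\n",
      sep = "")
  print(round(coef(x), 4))
  cat(sprintf("theta = %.4g, logLik = %.2f (convergence %d)\n",
              x$theta, x$loglik, x$convergence))
  p <- class_probabilities(x)
  cat(sprintf("P[D] = %.3f, P[N] = %.3f, P[B] = %.3f\n",
              p["D"], p["N"], p["B"]))
  invisible(x)
}

#' @export
coef.dfe_fit <- function(object, ...) {
  m <- object$model
  if (m$form == "parametric")
    c(beta_d = m$beta_d, b = m$b, p_b = m$p_b, beta_b = m$beta_b,
      epsilon = m$epsilon, theta = object$theta)
  else c(setNames(m$masses, paste0("mass", seq_along(m$masses))),
         epsilon = m$epsilon, theta = object$theta)
}

#' @export
logLik.dfe_fit <- function(object, ...) {
  np <- if (object$form == "parametric") 5 else length(object$model$masses)
  structure(object$loglik, df = np, class = "logLik")
}

#' @export
predict.dfe_fit <- function(object, type = c("sfs", "divergence"), ...) {
  type <- match.arg(type)
  d <- object$data
  if (type == "sfs")
    expected_sfs(object$model, object$theta, object$n, d$sfs_x$L)
  else {
    if (is.na(object$d_neutral)) stop("fit has no divergence component")
    expected_divergence(object$model, object$d_neutral, d$sfs_x$L)
  }
}

#' @export
simulate.dfe_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  E <- predict(object, "sfs")
  replicate(nsim, rpois(length(E), E), simplify = FALSE)
}
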
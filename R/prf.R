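## Poisson random field machinery.
##
## Under PRF theory, mutations with scaled selection coefficient S enter a
## population as a Poisson stream and sojourn at population frequency x
## with density
##     f(x) = theta * (1 - e^{-S(1-x)}) / (x (1-x) (1 - e^{-S})),
## reducing to theta/x for S = 0.  Binomial sampling of n chromosomes gives
## the expected unfolded SFS
##     E[xi_i] = theta * H_i(S),
##     H_i(S)  = Int_0^1 C(n,i) x^{i-1} (1-x)^{n-i-1} g(S, x) dx,
## with g the selective sojourn factor.  Both the polymorphism simulator
## and the DFE fitter are built on H_i, which keeps the generator and the
## fitter's forward model identical by construction.

#' Gauss-Legendre nodes and weights
#'
#' Golub-Welsch nodes/weights on (0, 1), used for all frequency-space
#' quadrature.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights` (each length `n`).
#' @export
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- (e$values + 1) / 2
  weights <- e$vectors[1, ]^2            # on [0,1]: 2 v1^2 / 2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

## Sojourn factor g(S, x) = (1 - e^{-S(1-x)}) / (1 - e^{-S}); 1-x at S = 0.
## Stable for strongly negative S via g = (e^{Sx} - e^S) / (1 - e^S).
.prf_g <- function(S, x) {
  out <- numeric(length(S))
  tiny <- abs(S) < 1e-8
  out[tiny] <- 1 - x[tiny]
  pos <- !tiny & S > 0
  out[pos] <- expm1(-S[pos] * (1 - x[pos])) / expm1(-S[pos])
  neg <- !tiny & S < 0
  out[neg] <- (exp(S[neg] * x[neg]) - exp(S[neg])) / (-expm1(S[neg]))
  out
}

## Quadrature context for sample size n: nodes x, and the binomial basis
## B[k, i] = w_k C(n,i) x_k^{i-1} (1-x_k)^{n-i-1}, so H = G %*% B with
## G[j, k] = g(S_j, x_k).  Memoized: the basis is hit thousands of times
## per DFE fit.
.basis_cache <- new.env(parent = emptyenv())

.prf_basis <- function(n, nodes = 64) {
  key <- paste(n, nodes)
  hit <- .basis_cache[[key]]
  if (!is.null(hit)) return(hit)
  gl <- gauss_legendre(nodes)
  x <- gl$nodes
  i <- seq_len(n - 1)
  B <- outer(x, i, function(x, i)
    choose(n, i) * x^(i - 1) * (1 - x)^(n - i - 1)) * gl$weights
  out <- list(n = n, x = x, w = gl$weights, B = B)
  .basis_cache[[key]] <- out
  out
}

#' Expected sampled SFS shape per unit theta
#'
#' Computes \eqn{H_i(S)} for \eqn{i = 1, \dots, n-1}: the expected number
#' of segregating sites with derived-allele count \eqn{i} in a sample of
#' `n` chromosomes, per unit of the scaled per-change mutation rate
#' \eqn{\theta}.  The neutral value is \eqn{1/i}.  For strongly
#' deleterious S the sojourn mass concentrates near frequency 0 and the
#' quadrature interval is shrunk accordingly.
#'
#' @param S numeric vector of scaled selection coefficients.
#' @param n sample size (chromosomes), at least 2.
#' @param nodes quadrature nodes in frequency space.
#' @return length(S) x (n-1) matrix of \eqn{H_i(S)}.
#' @export
#' @examples
#' prf_expected_shape(0, n = 4) * 100   # 100, 50, 33.3 for L*theta = 100
prf_expected_shape <- function(S, n, nodes = 64) {
  stopifnot(n >= 2)
  basis <- .prf_basis(n, nodes)
  .prf_H(S, basis)
}

.prf_H <- function(S, basis) {
  n <- basis$n
  K <- length(S)
  H <- matrix(0, K, n - 1)
  std <- S >= -40
  if (any(std)) {
    G <- matrix(0, sum(std), length(basis$x))
    Sm <- rep(S[std], times = length(basis$x))
    Xm <- rep(basis$x, each = sum(std))
    G[] <- .prf_g(Sm, Xm)
    H[std, ] <- G %*% basis$B
  }
  if (any(!std)) {
    ## shrink the interval to (0, c), c = 40/|S|: g ~ e^{Sx} is negligible
    ## beyond, and the fixed nodes would miss the boundary layer
    Sv <- S[!std]
    cc <- 40 / abs(Sv)
    K2 <- length(Sv)
    nx <- length(basis$x)
    Xk <- cc %o% basis$x                       # K2 x nx scaled nodes
    A <- .prf_g(rep(Sv, nx), as.vector(Xk))
    dim(A) <- c(K2, nx)
    A <- A * rep(basis$w, each = K2) * cc
    Hs <- matrix(0, K2, n - 1)
    for (i in seq_len(n - 1)) {
      Hs[, i] <- rowSums(A * choose(n, i) * Xk^(i - 1) *
                           (1 - Xk)^(n - i - 1))
    }
    H[!std, ] <- Hs
  }
  H
}

## Interpolator for the total expected number of segregating sites per unit
## theta, sum_i H_i(S), on an asinh(S)/log grid; used by the polymorphism
## simulator to price millions of candidate changes cheaply.
.prf_total_interp <- function(n, nodes = 64, lim = 2e4, grid = 3000) {
  basis <- .prf_basis(n, nodes)
  t <- seq(-asinh(lim), asinh(lim), length.out = grid)
  S <- sinh(t)
  tot <- rowSums(.prf_H(S, basis))
  stopifnot(all(tot > 0))
  logtot <- log(tot)
  function(Sq) {
    tq <- asinh(pmin(pmax(Sq, -lim), lim))
    exp(approx(t, logtot, tq)$y)
  }
}

#' Forward Wright-Fisher site-frequency spectrum (validation oracle)
#'
#' A deliberately naive discrete Wright-Fisher simulator of independent
#' biallelic sites under genic selection, used only to validate the PRF
#' quadrature: a haploid population of `M` chromosomes with per-generation
#' selective advantage `s = S / (2M)` matches the diffusion with scaled
#' coefficient `S = 4 N_e s` (diploid convention, `M = 2 N_e`).  Mutations
#' enter as singletons at rate `theta / 2` per generation, so the
#' stationary expected sampled SFS is `theta * prf_expected_shape(S, n)`.
#'
#' @param S scaled selection coefficient (diffusion scale).
#' @param theta scaled mutation rate of the simulated mutation stream.
#' @param n sample size (chromosomes) for the sampled SFS.
#' @param M haploid population size (default 200, i.e. N = 100 diploids).
#' @param generations number of generations after burn-in over which the
#'   SFS is accumulated.
#' @param burnin burn-in generations (default `10 * M`).
#' @return numeric vector of length `n - 1`: mean sampled SFS counts per
#'   generation (comparable to `theta * prf_expected_shape(S, n)`).
#' @export
forward_wf_sfs <- function(S, theta, n, M = 200, generations = 4000,
                           burnin = 10 * M) {
  s <- S / (2 * M)
  influx <- theta / 2
  freq <- numeric(0)
  acc <- numeric(n - 1)
  nacc <- 0L
  for (g in seq_len(burnin + generations)) {
    if (length(freq)) {
      p <- freq * (1 + s) / (1 + freq * s)
      freq <- rbinom(length(freq), M, p) / M
      freq <- freq[freq > 0 & freq < 1]
    }
    nnew <- rpois(1, influx)
    if (nnew) freq <- c(freq, rep(1 / M, nnew))
    if (g > burnin) {
      if (length(freq)) {
        i <- rbinom(length(freq), n, freq)
        i <- i[i > 0 & i < n]
        if (length(i)) acc <- acc + tabulate(i, n - 1)
      }
      nacc <- nacc + 1L
    }
  }
  acc / nacc
}
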
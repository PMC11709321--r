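## Mutation-selection codon machinery: site rate matrices, stationary
## distributions, scaled selection coefficients and their classes.

#' Relative fixation rate of a scaled selection coefficient
#'
#' The Halpern-Bruno factor \eqn{\omega(S) = S / (1 - e^{-S})}: the rate of
#' fixation of a mutation with scaled selection coefficient \eqn{S = 4N_e s}
#' relative to a neutral mutation.  \eqn{\omega(0) = 1} by continuity;
#' inputs with \eqn{|S| < 10^{-8}} are routed to that limit.
#'
#' @param S numeric vector of scaled selection coefficients.
#' @return numeric vector of relative fixation rates.
#' @export
#' @examples
#' fixation_rate(0)      # 1
#' fixation_rate(1.24)   # 1.745: weakly beneficial fixes faster
fixation_rate <- function(S) {
  out <- numeric(length(S))
  tiny <- abs(S) < 1e-8
  out[tiny] <- 1
  lo <- !tiny & S < -500          # e^{-S} overflows; rate is 0 anyway
  out[lo] <- 0
  ok <- !tiny & !lo
  out[ok] <- S[ok] / (-expm1(-S[ok]))
  out
}

#' Site-specific codon rate matrix under a mutation-selection model
#'
#' Builds the 61 x 61 generator \eqn{q_{a\to b}} over sense codons for one
#' site: zero for codon pairs differing at more than one position,
#' \eqn{\mu_{a\to b}} for synonymous single-nucleotide changes, and
#' \eqn{\mu_{a\to b}\,\Delta F / (1 - e^{-\Delta F})} for non-synonymous
#' ones, where \eqn{\Delta F = F_b - F_a} is the difference in scaled
#' amino-acid log fitness.  Mutations to stop codons are excluded from the
#' state space.
#'
#' @param model a [mutation_model()].
#' @param F numeric vector of 20 scaled amino-acid log fitnesses
#'   (alphabetical one-letter order); any additive constant cancels.
#' @return object of class `codon_rate_matrix`: list with `Q` (61 x 61,
#'   zero row sums), `model`, and the gauge-normalized `F`.
#' @export
codon_rate_matrix <- function(model, F) {
  stopifnot(inherits(model, "nuc_model"), length(F) == 20)
  if (!all(is.finite(F))) stop("non-finite fitness values")
  F <- F - mean(F)
  gc <- genetic_code()
  nb <- gc$neighbors[!gc$neighbors$stop_gain, ]
  mu <- model$rates[cbind(nb$from_base, nb$to_base)]
  dF <- ifelse(nb$syn, 0, F[nb$aa_to] - F[nb$aa_from])
  Q <- matrix(0, 61, 61, dimnames = list(gc$codons, gc$codons))
  Q[cbind(nb$from, nb$to)] <- mu * fixation_rate(dF)
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, model = model, F = F),
            class = "codon_rate_matrix")
}

#' Stationary distribution of a codon rate matrix
#'
#' For a reversible mutation model the closed form
#' \eqn{\pi_c \propto \psi_c e^{F_{aa(c)}}} is used, where \eqn{\psi_c} is
#' the product of equilibrium base frequencies over the codon's three
#' positions.  For a non-reversible model the closed form does not hold and
#' the null space of the generator is solved numerically (with a warning).
#'
#' @param m a `codon_rate_matrix`.
#' @return numeric vector of 61 stationary codon probabilities.
#' @export
stationary_distribution <- function(m) {
  stopifnot(inherits(m, "codon_rate_matrix"))
  gc <- genetic_code()
  if (m$model$reversible) {
    psi <- m$model$pi[gc$codon_base[, 1]] *
      m$model$pi[gc$codon_base[, 2]] *
      m$model$pi[gc$codon_base[, 3]]
    w <- psi * exp(m$F[gc$aa_index] - max(m$F))
    pi <- w / sum(w)
  } else {
    warning("non-reversible mutation model: solving for the stationary ",
            "distribution numerically")
    A <- rbind(t(m$Q), rep(1, 61))
    pi <- qr.solve(A, c(rep(0, 61), 1))
    pi <- pmax(pi, 0)
    pi <- pi / sum(pi)
  }
  names(pi) <- gc$codons
  pi
}

#' Scaled selection coefficient of a single-nucleotide codon change
#'
#' \eqn{S_0 = F_b - F_a}, the fitness difference between the target and
#' source amino acids on the site's landscape, and its class:
#' deleterious `D0` (\eqn{S_0 < -1}), nearly-neutral `N0`
#' (\eqn{-1 \le S_0 \le 1}; the boundaries are assigned to `N0` so the
#' classes partition the line), beneficial non-adaptive `B0`
#' (\eqn{S_0 > 1}), or `SYN` for synonymous changes (\eqn{S_0 = 0}).
#'
#' @param F numeric vector of 20 scaled amino-acid log fitnesses.
#' @param from,to source and target codons (strings or indices); must
#'   differ at exactly one nucleotide position and not be stop codons.
#' @return list with `S0` and `class`.
#' @export
#' @examples
#' F <- rep(0, 20); F[16] <- 1.5; F[13] <- -0.8   # S, P
#' scaled_selection(F, "TCT", "CCT")              # Ser -> Pro: S0 = -2.3, D0
scaled_selection <- function(F, from, to) {
  stopifnot(length(F) == 20)
  gc <- genetic_code()
  a <- if (is.character(from)) codon_index(from) else as.integer(from)
  b <- if (is.character(to)) codon_index(to) else as.integer(to)
  if (is.na(a) || is.na(b)) stop("codons must be sense codons")
  ndiff <- sum(gc$codon_base[a, ] != gc$codon_base[b, ])
  if (ndiff != 1) stop("codons must differ at exactly one position")
  if (gc$aa_index[a] == gc$aa_index[b])
    return(list(S0 = 0, class = "SYN"))
  S0 <- F[gc$aa_index[b]] - F[gc$aa_index[a]]
  list(S0 = S0, class = classify_s0(S0))
}

#' Classify scaled selection coefficients
#'
#' @param S0 numeric vector.
#' @param syn optional logical vector marking synonymous changes (`SYN`).
#' @return character vector in `{"D0","N0","B0","SYN"}`.
#' @export
classify_s0 <- function(S0, syn = NULL) {
  cls <- ifelse(S0 < -1, "D0", ifelse(S0 > 1, "B0", "N0"))
  if (!is.null(syn)) cls[syn] <- "SYN"
  cls
}

#' Gauge-normalize site fitness profiles
#'
#' Profiles are identifiable only up to an additive constant per site; the
#' package fixes the gauge by mean-centering the 20 fitnesses of each site.
#'
#' @param F a numeric vector of 20 fitnesses or an L x 20 matrix
#'   (rows = sites, columns = amino acids in alphabetical order).
#' @return same shape, mean-centered per site.
#' @export
gauge_normalize <- function(F) {
  if (is.matrix(F)) {
    stopifnot(ncol(F) == 20)
    F - rowMeans(F)
  } else {
    stopifnot(length(F) == 20)
    F - mean(F)
  }
}
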
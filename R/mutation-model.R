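## 4x4 nucleotide mutation models (GTR family, plus arbitrary matrices).

#' Nucleotide mutation model
#'
#' Builds a 4 x 4 nucleotide mutation rate matrix over bases A, C, G, T.
#' The usual entry point is the GTR parameterization
#' \eqn{\mu_{ab} = \rho_{ab}\,\psi_b} with symmetric exchangeabilities
#' \eqn{\rho} and equilibrium base frequencies \eqn{\psi}, which is
#' time-reversible by construction.  An arbitrary rate matrix (possibly
#' non-reversible) can be supplied via `rates`; its equilibrium is then
#' found numerically.
#'
#' Rates are normalized so that the expected number of mutations per
#' nucleotide site per unit time at equilibrium is 1
#' (\eqn{\sum_a \psi_a \sum_{b \ne a} \mu_{ab} = 1}), so branch lengths are
#' in expected mutations per site.  Set `normalize = FALSE` to keep the
#' input scale.
#'
#' @param exch symmetric exchangeabilities, either a named vector with
#'   names among `c("AC","AG","AT","CG","CT","GT")` (missing entries 1) or
#'   a symmetric 4 x 4 matrix. Ignored when `rates` is given.
#' @param pi equilibrium base frequencies (A, C, G, T); default uniform.
#' @param rates optional full 4 x 4 rate matrix with non-negative
#'   off-diagonal entries (diagonal is recomputed).
#' @param normalize logical; rescale to one mutation per site per unit time.
#' @return An object of class `nuc_model`: list with `rates` (4 x 4, zero
#'   row sums), `pi` (equilibrium frequencies) and `reversible`.
#' @export
#' @examples
#' mutation_model()                          # Jukes-Cantor
#' hky_model(kappa = 4, pi = c(.3, .2, .2, .3))
mutation_model <- function(exch = NULL, pi = NULL, rates = NULL,
                           normalize = TRUE) {
  if (is.null(rates)) {
    if (is.null(pi)) pi <- rep(0.25, 4)
    stopifnot(length(pi) == 4, all(pi > 0))
    pi <- pi / sum(pi)
    R <- matrix(1, 4, 4)
    if (!is.null(exch)) {
      if (is.matrix(exch)) {
        stopifnot(all(dim(exch) == 4), isTRUE(all.equal(exch, t(exch))))
        R <- exch
      } else {
        pairs <- c(AC = "AC", AG = "AG", AT = "AT",
                   CG = "CG", CT = "CT", GT = "GT")
        idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
        for (k in seq_along(pairs)) {
          v <- if (pairs[k] %in% names(exch)) exch[[pairs[k]]] else 1
          R[idx[k, 1], idx[k, 2]] <- R[idx[k, 2], idx[k, 1]] <- v
        }
      }
    }
    Q <- R * rep(pi, each = 4)
    diag(Q) <- 0
    reversible <- TRUE
  } else {
    Q <- as.matrix(rates)
    stopifnot(all(dim(Q) == 4))
    diag(Q) <- 0
    if (any(Q < 0)) stop("off-diagonal mutation rates must be non-negative")
    pi <- .stationary_4x4(Q)
    reversible <- max(abs(pi * Q - t(pi * Q))) < 1e-9 * max(Q)
  }
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    rate <- -sum(pi * diag(Q))
    if (rate <= 0) stop("degenerate mutation model (zero total rate)")
    Q <- Q / rate
  }
  dimnames(Q) <- list(BASES, BASES)
  names(pi) <- BASES
  structure(list(rates = Q, pi = pi, reversible = reversible),
            class = "nuc_model")
}

## equilibrium of a 4x4 generator by null space of t(Q)
.stationary_4x4 <- function(Qoff) {
  Q <- Qoff
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 4))
  b <- c(rep(0, 4), 1)
  pi <- qr.solve(A, b)
  if (any(pi < -1e-10)) stop("mutation model has no positive equilibrium")
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' @rdname mutation_model
#' @param kappa transition/transversion rate ratio for `hky_model`.
#' @export
hky_model <- function(kappa = 4, pi = c(0.3, 0.2, 0.2, 0.3)) {
  mutation_model(exch = c(AG = kappa, CT = kappa), pi = pi)
}

#' Test detailed balance of a nucleotide model
#'
#' @param model a `nuc_model`.
#' @param tol tolerance on \eqn{|\psi_a \mu_{ab} - \psi_b \mu_{ba}|}.
#' @return logical.
#' @export
is_reversible <- function(model, tol = 1e-9) {
  F <- model$pi * model$rates
  max(abs(F - t(F))) < tol * max(abs(model$rates))
}

#' @export
print.nuc_model <- function(x, ...) {
  cat("Nucleotide mutation model (",
      if (x$reversible) "reversible" else "non-reversible", ")\n", sep = "")
  print(round(x$rates, 4))
  cat("equilibrium:", paste(sprintf("%s=%.3f", BASES, x$pi),
                            collapse = " "), "\n")
  invisible(x)
}
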
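#' Flexible intention set
#'
#' Intentions are functions of the current belief that predict a plausible
#' future belief; their prediction errors act as attractors inside the
#' belief dynamics. The two stock intentions are linear maps on the 9-d
#' belief `(arm, target, home)`:
#' * `target`: sets the arm block equal to the target block (reach);
#' * `home`: sets the arm block equal to the home block (return to the home
#'   button).
#' Both leave the target and home blocks untouched, so the corresponding
#' prediction-error rows are structurally zero. Gains follow the
#' `(1 - beta, beta)` parameterization: `beta = 0` follows the reach
#' intention only, `beta = 1` the home intention only.
#'
#' @param beta intention balance in `[0, 1]`.
#' @param mappings optional custom list of 9 x 9 matrices (named); defaults
#'   to the target/home pair.
#' @param gains optional explicit nonnegative gains (overrides `beta`).
#' @return object of class `intention_set`.
#' @export
intention_set <- function(beta = 0.1, mappings = NULL, gains = NULL) {
  if (is.null(mappings))
    mappings <- list(target = intention_matrix("target"),
                     home = intention_matrix("home"))
  if (is.null(gains)) {
    stopifnot(beta >= 0, beta <= 1, length(mappings) == 2)
    gains <- c(1 - beta, beta)
  }
  stopifnot(length(gains) == length(mappings), all(gains >= 0))
  names(gains) <- names(mappings)
  structure(list(mappings = mappings, gains = gains),
            class = "intention_set")
}

#' Stock intention mapping matrices
#'
#' `target` replaces the arm block of the belief with its target block;
#' `home` replaces it with the home block; both are identity on the other
#' blocks (hence idempotent).
#'
#' @param which `"target"` or `"home"`.
#' @return a 9 x 9 matrix.
#' @export
intention_matrix <- function(which = c("target", "home")) {
  which <- match.arg(which)
  M <- diag(9)
  src <- if (which == "target") 4:6 else 7:9
  M[1:3, ] <- 0
  M[cbind(1:3, src)] <- 1
  M
}

#' Intention predictions H
#'
#' Column `k` is the intended belief `I_k mu`.
#'
#' @param set an [intention_set()].
#' @param mu 9-vector belief.
#' @return 9 x K matrix.
#' @export
compute_intentions <- function(set, mu) {
  if (any(!is.finite(mu))) stop("mu must be finite")
  H <- vapply(set$mappings, function(M) as.numeric(M %*% mu), numeric(9))
  colnames(H) <- names(set$mappings)
  H
}

#' Intention prediction errors E_i
#'
#' Column `k` is `h_k - mu`: the discrepancy between the intended and the
#' current belief. Rows 4..9 (target and home blocks) are exactly zero for
#' the stock intentions.
#'
#' @inheritParams compute_intentions
#' @return 9 x K matrix.
#' @export
intention_errors <- function(set, mu) {
  compute_intentions(set, mu) - mu
}

#' Dynamics-function prediction errors and the attractor contribution
#'
#' The dynamics function of intention `k` is `f_k(mu) = lambda e_ik`, so the
#' dynamics prediction error is `eps_mu_k = mu_prime - lambda e_ik` and the
#' gain-weighted attractor contribution to the first-order belief update is
#' `eps_i = -sum_k gamma_k (mu_prime - lambda e_ik)`. With the
#' `(1 - beta, beta)` gains this is
#' `-mu_prime + lambda ((1 - beta) e_it + beta e_ih)`.
#'
#' @param mu_prime 9-vector first-order belief.
#' @param E_i 9 x K matrix of intention prediction errors.
#' @param lambda attractor gain, per step (`0` freezes the attractors, e.g.
#'   during the delay period).
#' @param gains K nonnegative intention gains, or `NULL` to use
#'   `c(1 - beta, beta)`.
#' @param beta intention balance (used when `gains` is `NULL`).
#' @return list with `eps_mu` (9 x K) and `eps_i` (9-vector).
#' @export
dynamics_error <- function(mu_prime, E_i, lambda, gains = NULL, beta = 0.1) {
  stopifnot(lambda >= 0)
  E_i <- as.matrix(E_i)
  if (is.null(gains)) {
    stopifnot(beta >= 0, beta <= 1, ncol(E_i) == 2)
    gains <- c(1 - beta, beta)
  }
  eps_mu <- mu_prime - lambda * E_i
  eps_i <- -as.numeric(eps_mu %*% gains)
  list(eps_mu = eps_mu, eps_i = eps_i)
}
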
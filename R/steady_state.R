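#' Propagate a distribution through the chain
#'
#' Applies the one-step update `pi(t+1) = pi(t) P` a given number of times.
#'
#' @param pi0 Numeric probability vector (row-vector convention), length
#'   equal to `nrow(P)`.
#' @param P Row-stochastic transition matrix.
#' @param steps Non-negative integer number of steps; 0 returns `pi0`.
#' @return The propagated probability vector.
#' @examples
#' m <- valence_model(0.7, 0.1, 0.3, 0.2, 0.4)
#' P <- transition_matrix(m)
#' propagate(rep(1/8, 8), P, 100)
#' @export
propagate <- function(pi0, P, steps) {
  check_stochastic(P)
  if (length(pi0) != nrow(P)) {
    stop("length(pi0) must equal nrow(P)", call. = FALSE)
  }
  stopifnot(steps >= 0, steps == round(steps))
  v <- as.numeric(pi0)
  for (k in seq_len(steps)) v <- as.numeric(v %*% P)
  v
}

#' Stationary distribution of a finite chain
#'
#' Solves the balance equations `pi = pi P` with the normalization
#' `sum(pi) = 1` as a direct linear system (transposed balance equations with
#' the normalization row substituted). For an irreducible aperiodic chain the
#' solution is unique and equals the vector of long-run time fractions per
#' state. The residual `max |pi P - pi|` is verified against `tol`.
#'
#' @param P Row-stochastic transition matrix (any size).
#' @param tol Residual tolerance for the solved fixed point.
#' @return Probability vector, named after the columns of `P` if labelled.
#' @examples
#' stationary_distribution(mood_matrix(0.8))  # (0.5, 0.5) for any r
#' @export
stationary_distribution <- function(P, tol = 1e-12) {
  check_stochastic(P)
  n <- nrow(P)
  A <- t(P) - diag(n)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi_bar <- tryCatch(solve(A, b), error = function(e) {
    stop("stationary solve failed (singular system): ", conditionMessage(e),
         call. = FALSE)
  })
  resid <- max(abs(as.numeric(pi_bar %*% P) - pi_bar))
  if (resid > tol) {
    stop("stationary solve residual ", format(resid), " exceeds ",
         format(tol), call. = FALSE)
  }
  pi_bar <- as.numeric(pi_bar)
  names(pi_bar) <- colnames(P)
  pi_bar
}

#' Closed-form steady-state probability of positive valence
#'
#' Evaluates the exact rational expression for the stationary probability of
#' positive valence as a function of `alpha`, `beta`, `omega` and `r`. The
#' event-persistence parameter `s` does not enter: the long-run valence is
#' shaped by the attention paid to external events, not by how fast the
#' events themselves churn. The expression is kept in its tabulated grouped
#' form rather than an algebraically simplified one, so that it can be
#' cross-validated verbatim against the numerical stationary solve.
#'
#' All arguments are vectorized.
#'
#' @param alpha,beta,omega,r Parameters in (0, 1); recycled to a common
#'   length.
#' @return The stationary probability that V = 1.
#' @seealso [pi_v1_simplified()] for the `r = 0.5` / `alpha = beta` special
#'   case.
#' @examples
#' pi_v1_closed_form(alpha = 0.3, beta = 0.3, omega = 0.4, r = 0.7)  # 0.5
#' @export
pi_v1_closed_form <- function(alpha, beta, omega, r) {
  a <- alpha; b <- beta; w <- omega
  num <- w * (3 * a * w + b * w - b - 2 * w) * (2 * r - 1) / 4 -
    a * w * (5 * r / 2 - 7 / 4) + (a + w) * (r - 1)
  den <- w^2 * (a + b - 1) * (2 * r - 1) - w * (a + b) * (3 * r - 2) +
    (a + b + 2 * w) * (r - 1)
  if (any(abs(den) < 1e-14)) {
    stop("vanishing denominator in the closed-form expression", call. = FALSE)
  }
  num / den
}

#' Simplified steady-state positive-valence probability
#'
#' The closed form reduces, when `r = 0.5` or `alpha = beta`, to
#' `(omega - alpha (omega - 1)) / (2 omega - (alpha + beta)(omega - 1))`.
#' In this regime a positive valence prevails exactly when `alpha > beta`,
#' and `alpha = beta` gives 0.5. The denominator is strictly positive on the
#' open parameter cube. Vectorized.
#'
#' @param alpha,beta,omega Parameters in (0, 1).
#' @return The stationary probability that V = 1 in the reduced regime.
#' @examples
#' pi_v1_simplified(0.9, 0.1, 0.5)  # 0.95 / 1.5
#' @export
pi_v1_simplified <- function(alpha, beta, omega) {
  (omega - alpha * (omega - 1)) / (2 * omega - (alpha + beta) * (omega - 1))
}

# analytic egosyntonicity balance: stationary mass on the V == M states
# minus mass on the V != M states; syntonic states are 1, 2, 7, 8
delta_ego_analytic <- function(pi_bar) {
  2 * sum(pi_bar[c(1L, 2L, 7L, 8L)]) - 1
}

#' Steady-state summary of a valence model
#'
#' Builds the joint transition matrix (by both constructions, verified to
#' agree entrywise to 1e-12), solves for the stationary distribution, and
#' derives the scalar summaries:
#'
#' * `pi_v1`, `pi_v0` — stationary probability of positive / negative
#'   valence (mass on states 5-8 and 1-4);
#' * `delta_ego` — difference between the long-run fractions of time spent
#'   egosyntonic (V = M) and egodystonic, computed from the stationary masses
#'   (ergodicity equates time fractions with stationary probabilities);
#' * `mood_marginal`, `event_marginal` — both (0.5, 0.5) for every valid
#'   parameter set, since the component chains are symmetric.
#'
#' The numerical `pi_v1` is checked against the closed-form expression; a
#' mismatch beyond 1e-10 signals an internal transcription bug and raises an
#' error rather than returning silently inconsistent output.
#'
#' @param object A [valence_model()] object.
#' @param ... Unused.
#' @return An object of class `"summary.valence_model"`: a list with
#'   `params`, `pi_bar`, `pi_v1`, `pi_v0`, `delta_ego`, `mood_marginal`,
#'   `event_marginal`.
#' @examples
#' summary(valence_model(0.5, 0.1, 0.8, 0.2, 0.5))
#' @export
summary.valence_model <- function(object, ...) {
  P <- transition_matrix(object, method = "composed")
  Pp <- transition_matrix(object, method = "printed")
  if (max(abs(P - Pp)) > 1e-12) {
    stop("internal inconsistency: the two joint-matrix constructions ",
         "disagree beyond 1e-12", call. = FALSE)
  }
  pi_bar <- stationary_distribution(P)
  pi_v1 <- sum(pi_bar[5:8])
  p <- object$params
  pv1_cf <- pi_v1_closed_form(p[["alpha"]], p[["beta"]], p[["omega"]],
                              p[["r"]])
  if (abs(pi_v1 - pv1_cf) > 1e-10) {
    stop("internal inconsistency: closed-form pi_v1 (", format(pv1_cf),
         ") and stationary-solve pi_v1 (", format(pi_v1),
         ") disagree beyond 1e-10", call. = FALSE)
  }
  st <- state_space()
  res <- list(
    params = p,
    pi_bar = pi_bar,
    pi_v1 = pi_v1,
    pi_v0 = 1 - pi_v1,
    delta_ego = delta_ego_analytic(pi_bar),
    mood_marginal = c(M0 = sum(pi_bar[st$M == 0]),
                      M1 = sum(pi_bar[st$M == 1])),
    event_marginal = c(E0 = sum(pi_bar[st$E == 0]),
                       E1 = sum(pi_bar[st$E == 1]))
  )
  class(res) <- "summary.valence_model"
  res
}

#' @export
print.summary.valence_model <- function(x, digits = 6, ...) {
  p <- x$params
  cat("Steady state of the valence-mood-event chain\n")
  cat(sprintf("  parameters: r=%g s=%g alpha=%g beta=%g omega=%g\n",
              p[["r"]], p[["s"]], p[["alpha"]], p[["beta"]], p[["omega"]]))
  cat("  stationary distribution:\n")
  print(round(x$pi_bar, digits))
  cat(sprintf("  P(positive valence)  pi_v1    = %.*f\n", digits, x$pi_v1))
  cat(sprintf("  P(negative valence)  pi_v0    = %.*f\n", digits, x$pi_v0))
  cat(sprintf("  egosyntonicity bal.  delta_ego = %+.*f\n", digits,
              x$delta_ego))
  cat(sprintf("  mood marginal  (M0, M1) = (%.*f, %.*f)\n", digits,
              x$mood_marginal[1], digits, x$mood_marginal[2]))
  cat(sprintf("  event marginal (E0, E1) = (%.*f, %.*f)\n", digits,
              x$event_marginal[1], digits, x$event_marginal[2]))
  invisible(x)
}
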
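#' Simulate a trajectory of the joint chain
#'
#' Samples a seeded trajectory of the eight-state (V, M, E) chain by inverse
#' CDF draws from successive rows of the joint transition matrix, using one
#' random generator for the whole run so that a single seed fully determines
#' the trajectory. Sampling uses the composed joint matrix, so the simulated
#' law agrees exactly with the analytic chain.
#'
#' The initial state is drawn according to `init`:
#' `"uniform"` (default) draws uniformly over the eight states,
#' `"stationary"` draws from the stationary distribution, and `"fixed:k"`
#' (k in 1..8) starts deterministically in state k.
#'
#' @param object A [valence_model()] object.
#' @param nsim Number of transition steps (the trajectory has `nsim + 1`
#'   states including the initial one). Default 500000, the length used for
#'   the empirical egosyntonicity estimates in the phenotype analysis.
#' @param seed Integer seed; if non-NULL the RNG state is set from it and
#'   restored afterwards, following the convention of [stats::simulate()].
#' @param init Initial-state mode: `"uniform"`, `"stationary"` or
#'   `"fixed:<index>"`.
#' @param ... Unused.
#' @return A data frame of class `"valence_trajectory"` with columns `step`
#'   (0..nsim), `state` (1..8), `V`, `M`, `E`, `syntonic` (logical), and
#'   attributes `params`, `seed`, `init`.
#' @examples
#' m <- valence_model(0.5, 0.1, 0.8, 0.2, 0.5)
#' tr <- simulate(m, nsim = 1000, seed = 42)
#' delta_ego_empirical(tr)
#' @export
simulate.valence_model <- function(object, nsim = 500000L, seed = NULL,
                                   init = "uniform", ...) {
  stopifnot(nsim >= 1, nsim == round(nsim))
  if (!is.null(seed)) {
    if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
      stop("seed must be a single integer", call. = FALSE)
    }
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
  }
  P <- transition_matrix(object, method = "composed")
  cum <- t(apply(P, 1, cumsum))
  cum[, 8] <- 1  # guard against rounding at the top of the CDF

  s0 <- parse_init(init, P)
  states <- integer(nsim + 1L)
  states[1L] <- s0
  u <- stats::runif(nsim)
  st <- s0
  for (i in seq_len(nsim)) {
    # inverse CDF: number of cumulative cells strictly below the draw
    st <- 1L + sum(cum[st, ] < u[i])
    states[i + 1L] <- st
  }

  sp <- state_space()
  out <- data.frame(step = 0:nsim, state = states,
                    V = sp$V[states], M = sp$M[states], E = sp$E[states],
                    syntonic = sp$syntonic[states])
  attr(out, "params") <- object$params
  attr(out, "seed") <- seed
  attr(out, "init") <- init
  class(out) <- c("valence_trajectory", "data.frame")
  out
}

parse_init <- function(init, P) {
  if (identical(init, "uniform")) {
    sample.int(8L, 1L)
  } else if (identical(init, "stationary")) {
    sample.int(8L, 1L, prob = stationary_distribution(P))
  } else if (is.character(init) && grepl("^fixed:[1-8]$", init)) {
    as.integer(sub("^fixed:", "", init))
  } else {
    stop("init must be 'uniform', 'stationary' or 'fixed:<1-8>'",
         call. = FALSE)
  }
}

#' Empirical egosyntonicity balance of a trajectory
#'
#' Computes the fractions of steps spent egosyntonic (V = M) and egodystonic
#' (V != M), and their difference delta_ego, over the trajectory after
#' discarding an optional initial segment. The default `discard = 0` uses
#' the whole run: with trajectories of hundreds of thousands of steps the
#' initial-state bias is negligible and no burn-in is applied.
#'
#' @param trajectory A `"valence_trajectory"` from
#'   [simulate.valence_model()], or any data frame with a logical `syntonic`
#'   column.
#' @param discard Number of initial states to drop before averaging.
#' @return A list with `frac_syntonic`, `frac_dystonic`, `delta_ego_hat`,
#'   `n_steps` (number of states retained).
#' @export
delta_ego_empirical <- function(trajectory, discard = 0L) {
  stopifnot(is.data.frame(trajectory), "syntonic" %in% names(trajectory),
            discard >= 0, discard == round(discard))
  syn <- trajectory$syntonic
  if (discard >= length(syn)) {
    stop("discard leaves an empty trajectory segment", call. = FALSE)
  }
  syn <- syn[(discard + 1L):length(syn)]
  fs <- mean(syn)
  list(frac_syntonic = fs, frac_dystonic = 1 - fs,
       delta_ego_hat = 2 * fs - 1, n_steps = length(syn))
}

#' Empirical state occupation frequencies
#'
#' Fraction of trajectory states spent in each of the eight joint states;
#' converges to the stationary distribution by ergodicity.
#'
#' @inheritParams delta_ego_empirical
#' @return Named numeric vector of length 8 summing to 1.
#' @export
state_frequencies <- function(trajectory, discard = 0L) {
  stopifnot(is.data.frame(trajectory), "state" %in% names(trajectory))
  st <- trajectory$state
  if (discard >= length(st)) {
    stop("discard leaves an empty trajectory segment", call. = FALSE)
  }
  st <- st[(discard + 1L):length(st)]
  freq <- tabulate(st, nbins = 8L) / length(st)
  names(freq) <- state_labels()
  freq
}
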
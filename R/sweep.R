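#' Default parameter grid for the phenotype sweep
#'
#' The sweep varies `alpha`, `beta`, `r` and `omega` over
#' {0.01, 0.1, 0.2, ..., 0.9, 0.99} — eleven values per parameter, the nine
#' interior decimal steps plus the two near-boundary extremes — giving
#' 11^4 = 14641 combinations, with the event persistence fixed at
#' `s = 0.1` (external situations change rapidly; the steady-state valence
#' is independent of `s` in any case).
#'
#' @param values Grid values applied to each swept parameter.
#' @param s Fixed event-persistence value.
#' @return A list of class `"ego_grid"` with elements `alpha`, `beta`, `r`,
#'   `omega` (the per-parameter value vectors) and `s`.
#' @examples
#' g <- phenotype_grid()
#' length(g$alpha)^4  # 14641
#' @export
phenotype_grid <- function(values = c(0.01, seq(0.1, 0.9, by = 0.1), 0.99),
                           s = 0.1) {
  values <- round(values, 10)  # keep decimal grid keys exact
  stopifnot(all(values > 0 & values < 1), s > 0, s < 1)
  structure(list(alpha = values, beta = values, r = values, omega = values,
                 s = s),
            class = "ego_grid")
}

#' Classify a parameter combination into a behavioural phenotype
#'
#' Assigns one of four classes from the signs of `pi_v1 - 0.5` (does the
#' individual spend most time in positive valence?) and `delta_ego` (do they
#' spend most time egosyntonic?):
#'
#' * `BH` (balanced happy): `pi_v1 > 0.5`, `delta_ego > 0`
#' * `SD` (self-deluded): `pi_v1 < 0.5`, `delta_ego > 0`
#' * `CT` (chronically troubled): `pi_v1 < 0.5`, `delta_ego < 0`
#' * `TH` (troubled happy): `pi_v1 > 0.5`, `delta_ego < 0`
#'
#' Values within `tol` of the class boundaries are labelled `"boundary"`
#' rather than silently assigned — exact ties (the whole `alpha = beta`
#' plane has `pi_v1 = 0.5`) are real degeneracies, and for simulated
#' `delta_ego` a wider guard band keeps Monte Carlo noise from fabricating a
#' phenotype. Vectorized.
#'
#' @param pi_v1 Stationary positive-valence probability in [0, 1].
#' @param delta_ego Egosyntonicity balance in [-1, 1].
#' @param tol Half-width of the boundary band; default 1e-9 suits analytic
#'   values, 0.02 is recommended for 500000-step empirical estimates.
#' @return Character vector over {"BH", "SD", "CT", "TH", "boundary"}.
#' @examples
#' classify_phenotype(c(0.7, 0.3, 0.3, 0.7), c(0.2, 0.2, -0.2, -0.2))
#' @export
classify_phenotype <- function(pi_v1, delta_ego, tol = 1e-9) {
  stopifnot(tol >= 0)
  if (any(pi_v1 < 0 | pi_v1 > 1)) {
    stop("pi_v1 must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(pi_v1), length(delta_ego))
  pi_v1 <- rep_len(pi_v1, n)
  delta_ego <- rep_len(delta_ego, n)
  lab <- rep("boundary", n)
  lab[pi_v1 > 0.5 + tol & delta_ego > tol] <- "BH"
  lab[pi_v1 < 0.5 - tol & delta_ego > tol] <- "SD"
  lab[pi_v1 < 0.5 - tol & delta_ego < -tol] <- "CT"
  lab[pi_v1 > 0.5 + tol & delta_ego < -tol] <- "TH"
  lab
}

#' Sweep the parameter grid and label phenotypes
#'
#' Evaluates the model over every combination of the grid. In `"analytic"`
#' mode each cell gets the closed-form `pi_v1` and the `delta_ego` derived
#' from the stationary distribution — deterministic and seed-free. In
#' `"simulated"` mode each cell additionally runs a seeded trajectory of
#' `n_steps` transitions and records the empirical `delta_ego_hat`,
#' mirroring the Monte Carlo protocol (one run per cell, per-cell seeds
#' derived from `seed`); classification then uses the empirical value with
#' the wider guard band.
#'
#' Cells are evaluated independently and the output is ordered canonically
#' by (alpha, beta, r, omega).
#'
#' @param grid A grid from [phenotype_grid()].
#' @param mode `"analytic"` (default) or `"simulated"`.
#' @param n_steps Trajectory length per cell in simulated mode.
#' @param seed Base seed for simulated mode; cell i uses `seed + i - 1`.
#' @param tol Boundary tolerance passed to [classify_phenotype()]; defaults
#'   to 1e-9 for analytic and 0.02 for simulated classification.
#' @return A data frame of class `"ego_sweep"` with columns `alpha`, `beta`,
#'   `r`, `omega`, `s`, `pi_v1`, `delta_ego`, (simulated mode only:
#'   `delta_ego_hat`, `n_steps`, `cell_seed`), `class`; attributes `grid`,
#'   `mode`, `tol`, `seed`.
#' @examples
#' sw <- run_sweep(phenotype_grid(values = c(0.2, 0.5, 0.8)))
#' table(sw$class)
#' @export
run_sweep <- function(grid = phenotype_grid(),
                      mode = c("analytic", "simulated"),
                      n_steps = 500000L, seed = 1L, tol = NULL) {
  stopifnot(inherits(grid, "ego_grid"))
  mode <- match.arg(mode)
  if (is.null(tol)) tol <- if (mode == "analytic") 1e-9 else 0.02

  cells <- expand.grid(omega = grid$omega, r = grid$r, beta = grid$beta,
                       alpha = grid$alpha, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$alpha, cells$beta, cells$r, cells$omega), ]
  rownames(cells) <- NULL
  n <- nrow(cells)

  pi_v1 <- pi_v1_closed_form(cells$alpha, cells$beta, cells$omega, cells$r)
  d_ego <- vapply(seq_len(n), function(i) {
    m <- valence_model(r = cells$r[i], s = grid$s, alpha = cells$alpha[i],
                       beta = cells$beta[i], omega = cells$omega[i])
    delta_ego_analytic(stationary_distribution(
      transition_matrix(m, method = "composed")))
  }, numeric(1))

  out <- data.frame(alpha = cells$alpha, beta = cells$beta, r = cells$r,
                    omega = cells$omega, s = grid$s,
                    pi_v1 = pi_v1, delta_ego = d_ego)

  if (mode == "simulated") {
    d_hat <- vapply(seq_len(n), function(i) {
      m <- valence_model(r = cells$r[i], s = grid$s, alpha = cells$alpha[i],
                         beta = cells$beta[i], omega = cells$omega[i])
      tr <- simulate(m, nsim = n_steps, seed = seed + i - 1L)
      delta_ego_empirical(tr)$delta_ego_hat
    }, numeric(1))
    out$delta_ego_hat <- d_hat
    out$n_steps <- n_steps
    out$cell_seed <- seed + seq_len(n) - 1L
    out$class <- classify_phenotype(out$pi_v1, d_hat, tol = tol)
  } else {
    out$class <- classify_phenotype(out$pi_v1, out$delta_ego, tol = tol)
  }

  attr(out, "grid") <- grid
  attr(out, "mode") <- mode
  attr(out, "tol") <- tol
  attr(out, "seed") <- if (mode == "simulated") seed else NULL
  class(out) <- c("ego_sweep", "data.frame")
  out
}

#' The alpha + beta = 1 slice of the sweep
#'
#' Restricts the sweep to the sensitivity pairs with `alpha + beta = 1`, so
#' that the mismatch `alpha - beta` runs over a symmetric range (−0.98 to
#' 0.98 on the default grid), crossed with the full `r` grid at a single
#' attention level `omega`. These are the axes of the phenotype phase
#' diagrams: `pi_v1` and `delta_ego` as functions of (alpha − beta, r).
#'
#' @param omega Attention level for the slice.
#' @param grid Grid whose `alpha`/`beta`/`r` values are used; pairs are
#'   selected where `1 - alpha` is itself on the beta grid.
#' @param tol Boundary tolerance for classification.
#' @return An `"ego_sweep"` data frame with an extra `mismatch` column
#'   (`alpha - beta`), ordered by (mismatch, r).
#' @examples
#' sl <- slice_mismatch(omega = 0.5)
#' range(sl$mismatch)
#' @export
slice_mismatch <- function(omega, grid = phenotype_grid(), tol = 1e-9) {
  stopifnot(inherits(grid, "ego_grid"), omega > 0, omega < 1)
  alpha <- grid$alpha[vapply(grid$alpha, function(a) {
    any(abs(grid$beta - (1 - a)) < 1e-9)
  }, logical(1))]
  if (length(alpha) == 0L) {
    stop("grid contains no (alpha, beta) pairs with alpha + beta = 1",
         call. = FALSE)
  }
  beta <- round(1 - alpha, 10)
  cells <- expand.grid(r = grid$r, pair = seq_along(alpha),
                       KEEP.OUT.ATTRS = FALSE)
  a <- alpha[cells$pair]; b <- beta[cells$pair]

  pi_v1 <- pi_v1_closed_form(a, b, omega, cells$r)
  d_ego <- vapply(seq_len(nrow(cells)), function(i) {
    m <- valence_model(r = cells$r[i], s = grid$s, alpha = a[i], beta = b[i],
                       omega = omega)
    delta_ego_analytic(stationary_distribution(
      transition_matrix(m, method = "composed")))
  }, numeric(1))

  out <- data.frame(alpha = a, beta = b, r = cells$r, omega = omega,
                    s = grid$s, mismatch = round(a - b, 10),
                    pi_v1 = pi_v1, delta_ego = d_ego,
                    class = classify_phenotype(pi_v1, d_ego, tol = tol))
  out <- out[order(out$mismatch, out$r), ]
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  attr(out, "mode") <- "analytic"
  attr(out, "tol") <- tol
  class(out) <- c("ego_sweep", "data.frame")
  out
}
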
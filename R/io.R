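#' Export a transition matrix
#'
#' Writes a transition matrix to CSV (labelled rows and columns, full double
#' precision) or JSON (nested row arrays plus the parameter block), for
#' inspection and golden-file comparisons.
#'
#' @param model A [valence_model()] object.
#' @param file Output path; the parent directory must exist.
#' @param format `"csv"` or `"json"`.
#' @param method Matrix construction passed to [transition_matrix()].
#' @return `file`, invisibly.
#' @export
write_transition <- function(model, file, format = c("csv", "json"),
                             method = "composed") {
  format <- match.arg(format)
  P <- transition_matrix(model, method = method)
  if (format == "csv") {
    utils::write.csv(format(P, digits = 17, trim = TRUE), file = file,
                     quote = FALSE)
  } else {
    rows <- lapply(seq_len(nrow(P)), function(i) unname(P[i, ]))
    jsonlite::write_json(
      list(params = as.list(model$params),
           states = state_labels(),
           matrix = rows),
      path = file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read back an exported transition matrix
#'
#' @param file Path written by [write_transition()].
#' @param format `"csv"` or `"json"`.
#' @return The matrix with state-label dimnames.
#' @export
read_transition <- function(file, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(file, row.names = 1, check.names = FALSE)
    as.matrix(df)
  } else {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    P <- x$matrix
    if (is.list(P)) P <- do.call(rbind, lapply(P, unlist))
    dimnames(P) <- list(x$states, x$states)
    P
  }
}

#' Export a steady-state summary as JSON
#'
#' Serializes every field of a [summary.valence_model()] object at full
#' precision.
#'
#' @param summary_obj A `"summary.valence_model"` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_steady_json <- function(summary_obj, file) {
  stopifnot(inherits(summary_obj, "summary.valence_model"))
  jsonlite::write_json(
    list(params = as.list(summary_obj$params),
         pi_bar = unname(summary_obj$pi_bar),
         pi_v1 = summary_obj$pi_v1,
         pi_v0 = summary_obj$pi_v0,
         delta_ego = summary_obj$delta_ego,
         mood_marginal = unname(summary_obj$mood_marginal),
         event_marginal = unname(summary_obj$event_marginal)),
    path = file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Export a sweep table with a reproducibility sidecar
#'
#' Writes the sweep records as RFC-4180 CSV ('.' decimal separator, UTF-8)
#' and a JSON sidecar holding the grid definition, mode, tolerance and seed,
#' sufficient to re-execute the run bit-for-bit.
#'
#' @param sweep An `"ego_sweep"` data frame.
#' @param file CSV output path; the sidecar is written next to it as
#'   `<file>.json`.
#' @return `file`, invisibly.
#' @export
write_sweep <- function(sweep, file) {
  stopifnot(inherits(sweep, "ego_sweep"))
  utils::write.csv(as.data.frame(sweep), file = file, row.names = FALSE)
  g <- attr(sweep, "grid")
  jsonlite::write_json(
    list(grid = list(alpha = g$alpha, beta = g$beta, r = g$r,
                     omega = g$omega, s = g$s),
         mode = attr(sweep, "mode"),
         tol = attr(sweep, "tol"),
         seed = attr(sweep, "seed"),
         n_records = nrow(sweep),
         package_version = as.character(utils::packageVersion("egovalence"))),
    path = paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Export a trajectory as CSV
#'
#' Columns step, V, M, E, state, syntonic; the parameters, seed and
#' initialization mode are recorded as `#`-prefixed comment lines before the
#' header.
#'
#' @param trajectory A `"valence_trajectory"` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(trajectory, file) {
  stopifnot(inherits(trajectory, "valence_trajectory"))
  p <- attr(trajectory, "params")
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# params: r=%.15g s=%.15g alpha=%.15g beta=%.15g omega=%.15g",
            p[["r"]], p[["s"]], p[["alpha"]], p[["beta"]], p[["omega"]]),
    sprintf("# seed: %s", format(attr(trajectory, "seed"))),
    sprintf("# init: %s", attr(trajectory, "init"))), con)
  utils::write.csv(as.data.frame(trajectory), file = con, row.names = FALSE)
  invisible(file)
}
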
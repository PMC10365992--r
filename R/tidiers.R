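#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy summaries of a hierarchical fit
#'
#' One row per parameter and level with the posterior mean, sd, central 90%
#' interval and the Gelman-Rubin diagnostic.
#'
#' @param x An `fm_fit`.
#' @param levels Which levels to keep (default the group-level means).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fm_fit <- function(x, levels = "group_mean", ...) {
  d <- x$draws
  if (!is.null(levels)) d <- d[d$level %in% levels, ]
  out <- d |>
    dplyr::group_by(.data$parameter, .data$level) |>
    dplyr::summarise(
      estimate = mean(.data$value), std.error = sd(.data$value),
      conf.low = quantile(.data$value, 0.05),
      conf.high = quantile(.data$value, 0.95),
      .groups = "drop"
    )
  dplyr::left_join(out, x$rhat, by = c("parameter", "level"))
}

#' @rdname tidy.fm_fit
#' @export
glance.fm_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subjects),
    n_retained = x$n_retained,
    chains = x$config$chains,
    max_rhat = max(x$rhat$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' Tidy an allocation solution
#'
#' @param x An `fm_scenario_solution`.
#' @param ... Unused.
#' @return A tibble with the allocation table (`s`, `f_tilde`).
#' @export
tidy.fm_scenario_solution <- function(x, ...) {
  tibble::as_tibble(x$allocation[, c("s", "f_tilde")])
}

#' @rdname tidy.fm_scenario_solution
#' @export
glance.fm_scenario_solution <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, loss = x$loss,
    tau = x$tau %||% NA_real_, bound = x$bound %||% NA_real_,
    k = attr(x$allocation, "k"), converged = x$converged
  )
}

#' Tidy an escort-exponent optimization
#'
#' @param x An `fm_escort_opt`.
#' @param ... Unused.
#' @return The scanned profile tibble (gamma, loss).
#' @export
tidy.fm_escort_opt <- function(x, ...) x$profile

#' @rdname tidy.fm_escort_opt
#' @export
glance.fm_escort_opt <- function(x, ...) {
  tibble::tibble(gamma_star = x$gamma_star, loss = x$loss,
                 objective = x$objective, n_levels = x$n)
}
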
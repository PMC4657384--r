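# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @rdname stoqssa_tidiers
#' @title Tidy and summarize stoqssa result objects
#' @description `tidy()` returns the per-unit table of a result (per initial
#'   condition, per species, ...); `glance()` returns a one-row summary.
#' @param x A result object.
#' @param ... Unused.
#' @export
tidy.qssa_det_error <- function(x, ...) x$per_ic

#' @rdname stoqssa_tidiers
#' @export
glance.qssa_det_error <- function(x, ...) {
  tibble::tibble(max_error = x$max_error, observable = x$observable,
                 T = x$T, n_ic = x$n_evaluated)
}

#' @rdname stoqssa_tidiers
#' @export
tidy.qssa_moments <- function(x, ...) x$summary

#' @rdname stoqssa_tidiers
#' @export
glance.qssa_moments <- function(x, ...) {
  tibble::tibble(n_reps = x$n_reps, burn_in = x$burn_in, t_end = x$t_end,
                 seed_base = x$seed_base, pooled = x$pooled)
}

#' @rdname stoqssa_tidiers
#' @export
tidy.qssa_stoch_error <- function(x, ...) {
  tibble::tibble(statistic = c("cv_full", "cv_reduced", "cv_rel_error", "cv_diff"),
                 value = c(x$cv_full, x$cv_reduced, x$cv_rel_error, x$cv_diff),
                 se = c(NA, NA, x$se_rel, x$se_diff))
}

#' @rdname stoqssa_tidiers
#' @export
glance.qssa_stoch_error <- function(x, ...) {
  tibble::tibble(cv_full = x$cv_full, cv_reduced = x$cv_reduced,
                 cv_rel_error = x$cv_rel_error, se_rel = x$se_rel,
                 cv_diff = x$cv_diff, se_diff = x$se_diff,
                 observable = x$observable, n_reps = x$n_reps)
}

#' @rdname stoqssa_tidiers
#' @export
tidy.qssa_validation <- function(x, ...) x$det_report$per_ic

#' @rdname stoqssa_tidiers
#' @export
glance.qssa_validation <- function(x, ...) {
  tibble::tibble(model = x$pair_name %||% NA_character_,
                 verdict = x$verdict,
                 max_error = x$det_report$max_error,
                 threshold = x$threshold,
                 argmax = paste(names(x$det_report$argmax),
                                format(unname(x$det_report$argmax), digits = 4),
                                sep = "=", collapse = ", "),
                 T = x$det_report$T,
                 region_mode = x$provenance$region_mode,
                 n_reps = x$provenance$n_reps,
                 seed = x$provenance$seed)
}

#' Plot a trajectory
#'
#' @param object A `qssa_trajectory` (from [integrate_network()] or
#'   [gillespie_run()]).
#' @param species Species to draw; default all.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qssa_trajectory <- function(object, species = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "species", values_to = "value")
  if (!is.null(species)) long <- dplyr::filter(long, .data$species %in% !!species)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "level", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an SSA ensemble (spaghetti + mean)
#'
#' @param object A `qssa_ensemble` from [simulate_ensemble()].
#' @param species Single species to draw.
#' @param max_reps Maximum individual replicates drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qssa_ensemble <- function(object, species, max_reps = 50, ...) {
  df <- tibble::as_tibble(object)
  sub <- dplyr::filter(df, .data$rep <= max_reps)
  mn <- dplyr::summarise(dplyr::group_by(df, .data$time),
                         value = mean(.data[[species]]))
  ggplot2::ggplot(sub, ggplot2::aes(.data$time, .data[[species]],
                                    group = .data$rep)) +
    ggplot2::geom_step(alpha = 0.2) +
    ggplot2::geom_line(data = mn, ggplot2::aes(.data$time, .data$value),
                       inherit.aes = FALSE, colour = "red", linewidth = 1) +
    ggplot2::labs(x = "time", y = species) +
    ggplot2::theme_minimal()
}

#' Plot the per-IC deterministic reduction error
#'
#' Shows the reduction error across the scanned initial conditions, faceted
#' against the first two varying coordinates.
#'
#' @param object A `qssa_det_error` from [deterministic_qssa_error()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qssa_det_error <- function(object, ...) {
  tb <- object$per_ic
  dims <- setdiff(names(tb), "error")
  varying <- dims[vapply(tb[dims], function(v) length(unique(v)) > 1, TRUE)]
  if (!length(varying)) varying <- dims[1]
  x <- varying[1]
  p <- ggplot2::ggplot(tb, ggplot2::aes(.data[[x]], .data$error))
  if (length(varying) >= 2) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = factor(.data[[varying[2]]]))) +
      ggplot2::labs(colour = varying[2])
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$max_error, linetype = 2) +
    ggplot2::labs(y = "reduction error") +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep of the two error measures
#'
#' @param sweep_tbl The tibble returned by [qssa_sweep()].
#' @param param Name of the parameter column.
#' @param log_x Use a log10 x axis?
#' @return A ggplot with the deterministic and the stochastic error curves.
#' @export
plot_sweep <- function(sweep_tbl, param = names(sweep_tbl)[1], log_x = TRUE) {
  long <- tidyr::pivot_longer(sweep_tbl,
                              dplyr::any_of(c("det_error", "stoch_error")),
                              names_to = "measure", values_to = "error")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data[[param]], .data$error,
                                          colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "reduction error", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' @importFrom rlang .data
NULL
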
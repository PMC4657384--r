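#' Pair a full network with its QSSA reduction
#'
#' A `model_pair` links a full reaction network to a reduced one: the species
#' shared by both are the slow coordinates, the remaining species of the full
#' network are the fast coordinates eliminated by the reduction. The pair
#' carries the QSS map (fast-species values as a function of the reduced slow
#' state) and, when the reduced model uses a transformed variable (e.g. a
#' total-repressor variable), an explicit `lift` describing how a reduced
#' state plus fast-species values becomes a full-model initial state.
#'
#' @param full,reduced [reaction_network()]s with eliminated species already
#'   substituted away.
#' @param observable Name of the species (present in both networks) whose
#'   trajectories are compared by the reduction-error metric.
#' @param qss_map Function from a named reduced (slow) state to named values
#'   of the fast species.
#' @param lift Function `(slow, fast)` returning the named full-model initial
#'   state. Default: shared species from `slow`, the rest from `fast`.
#' @param ic_filter Optional predicate on the named full initial state;
#'   infeasible grid points (e.g. conservation-violating combinations) are
#'   skipped by the error scan.
#' @param name Optional label.
#' @param fast Names of the free fast coordinates of the full model scanned
#'   by the error metric; defaults to every full-model species absent from
#'   the reduced one. Override when `lift` derives some of those species
#'   from the reduced state instead.
#' @param params Named list of the model parameters the pair was built from
#'   (kept for reporting and for the analytic validity estimates).
#' @param defaults Named list of recommended settings for this model
#'   (`T` for the reduction-error horizon, `burn_in`, `t_end` and `n_reps`
#'   for stationary sampling, `n_out` for the ODE grid).
#' @return A `model_pair` object.
#' @export
model_pair <- function(full, reduced, observable, qss_map = NULL, lift = NULL,
                       ic_filter = NULL, name = NULL, params = list(),
                       defaults = list(), fast = NULL) {
  stopifnot(inherits(full, "reaction_network"), inherits(reduced, "reaction_network"))
  if (has_eliminated(full) || has_eliminated(reduced))
    stop("apply_conservation() both networks before pairing", call. = FALSE)
  shared <- intersect(reduced$species$name, full$species$name)
  # `fast` are the free fast coordinates scanned by the error metric; full-model
  # species that are neither shared nor fast must be produced by `lift`
  # (e.g. R = T - D_R when the reduced model uses a total variable).
  fast <- fast %||% setdiff(full$species$name, shared)
  if (!observable %in% shared)
    stop("observable `", observable, "` must be present in both networks", call. = FALSE)
  if (is.null(lift)) {
    lift <- function(slow, fast_vals) {
      st <- c(slow[shared], fast_vals)
      st[full$species$name]
    }
  }
  structure(list(full = full, reduced = reduced, observable = observable,
                 shared = shared, fast = fast,
                 qss_map = qss_map, lift = lift, ic_filter = ic_filter,
                 name = name %||% full$name,
                 params = params, defaults = defaults),
            class = "model_pair")
}

#' @export
print.model_pair <- function(x, ...) {
  cat("<model pair", if (!is.null(x$name)) paste0("`", x$name, "`"), ">\n")
  cat("  slow (shared):", paste(x$shared, collapse = ", "), "\n")
  cat("  fast (full only):", if (length(x$fast)) paste(x$fast, collapse = ", ")
      else "none", "\n")
  cat("  observable:", x$observable, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
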
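#' Integrate a network deterministically
#'
#' Solves the mass-action/closed-form ODE system with a stiff-capable solver
#' (`deSolve::lsoda`), sampling the solution on a uniform grid. The full
#' models are stiff when binding/unbinding rates are large, so the defaults
#' keep tolerances tight enough to resolve the fast initial transient.
#'
#' @param network A [reaction_network()] without eliminated species.
#' @param initial Named initial state (concentrations); defaults to the
#'   network's declared initial values.
#' @param t_end Final time (model time units).
#' @param n_out Number of output intervals: the trajectory has `n_out + 1`
#'   uniformly spaced rows over `[0, t_end]`.
#' @param rtol,atol Local error tolerances.
#' @param method `deSolve` method name.
#' @return A `qssa_trajectory`: a tibble with a `time` column and one column
#'   per species.
#' @export
#' @examples
#' pair <- make_genetic_nfl()
#' tr <- integrate_network(pair$reduced, t_end = 20, n_out = 200)
integrate_network <- function(network, initial = NULL, t_end, n_out = 2000,
                              rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  if (has_eliminated(network))
    stop("network still contains eliminated species; call apply_conservation() first",
         call. = FALSE)
  y0 <- if (is.null(initial)) initial_state(network) else
    stats::setNames(match_state(network, initial), network$species$name)
  check_conservation_state(network, y0)
  ptr <- net_ptr(network)
  times <- seq(0, t_end, length.out = n_out + 1)
  rhs <- function(t, y, parms) list(net_rhs_cpp(ptr, y))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  istate <- attr(sol, "istate")[1]
  if (!is.null(istate) && istate < 0)
    stop("ODE integration failed (istate = ", istate, ") near t = ",
         format(max(sol[, 1])), call. = FALSE)
  if (nrow(sol) < length(times))
    stop("ODE integration stopped early at t = ", format(max(sol[, 1])), call. = FALSE)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out) <- c("time", network$species$name)
  as_qssa_trajectory(out, network$species$name)
}

check_conservation_state <- function(network, y0) {
  for (cl in network$conservation) {
    v <- sum(cl$coef * y0[names(cl$coef)])
    if (abs(v - cl$total) > 1e-6 * max(1, abs(cl$total)))
      stop("initial state violates conservation law (total ", cl$total,
           ", got ", format(v), ")", call. = FALSE)
  }
  invisible(TRUE)
}

as_qssa_trajectory <- function(df, species) {
  structure(df, species = species,
            class = c("qssa_trajectory", class(tibble::tibble())))
}

#' Locate a steady state
#'
#' Integrates from `guess` for `t_relax` time units, then polishes the result
#' with damped Newton iterations on the right-hand side (numerical Jacobian)
#' until the residual falls below `tol` times the state scale.
#'
#' @inheritParams integrate_network
#' @param guess Named starting state; defaults to the declared initial values.
#' @param t_relax Length of the relaxation integration used to seed Newton.
#' @param tol Residual tolerance relative to `max(1, |state|)`.
#' @return Named steady-state vector.
#' @export
steady_state <- function(network, guess = NULL, t_relax = 100, tol = 1e-10) {
  y0 <- if (is.null(guess)) initial_state(network) else
    stats::setNames(match_state(network, guess), network$species$name)
  tr <- integrate_network(network, y0, t_end = t_relax, n_out = 50)
  x <- as.numeric(tr[nrow(tr), -1])
  names(x) <- network$species$name
  ptr <- net_ptr(network)
  f <- function(z) as.numeric(net_rhs_cpp(ptr, z))
  scale_tol <- function(z) tol * max(1, max(abs(z)))
  res <- f(x)
  for (it in seq_len(60)) {
    if (max(abs(res)) < scale_tol(x)) break
    J <- pracma::jacobian(f, x)
    step <- tryCatch(solve(J, -res), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      res_new <- f(x_new)
      if (max(abs(res_new)) < max(abs(res)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- x_new
    res <- res_new
  }
  if (max(abs(res)) >= scale_tol(x))
    stop("steady-state search did not converge; final residual ",
         format(max(abs(res))), call. = FALSE)
  stats::setNames(x, network$species$name)
}

#' Relative L1 distance between two trajectories
#'
#' The single-trajectory reduction error
#' \deqn{\int_0^T |X_{full}(t) - X_{QSSA}(t)|\,dt \,/\, \int_0^T |X_{QSSA}(t)|\,dt,}
#' computed by the trapezoidal rule on the trajectories' common uniform grid.
#'
#' @param full_traj,reduced_traj Trajectories sampled on the same time grid
#'   covering `[0, T]`.
#' @param species Name of the compared species (present in both).
#' @param T Upper integration limit; defaults to the grid's final time.
#' @return Nonnegative scalar error.
#' @export
l1_relative_error <- function(full_traj, reduced_traj, species, T = NULL) {
  t1 <- full_traj$time
  t2 <- reduced_traj$time
  if (length(t1) != length(t2) || max(abs(t1 - t2)) > 1e-9 * max(t1[length(t1)], 1))
    stop("trajectories are not on a common time grid", call. = FALSE)
  if (!species %in% names(full_traj) || !species %in% names(reduced_traj))
    stop("species `", species, "` absent from a trajectory", call. = FALSE)
  if (is.null(T)) T <- t1[length(t1)]
  if (t1[length(t1)] < T - 1e-9) stop("grid does not cover [0, T]", call. = FALSE)
  keep <- t1 <= T + 1e-9 * max(T, 1)
  tt <- t1[keep]
  xf <- full_traj[[species]][keep]
  xr <- reduced_traj[[species]][keep]
  den <- pracma::trapz(tt, abs(xr))
  if (den <= 0) stop("degenerate reduced trajectory: zero denominator integral",
                     call. = FALSE)
  pracma::trapz(tt, abs(xf - xr)) / den
}

#' Write / read a trajectory as CSV
#'
#' Plain `time,<species...>` CSV, one row per output point.
#'
#' @param traj A trajectory tibble.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  if (names(df)[1] != "time") stop("expected a `time` first column", call. = FALSE)
  as_qssa_trajectory(df, setdiff(names(df), "time"))
}
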
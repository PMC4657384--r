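#' Declare a species of a reaction network
#'
#' @param name Species name (a valid identifier).
#' @param role One of `"slow"`, `"fast"`, `"eliminated"`. Fast species are the
#'   ones a QSS reduction eliminates (their whole physical range is scanned by
#'   the validator); eliminated species are removed algebraically through a
#'   conservation law by [apply_conservation()].
#' @param initial Nonnegative initial value, in concentration units (counts are
#'   obtained as `initial * volume` when simulating stochastically).
#' @param lo,hi Physical range of the species. `hi = Inf` declares an
#'   unbounded species; the validator then demands an explicit cap.
#' @return A one-row tibble describing the species.
#' @export
#' @examples
#' species_spec("D_A", "fast", initial = 0, lo = 0, hi = 1)
species_spec <- function(name, role = c("slow", "fast", "eliminated"),
                         initial = 0, lo = 0, hi = Inf) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.finite(initial) || initial < 0)
    stop("initial value of `", name, "` must be a nonnegative real", call. = FALSE)
  if (lo > hi) stop("physical range of `", name, "` has lo > hi", call. = FALSE)
  if (initial < lo - 1e-12 || initial > hi + 1e-12)
    stop("initial value of `", name, "` lies outside its physical range", call. = FALSE)
  tibble::tibble(name = name, role = role, initial = as.numeric(initial),
                 lo = as.numeric(lo), hi = as.numeric(hi))
}

#' Declare a reaction
#'
#' @param name Reaction name.
#' @param reactants,products Named numeric vectors of stoichiometric
#'   coefficients (use `NULL` for none, e.g. a zeroth-order birth).
#' @param rate A [mass_action()] or [rate_expr()] rate law. For mass action
#'   the reactant stoichiometry sets the multiplicities.
#' @return A `qssa_reaction` object.
#' @export
#' @examples
#' reaction("binding", c(R = 1, D_A = 1), c(D_R = 1), mass_action(10))
reaction <- function(name, reactants = NULL, products = NULL, rate) {
  stopifnot(is.character(name), length(name) == 1)
  if (!inherits(rate, "rate_law")) stop("`rate` must be a rate law", call. = FALSE)
  norm_stoich <- function(s, what) {
    if (is.null(s) || length(s) == 0) return(stats::setNames(numeric(), character()))
    if (is.null(names(s)) || any(names(s) == ""))
      stop(what, " stoichiometry must be a named vector", call. = FALSE)
    if (any(s < 0) || any(s != round(s)))
      stop(what, " stoichiometric coefficients must be nonnegative integers", call. = FALSE)
    s[s > 0]
  }
  structure(list(name = name,
                 reactants = norm_stoich(reactants, "reactant"),
                 products = norm_stoich(products, "product"),
                 rate = rate),
            class = "qssa_reaction")
}

#' Declare a conservation law
#'
#' A linear combination of species that stays constant along every trajectory,
#' e.g. total DNA (`D_A + D_R = 1`) or total enzyme (`E + E_R = E_T`).
#'
#' @param coef Named numeric vector of coefficients.
#' @param total The conserved total.
#' @return A `conservation_law` object.
#' @export
conservation_law <- function(coef, total) {
  if (is.null(names(coef)) || any(names(coef) == ""))
    stop("conservation coefficients must be named", call. = FALSE)
  structure(list(coef = coef, total = as.numeric(total)), class = "conservation_law")
}

#' Build a reaction network
#'
#' The single representation driving both the deterministic right-hand side
#' ([evaluate_rhs()], [integrate_network()]) and the stochastic propensities
#' ([propensities()], [gillespie_run()]). Rate laws may be elementary
#' (mass action) or closed-form (Hill, Michaelis–Menten, total-QSS roots).
#'
#' @param species A tibble of species rows from [species_spec()] (bind with
#'   `rbind()`/`dplyr::bind_rows()`), order defines the state layout.
#' @param reactions List of [reaction()]s.
#' @param conservation List of [conservation_law()]s.
#' @param volume System volume \eqn{\Omega} (counts = concentration × volume);
#'   default 1.
#' @param prefactor Optional named list mapping a species name to a
#'   [rate_expr()]: the assembled derivative of that species is divided by the
#'   prefactor value (needed only for prefactor-QSSA reductions). Stochastic
#'   simulation of prefactored networks is refused; see [strip_prefactor()].
#' @param name Optional model name, used in printing and reports.
#' @return A `reaction_network` object.
#' @export
reaction_network <- function(species, reactions, conservation = list(),
                             volume = 1, prefactor = NULL, name = NULL) {
  species <- dplyr::bind_rows(species)
  if (anyDuplicated(species$name)) stop("duplicate species names", call. = FALSE)
  if (!is.numeric(volume) || length(volume) != 1 || volume <= 0)
    stop("`volume` must be a positive real", call. = FALSE)
  if (inherits(reactions, "qssa_reaction")) reactions <- list(reactions)
  if (inherits(conservation, "conservation_law")) conservation <- list(conservation)
  names(reactions) <- vapply(reactions, `[[`, "", "name")
  if (anyDuplicated(names(reactions))) stop("duplicate reaction names", call. = FALSE)

  net <- structure(list(species = species, reactions = reactions,
                        conservation = conservation, volume = as.numeric(volume),
                        prefactor = prefactor, name = name,
                        .cache = new.env(parent = emptyenv())),
                   class = "reaction_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  sp <- net$species
  for (r in net$reactions) {
    used <- c(names(r$reactants), names(r$products), rate_law_species(r$rate))
    unknown <- setdiff(used, sp$name)
    if (length(unknown))
      stop("reaction `", r$name, "` references undeclared species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (cl in net$conservation) {
    unknown <- setdiff(names(cl$coef), sp$name)
    if (length(unknown))
      stop("conservation law references undeclared species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    tot0 <- sum(cl$coef * sp$initial[match(names(cl$coef), sp$name)])
    if (abs(tot0 - cl$total) > 1e-8 * max(1, abs(cl$total)))
      stop("initial state violates conservation law (",
           paste(names(cl$coef), collapse = "+"), " = ", cl$total, ")", call. = FALSE)
    for (r in net$reactions) {
      d <- stats::setNames(numeric(length(cl$coef)), names(cl$coef))
      pr <- r$products[names(r$products) %in% names(cl$coef)]
      re <- r$reactants[names(r$reactants) %in% names(cl$coef)]
      d[names(pr)] <- d[names(pr)] + pr
      d[names(re)] <- d[names(re)] - re
      if (abs(sum(cl$coef * d)) > 1e-12)
        stop("reaction `", r$name, "` breaks the conservation law on ",
             paste(names(cl$coef), collapse = "+"), call. = FALSE)
    }
  }
  elim <- sp$name[sp$role == "eliminated"]
  for (e in elim) {
    n_laws <- sum(vapply(net$conservation, function(cl) e %in% names(cl$coef), TRUE))
    if (n_laws != 1)
      stop("eliminated species `", e, "` must appear in exactly one conservation law",
           call. = FALSE)
  }
  if (!is.null(net$prefactor)) {
    bad <- setdiff(names(net$prefactor), sp$name)
    if (length(bad)) stop("prefactor on undeclared species: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (pf in net$prefactor) {
      if (!inherits(pf, "rate_law") || pf$kind != "closed_form")
        stop("prefactors must be rate_expr() objects", call. = FALSE)
    }
  }
  invisible(net)
}

n_species <- function(net) nrow(net$species)

retained_species <- function(net) net$species$name[net$species$role != "eliminated"]

has_eliminated <- function(net) any(net$species$role == "eliminated")

is_prefactored <- function(net) !is.null(net$prefactor) && length(net$prefactor) > 0

#' Initial state of a network
#'
#' @param network A [reaction_network()].
#' @return Named numeric vector of initial concentrations.
#' @export
initial_state <- function(network) {
  stats::setNames(network$species$initial, network$species$name)
}

# ---- compiled representation ------------------------------------------------

net_compiled_spec <- function(net) {
  sp <- net$species$name
  rxns <- lapply(unname(net$reactions), function(r) {
    delta <- stats::setNames(numeric(length(sp)), sp)
    if (length(r$products)) delta[names(r$products)] <- delta[names(r$products)] + r$products
    if (length(r$reactants)) delta[names(r$reactants)] <- delta[names(r$reactants)] - r$reactants
    nz <- which(delta != 0)
    out <- list(kind = if (r$rate$kind == "mass_action") 0L else 1L,
                k = if (r$rate$kind == "mass_action") r$rate$k else 0,
                re_i = as.integer(match(names(r$reactants), sp) - 1L),
                re_m = as.integer(unname(r$reactants)),
                net_i = as.integer(nz - 1L),
                net_d = unname(delta[nz]))
    if (out$kind == 1L)
      out$expr <- rpn_compile(r$rate$expr, sp, r$rate$params)
    out
  })
  pf <- list()
  if (is_prefactored(net)) {
    pf <- list(idx = as.integer(match(names(net$prefactor), sp) - 1L),
               exprs = lapply(net$prefactor,
                              function(p) rpn_compile(p$expr, sp, p$params)))
  }
  list(n_species = length(sp), reactions = rxns, prefactor = pf)
}

net_ptr <- function(net) {
  cache <- net$.cache
  if (is.null(cache$ptr) || !xptr_valid_cpp(cache$ptr)) {
    cache$ptr <- net_compile_cpp(net_compiled_spec(net))
  }
  cache$ptr
}

# ---- core operations --------------------------------------------------------

#' Evaluate the deterministic right-hand side
#'
#' Returns the time derivative of every (non-eliminated) species at a state:
#' the stoichiometry-weighted sum of all rate-law values, with any declared
#' prefactor dividing the corresponding derivative.
#'
#' @param network A [reaction_network()] whose eliminated species have been
#'   substituted away (see [apply_conservation()]).
#' @param state Named numeric state (concentrations), covering every species.
#' @return Named numeric vector of derivatives.
#' @export
#' @examples
#' pair <- make_genetic_nfl()
#' evaluate_rhs(pair$reduced, c(M = 100, R = 0))
evaluate_rhs <- function(network, state) {
  if (has_eliminated(network))
    stop("network still contains eliminated species; call apply_conservation() first",
         call. = FALSE)
  x <- match_state(network, state)
  rates <- net_rates_cpp(net_ptr(network), x)
  if (any(rates < -1e-12))
    stop("rate law of reaction `",
         names(network$reactions)[which.min(rates)],
         "` is negative at this state", call. = FALSE)
  stats::setNames(as.numeric(net_rhs_cpp(net_ptr(network), x)), network$species$name)
}

match_state <- function(network, state) {
  sp <- network$species$name
  if (is.null(names(state))) {
    if (length(state) != length(sp))
      stop("unnamed state of wrong length", call. = FALSE)
    return(as.numeric(state))
  }
  unknown <- setdiff(names(state), sp)
  if (length(unknown))
    stop("unknown species in state: ", paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(sp, names(state))
  if (length(missing))
    stop("state is missing species: ", paste(missing, collapse = ", "), call. = FALSE)
  as.numeric(state[sp])
}

#' Stochastic propensities at a count state
#'
#' Applies the concentration-substitution rule uniformly to elementary and
#' non-elementary rate laws: \eqn{a_j = \Omega f_j(n/\Omega)} with
#' \eqn{\Omega} the network volume.
#'
#' @inheritParams evaluate_rhs
#' @param counts Named vector of nonnegative molecule counts.
#' @return Named numeric vector of propensities, one per reaction.
#' @export
propensities <- function(network, counts) {
  if (has_eliminated(network))
    stop("network still contains eliminated species; call apply_conservation() first",
         call. = FALSE)
  n <- match_state(network, counts)
  if (any(n < 0)) stop("negative counts", call. = FALSE)
  stats::setNames(as.numeric(net_propensities_cpp(net_ptr(network), n, network$volume)),
                  names(network$reactions))
}

#' Eliminate species through conservation laws
#'
#' Replaces every species declared with role `"eliminated"` by
#' `(total - weighted sum of retained species) / coefficient` inside all rate
#' laws, drops it from all stoichiometries, and removes it from the state.
#' Mass-action laws that consumed an eliminated species become closed-form
#' laws. Networks without eliminated species are returned unchanged.
#'
#' @inheritParams evaluate_rhs
#' @return An equivalent `reaction_network` of lower dimension.
#' @export
apply_conservation <- function(network) {
  elim <- network$species$name[network$species$role == "eliminated"]
  if (!length(elim)) return(network)

  subs <- list()
  used_laws <- logical(length(network$conservation))
  for (e in elim) {
    il <- which(vapply(network$conservation, function(cl) e %in% names(cl$coef), TRUE))
    cl <- network$conservation[[il]]
    other <- setdiff(names(cl$coef), e)
    retained_other <- setdiff(other, elim)
    if (!setequal(other, retained_other))
      stop("conservation law couples two eliminated species; eliminate one at a time",
           call. = FALSE)
    expr <- as.numeric(cl$total)
    for (s in other) {
      term <- if (cl$coef[[s]] == 1) as.name(s) else call("*", cl$coef[[s]], as.name(s))
      expr <- call("-", expr, term)
    }
    if (cl$coef[[e]] != 1) expr <- call("/", call("(", expr), cl$coef[[e]])
    subs[[e]] <- if (is.call(expr)) call("(", expr) else expr
    used_laws[il] <- TRUE
  }

  new_reactions <- lapply(network$reactions, function(r) {
    rl <- r$rate
    if (rl$kind == "mass_action") {
      if (any(names(r$reactants) %in% elim)) {
        e <- NULL
        for (s in names(r$reactants)) {
          sym <- if (s %in% elim) subs[[s]] else as.name(s)
          for (m in seq_len(r$reactants[[s]])) {
            e <- if (is.null(e)) sym else call("*", e, sym)
          }
        }
        rl <- rate_expr(call("*", rl$k, e))
      }
    } else {
      needs <- intersect(rate_law_species(rl), elim)
      if (length(needs)) {
        rl <- rate_expr(subst_expr(rl$expr, subs), params = rl$params)
      }
    }
    r$reactants <- r$reactants[!names(r$reactants) %in% elim]
    r$products <- r$products[!names(r$products) %in% elim]
    r$rate <- rl
    r
  })

  reaction_network(species = network$species[!network$species$name %in% elim, ],
                   reactions = new_reactions,
                   conservation = network$conservation[!used_laws],
                   volume = network$volume,
                   prefactor = network$prefactor,
                   name = network$name)
}

#' Drop a network's prefactor
#'
#' The stochastic counterpart of a prefactor-QSSA reduction uses the reduced
#' reactions as propensities on the untransformed variable, i.e. without the
#' prefactor; this helper returns that network.
#'
#' @inheritParams evaluate_rhs
#' @export
strip_prefactor <- function(network) {
  if (!is_prefactored(network)) return(network)
  reaction_network(species = network$species, reactions = network$reactions,
                   conservation = network$conservation, volume = network$volume,
                   prefactor = NULL, name = network$name)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction network", if (!is.null(x$name)) paste0("`", x$name, "`"), ">\n")
  cat("  species  :", paste0(x$species$name, " (", x$species$role, ")",
                             collapse = ", "), "\n")
  cat("  reactions:", length(x$reactions), "   volume:", x$volume,
      if (is_prefactored(x)) "  [prefactored]" else "", "\n")
  for (cl in x$conservation) {
    cat("  conserved:", paste(ifelse(cl$coef == 1, names(cl$coef),
                                     paste0(cl$coef, "*", names(cl$coef))),
                              collapse = " + "), "=", cl$total, "\n")
  }
  invisible(x)
}
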
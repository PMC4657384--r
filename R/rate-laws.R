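#' Mass-action rate law
#'
#' An elementary rate law: the macroscopic rate is the rate constant times the
#' product of the reactant concentrations (with multiplicity, taken from the
#' reaction's reactant stoichiometry). The corresponding propensity follows the
#' concentration-substitution rule \eqn{a = \Omega k \prod_i (n_i/\Omega)^{\nu_i}}.
#'
#' @param k Positive rate constant.
#' @return A `rate_law` object of kind `"mass_action"`.
#' @export
#' @examples
#' mass_action(10)
mass_action <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0) {
    stop("mass_action() needs a single positive finite rate constant", call. = FALSE)
  }
  structure(list(kind = "mass_action", k = as.numeric(k)),
            class = "rate_law")
}

#' Closed-form (non-elementary) rate law
#'
#' A rate law given as an arithmetic expression of species names and named
#' parameters — Hill functions, Michaelis–Menten terms, total-QSS quadratic
#' roots, and the like. The expression grammar is deliberately restricted to
#' `+`, `-`, `*`, `/`, `^`, `sqrt()` and parentheses; anything else is
#' rejected, which keeps both the deterministic right-hand side and the
#' stochastic propensity evaluation fast and auditable. The same macroscopic
#' expression serves as ODE rate and (after the \eqn{X = n_X/\Omega}
#' substitution) as SSA propensity.
#'
#' @param expr The rate expression: a one-sided formula (`~ aM * K / (K + R)`),
#'   a quoted expression, or a string to parse.
#' @param params Named numeric vector of positive parameter values appearing
#'   in the expression.
#' @return A `rate_law` object of kind `"closed_form"`.
#' @export
#' @examples
#' rate_expr(~ aM * K / (K + R), params = c(aM = 300, K = 10))
rate_expr <- function(expr, params = numeric()) {
  e <- as_rate_expression(expr)
  params <- unlist(params)
  if (length(params) && (is.null(names(params)) || any(names(params) == "")))
    stop("all rate-law parameters must be named", call. = FALSE)
  if (length(params) && any(!is.finite(params)))
    stop("rate-law parameters must be finite", call. = FALSE)
  check_rate_grammar(e, known = names(params))
  structure(list(kind = "closed_form", expr = e, params = params),
            class = "rate_law")
}

as_rate_expression <- function(expr) {
  if (inherits(expr, "formula")) {
    if (length(expr) != 2) stop("rate formulas must be one-sided", call. = FALSE)
    expr[[2]]
  } else if (is.character(expr) && length(expr) == 1) {
    str2lang(expr)
  } else if (is.language(expr) || is.numeric(expr)) {
    expr
  } else {
    stop("cannot interpret rate expression", call. = FALSE)
  }
}

rate_ops <- c("+", "-", "*", "/", "^", "sqrt", "(")

# Walks an expression and errors on anything outside the whitelisted grammar.
# Symbols must be either declared parameters or (later) declared species.
check_rate_grammar <- function(e, known = character()) {
  syms <- character()
  walk <- function(e) {
    if (is.numeric(e)) {
      invisible()
    } else if (is.name(e)) {
      syms <<- c(syms, as.character(e))
    } else if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% rate_ops) {
        stop("`", op, "` is not in the allowed rate-law grammar (",
             paste(setdiff(rate_ops, "("), collapse = " "), ")", call. = FALSE)
      }
      for (i in seq_along(e)[-1]) walk(e[[i]])
    } else {
      stop("unsupported construct in rate expression", call. = FALSE)
    }
  }
  walk(e)
  unique(syms)
}

# Free symbols of a rate expression that are not parameters: the species it reads.
rate_law_species <- function(rl) {
  if (rl$kind != "closed_form") return(character())
  setdiff(check_rate_grammar(rl$expr), names(rl$params))
}

# Substitute expressions for symbols (used by apply_conservation()).
subst_expr <- function(e, env_list) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(env_list)) return(env_list[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- subst_expr(e[[i]], env_list)
    return(e)
  }
  e
}

# Compile a rate expression to the postfix bytecode consumed by the C++ core.
# Opcodes: 1 PUSH_CONST(i) 2 PUSH_SPECIES(i) 3 + 4 - 5 * 6 / 7 ^ 8 sqrt 9 neg.
rpn_compile <- function(expr, species_names, params = numeric()) {
  code <- integer()
  consts <- numeric()
  depth <- 0L
  max_depth <- 0L
  push <- function(op, arg = NULL) {
    code <<- c(code, op, arg)
    if (op %in% c(1L, 2L)) {
      depth <<- depth + 1L
    } else if (op %in% c(3L, 4L, 5L, 6L, 7L)) {
      depth <<- depth - 1L
    }
    max_depth <<- max(max_depth, depth)
  }
  rec <- function(e) {
    if (is.numeric(e)) {
      consts <<- c(consts, as.numeric(e))
      push(1L, length(consts) - 1L)
    } else if (is.name(e)) {
      nm <- as.character(e)
      if (nm %in% species_names) {
        push(2L, match(nm, species_names) - 1L)
      } else if (nm %in% names(params)) {
        consts <<- c(consts, unname(params[[nm]]))
        push(1L, length(consts) - 1L)
      } else {
        stop("symbol `", nm, "` is neither a declared species nor a parameter",
             call. = FALSE)
      }
    } else if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "(") {
        rec(e[[2]])
      } else if (op == "-" && length(e) == 2) {
        rec(e[[2]]); push(9L)
      } else if (op == "+" && length(e) == 2) {
        rec(e[[2]])
      } else if (op == "sqrt") {
        rec(e[[2]]); push(8L)
      } else if (op %in% c("+", "-", "*", "/", "^")) {
        rec(e[[2]]); rec(e[[3]])
        push(c("+" = 3L, "-" = 4L, "*" = 5L, "/" = 6L, "^" = 7L)[[op]])
      } else {
        stop("`", op, "` is not in the allowed rate-law grammar", call. = FALSE)
      }
    } else {
      stop("unsupported construct in rate expression", call. = FALSE)
    }
  }
  rec(expr)
  if (max_depth > 60L) stop("rate expression too deeply nested", call. = FALSE)
  list(code = as.integer(code), consts = as.numeric(consts))
}

# Evaluate a rate law in R at a named concentration state (reference path;
# the engines use the compiled bytecode).
eval_rate_law <- function(rl, state, reactants = NULL) {
  if (rl$kind == "mass_action") {
    v <- rl$k
    if (length(reactants)) {
      v <- v * prod(state[names(reactants)]^unname(reactants))
    }
    unname(v)
  } else {
    unname(eval(rl$expr, envir = c(as.list(state), as.list(rl$params))))
  }
}

#' @export
print.rate_law <- function(x, ...) {
  if (x$kind == "mass_action") {
    cat("<rate law> mass action, k =", format(x$k), "\n")
  } else {
    cat("<rate law>", deparse1(x$expr), "\n")
    if (length(x$params)) {
      cat("  params:", paste(names(x$params), format(unname(x$params)),
                             sep = " = ", collapse = ", "), "\n")
    }
  }
  invisible(x)
}
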
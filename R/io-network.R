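# Network definition files: a nested key-value (YAML) format declaring
# species, parameters, reactions, conservation laws and the volume. Rate
# expressions use the same whitelisted grammar as rate_expr().

#' Read / write a network definition file
#'
#' The file is YAML with the layout:
#' \preformatted{
#' name: genetic_nfl_reduced
#' volume: 1
#' parameters: {alpha_M: 300, K_D: 10, beta_M: 1}
#' species:
#'   - {name: M, role: slow, initial: 100, range: [0, .inf]}
#'   - {name: R, role: slow, initial: 100, range: [0, .inf]}
#' reactions:
#'   - name: transcription
#'     products: {M: 1}
#'     rate: {kind: closed_form, expression: "alpha_M * K_D / (K_D + R)"}
#'   - name: mRNA_decay
#'     reactants: {M: 1}
#'     rate: {kind: mass_action, constant: 1}
#' }
#' Closed-form expressions may use the global `parameters` plus species
#' names, restricted to `+ - * / ^ sqrt` and parentheses. Optional keys:
#' `conservation` (list of `{coefficients: {...}, total: x}`) and
#' `prefactor` (map species -> expression).
#'
#' @param path File path.
#' @return A [reaction_network()].
#' @export
read_network_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  pars <- unlist(doc$parameters %||% list())
  species <- lapply(doc$species, function(s) {
    rng <- s$range %||% c(0, Inf)
    species_spec(s$name, s$role %||% "slow", s$initial %||% 0,
                 lo = rng[[1]], hi = if (is.null(rng[[2]])) Inf else rng[[2]])
  })
  sp_names <- vapply(doc$species, `[[`, "", "name")
  reactions <- lapply(doc$reactions, function(r) {
    rate <- r$rate
    rl <- if (identical(rate$kind, "mass_action")) {
      mass_action(rate$constant)
    } else if (identical(rate$kind, "closed_form")) {
      e <- str2lang(rate$expression)
      used <- setdiff(check_rate_grammar(e), sp_names)
      local_pars <- unlist(rate$parameters %||% list())
      all_pars <- c(local_pars, pars[setdiff(used, names(local_pars))])
      missing <- setdiff(used, names(all_pars))
      if (length(missing))
        stop("reaction `", r$name, "` uses undefined parameters: ",
             paste(missing, collapse = ", "), call. = FALSE)
      rate_expr(e, params = all_pars[used])
    } else {
      stop("reaction `", r$name, "`: rate kind must be mass_action or closed_form",
           call. = FALSE)
    }
    reaction(r$name, unlist(r$reactants %||% NULL), unlist(r$products %||% NULL), rl)
  })
  conservation <- lapply(doc$conservation %||% list(), function(cl) {
    conservation_law(unlist(cl$coefficients), cl$total)
  })
  prefactor <- NULL
  if (!is.null(doc$prefactor)) {
    prefactor <- lapply(doc$prefactor, function(ex) {
      e <- str2lang(ex)
      used <- setdiff(check_rate_grammar(e), sp_names)
      rate_expr(e, params = pars[used])
    })
  }
  reaction_network(species = species, reactions = reactions,
                   conservation = conservation, volume = doc$volume %||% 1,
                   prefactor = prefactor, name = doc$name)
}

#' @rdname read_network_yaml
#' @param network A [reaction_network()].
#' @export
write_network_yaml <- function(network, path) {
  sp <- network$species
  doc <- list(
    name = network$name,
    volume = network$volume,
    species = lapply(seq_len(nrow(sp)), function(i) {
      list(name = sp$name[i], role = sp$role[i], initial = sp$initial[i],
           range = list(sp$lo[i], if (is.finite(sp$hi[i])) sp$hi[i] else NULL))
    }),
    reactions = lapply(unname(network$reactions), function(r) {
      rate <- if (r$rate$kind == "mass_action") {
        list(kind = "mass_action", constant = r$rate$k)
      } else {
        list(kind = "closed_form", expression = deparse1(r$rate$expr),
             parameters = as.list(r$rate$params))
      }
      out <- list(name = r$name, rate = rate)
      if (length(r$reactants)) out$reactants <- as.list(r$reactants)
      if (length(r$products)) out$products <- as.list(r$products)
      out
    }))
  if (length(network$conservation)) {
    doc$conservation <- lapply(network$conservation, function(cl) {
      list(coefficients = as.list(cl$coef), total = cl$total)
    })
  }
  if (is_prefactored(network)) {
    doc$prefactor <- lapply(network$prefactor, function(p) deparse1(p$expr))
    pf_pars <- do.call(c, unname(lapply(network$prefactor, function(p) p$params)))
    if (length(pf_pars)) doc$parameters <- as.list(pf_pars[!duplicated(names(pf_pars))])
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}
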
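# Flux balance analysis.
#
# Steady state means every internal metabolite is mass-balanced: for each
# metabolite c, sum_r S[c, r] * v_r = 0. Within flux bounds l_r <= v_r <= u_r
# the biomass flux v_bio is maximized; its optimum is the predicted growth
# rate (gDW/h). A gene knockout enters as the set of reactions whose GPR went
# FALSE, with those reactions' bounds clamped to [0, 0].

#' Maximize biomass flux (FBA)
#'
#' Builds and solves the growth LP: `max v_bio` subject to `S v = 0` and the
#' flux bounds, with `disabled_reactions` clamped to zero flux. Unbounded
#' directions are capped at `config$big_M` before solving. Every optimal
#' solution is re-checked against the mass-balance residuals and bounds within
#' `config$feas_tol` (the feasibility certificate); an objective within
#' `config$opt_tol` of zero is reported as exactly 0.
#'
#' @param model a [metabolic_model].
#' @param disabled_reactions character vector of reaction ids to knock out.
#' @param config a [solver_config].
#' @return a list of class `flux_solution` with `status`
#'   (`"optimal"`/`"infeasible"`/`"unbounded"`), `objective` (biomass flux;
#'   `NA` unless optimal), `fluxes` (named vector) and `residual_max`.
#' @examples
#' mod <- build_polyamine_minimodel()
#' maximize_biomass(mod)$objective
#' maximize_biomass(mod, disabled_reactions = "R_AMD1")$objective
#' @export
maximize_biomass <- function(model, disabled_reactions = character(0),
                             config = solver_config()) {
  stopifnot(inherits(model, "metabolic_model"))
  rxn_ids <- reaction_ids(model)
  bad <- setdiff(disabled_reactions, rxn_ids)
  if (length(bad) > 0) {
    stop("disabled_reactions not in model: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bio <- match(model$biomass_reaction_id, rxn_ids)
  if (is.na(bio)) stop("model has no biomass reaction", call. = FALSE)

  S <- stoich_matrix(model)
  lower <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  upper <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  lower <- pmax(lower, -config$big_M)
  upper <- pmin(upper, config$big_M)
  off <- rxn_ids %in% disabled_reactions
  lower[off] <- 0
  upper[off] <- 0

  obj <- numeric(length(rxn_ids))
  obj[bio] <- 1

  res <- solve_lp(obj, S, lower, upper, maximize = TRUE, config = config)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective = NA_real_,
                          fluxes = setNames(rep(NA_real_, length(rxn_ids)), rxn_ids),
                          residual_max = NA_real_),
                     class = "flux_solution"))
  }
  v <- res$x
  resid <- max(abs(S %*% v), 0)
  scale <- max(1, max(abs(v)))
  if (resid > config$feas_tol * scale ||
      any(v < lower - config$feas_tol * scale) ||
      any(v > upper + config$feas_tol * scale)) {
    stop(sprintf(paste0("solver returned an infeasible optimum (max residual %.3g); ",
                        "backend '%s' failed its feasibility certificate"),
                 resid, config$backend), call. = FALSE)
  }
  objective <- res$objective
  if (abs(objective) <= config$opt_tol) objective <- 0
  structure(list(status = "optimal", objective = objective,
                 fluxes = setNames(v, rxn_ids), residual_max = resid),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (identical(x$status, "optimal")) {
    cat(sprintf("  biomass flux: %.6g gDW/h", x$objective))
  }
  cat("\n")
  invisible(x)
}

#' Apply a growth medium to a model
#'
#' The medium is a named vector mapping exchange-reaction ids to the maximum
#' intake flux of the corresponding nutrient. Exchange reactions are written
#' `met <-> (nothing)`, so intake is negative flux: a medium entry of 10 sets
#' the exchange lower bound to -10. Every exchange *not* listed has its intake
#' fixed to zero (the substrate is not available), while secretion through it
#' stays open — matching the convention that non-available substrates get zero
#' uptake flux.
#'
#' @param model a [metabolic_model].
#' @param medium named numeric vector (exchange id -> max intake, >= 0).
#' @return a modified copy of the model with `model$medium` replaced.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "metabolic_model"))
  if (length(medium) > 0 && (is.null(names(medium)) || any(!nzchar(names(medium))))) {
    stop("medium must be a named vector of exchange reaction ids", call. = FALSE)
  }
  rxn_ids <- reaction_ids(model)
  unknown <- setdiff(names(medium), rxn_ids)
  if (length(unknown) > 0) {
    stop("medium references unknown reaction(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (ex in names(medium)) {
    if (!get_reaction(model, ex)$is_exchange) {
      stop("medium entry '", ex, "' is not an exchange reaction", call. = FALSE)
    }
    if (medium[[ex]] < 0) stop("medium intake for '", ex, "' must be >= 0", call. = FALSE)
  }
  for (i in seq_along(model$reactions)) {
    rxn <- model$reactions[[i]]
    if (!rxn$is_exchange) next
    intake <- if (rxn$id %in% names(medium)) medium[[rxn$id]] else 0
    rxn$lower_bound <- -intake
    rxn$reversible <- rxn$lower_bound < 0
    model$reactions[[i]] <- rxn
  }
  model$medium <- medium[order(names(medium))]
  validate_model(model)
  model
}
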
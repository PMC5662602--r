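# Constraint-based metabolic model containers.
#
# A metabolic_model is a plain list with insertion-ordered metabolites and
# reactions, a gene set, a designated biomass reaction and a growth medium.
# Insertion order is part of the contract: the stoichiometric matrix, and
# hence every LP, is built in that order, so results are reproducible.

#' Create a metabolite
#'
#' @param id unique nonempty id string.
#' @param name free-text name.
#' @param compartment compartment tag (default `"c"`).
#' @return a list of class `metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = "c") {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment),
            class = "metabolite")
}

#' Create a reaction
#'
#' Stoichiometry follows the usual convention: substrates carry negative
#' coefficients, products positive. Exchange reactions are written
#' `met <-> (nothing)` with a single coefficient of -1; negative flux is
#' uptake, positive flux secretion. Coefficients are stored as exact rationals
#' (pass `"1/3"` or `0.01` and get it back verbatim from the serializer).
#'
#' @param id unique reaction id.
#' @param stoichiometry named vector (metabolite id -> coefficient); values may
#'   be numeric or strings such as `"1/2"`.
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param reversible logical; irreversible reactions must have
#'   `lower_bound >= 0`.
#' @param gpr GPR rule string (parsed with [parse_gpr()]) or an AST.
#' @param is_exchange logical; exchange/sink reactions touch exactly one
#'   metabolite.
#' @param name free-text name.
#' @return a list of class `reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     reversible = lower_bound < 0, gpr = "",
                     is_exchange = FALSE, name = id) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  mets <- names(stoichiometry)
  if (length(stoichiometry) > 0 && (is.null(mets) || any(!nzchar(mets)))) {
    stop("stoichiometry must be a named vector of metabolite coefficients", call. = FALSE)
  }
  rat <- as_rational(unname(stoichiometry))
  if (any(rat$num == 0)) {
    stop("reaction ", id, ": zero stoichiometric coefficients are not allowed", call. = FALSE)
  }
  rule <- if (inherits(gpr, "gpr_rule")) gpr else parse_gpr(gpr)
  structure(list(
    id = id, name = name,
    stoich = list(met = as.character(mets), num = rat$num, den = rat$den),
    lower_bound = as.numeric(lower_bound),
    upper_bound = as.numeric(upper_bound),
    reversible = isTRUE(reversible),
    gpr = rule,
    is_exchange = isTRUE(is_exchange)
  ), class = "reaction")
}

#' Numeric stoichiometry of a reaction
#' @param rxn a [reaction].
#' @return named numeric vector (metabolite id -> coefficient).
#' @export
reaction_coefficients <- function(rxn) {
  setNames(rxn$stoich$num / rxn$stoich$den, rxn$stoich$met)
}

#' Assemble a constraint-based metabolic model
#'
#' @param metabolites list of [metabolite] objects.
#' @param reactions list of [reaction] objects.
#' @param genes character vector of gene ids; every GPR leaf must be a member.
#' @param biomass_reaction_id id of the biomass (growth) reaction.
#' @param medium named numeric vector: exchange reaction id -> maximum uptake
#'   flux (a positive number; uptake itself is carried as negative flux).
#' @param id model id string.
#' @return a list of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes, biomass_reaction_id,
                            medium = NULL, id = "model") {
  model <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    genes = sort(unique(as.character(genes))),
    biomass_reaction_id = biomass_reaction_id,
    medium = if (is.null(medium)) setNames(numeric(0), character(0)) else medium
  ), class = "metabolic_model")
  validate_model(model)
  model
}

metabolite_ids <- function(model) vapply(model$metabolites, `[[`, character(1), "id")

#' Reaction ids of a model, in insertion order
#' @param model a [metabolic_model].
#' @return character vector.
#' @export
reaction_ids <- function(model) vapply(model$reactions, `[[`, character(1), "id")

#' Look up a reaction by id
#' @param model a [metabolic_model].
#' @param id reaction id.
#' @return the [reaction], or an error if absent.
#' @export
get_reaction <- function(model, id) {
  i <- match(id, reaction_ids(model))
  if (is.na(i)) stop("no reaction with id '", id, "'", call. = FALSE)
  model$reactions[[i]]
}

#' Validate a metabolic model
#'
#' Checks ids, bounds, GPR gene membership, stoichiometry references and the
#' biomass designation. All violations are aggregated and reported in a single
#' error so a broken model file is diagnosed in one pass.
#'
#' @param model a [metabolic_model].
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  errors <- character(0)
  met_ids <- metabolite_ids(model)
  if (anyDuplicated(met_ids)) {
    errors <- c(errors, paste0("duplicate metabolite ids: ",
                               paste(unique(met_ids[duplicated(met_ids)]), collapse = ", ")))
  }
  rxn_ids <- reaction_ids(model)
  if (anyDuplicated(rxn_ids)) {
    errors <- c(errors, paste0("duplicate reaction ids: ",
                               paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  }
  for (rxn in model$reactions) {
    if (rxn$lower_bound > rxn$upper_bound) {
      errors <- c(errors, paste0("reaction ", rxn$id, ": lower_bound > upper_bound"))
    }
    if (!rxn$reversible && rxn$lower_bound < 0) {
      errors <- c(errors, paste0("reaction ", rxn$id,
                                 ": irreversible but lower_bound < 0"))
    }
    dangling <- setdiff(rxn$stoich$met, met_ids)
    if (length(dangling) > 0) {
      errors <- c(errors, paste0("reaction ", rxn$id, ": undeclared metabolite(s) ",
                                 paste(dangling, collapse = ", ")))
    }
    n_met <- length(rxn$stoich$met)
    if (rxn$is_exchange && n_met != 1) {
      errors <- c(errors, paste0("reaction ", rxn$id,
                                 ": exchange reactions must touch exactly one metabolite"))
    }
    if (!rxn$is_exchange && n_met == 0) {
      errors <- c(errors, paste0("reaction ", rxn$id, ": empty stoichiometry"))
    }
    bad_genes <- setdiff(gpr_genes(rxn$gpr), model$genes)
    if (length(bad_genes) > 0) {
      errors <- c(errors, paste0("reaction ", rxn$id, ": GPR gene(s) not in model gene set: ",
                                 paste(bad_genes, collapse = ", ")))
    }
  }
  if (is.null(model$biomass_reaction_id) || !nzchar(model$biomass_reaction_id %||% "")) {
    errors <- c(errors, "missing biomass_reaction_id")
  } else if (!(model$biomass_reaction_id %in% rxn_ids)) {
    errors <- c(errors, paste0("biomass_reaction_id '", model$biomass_reaction_id,
                               "' is not a reaction in the model"))
  }
  bad_medium <- setdiff(names(model$medium), rxn_ids)
  if (length(bad_medium) > 0) {
    errors <- c(errors, paste0("medium references unknown reaction(s): ",
                               paste(bad_medium, collapse = ", ")))
  }
  for (ex in names(model$medium)) {
    if (ex %in% rxn_ids && !get_reaction(model, ex)$is_exchange) {
      errors <- c(errors, paste0("medium entry '", ex, "' is not an exchange reaction"))
    }
  }
  if (length(errors) > 0) {
    stop("invalid model:\n  - ", paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  invisible(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stoichiometric matrix of a model
#'
#' Rows are metabolites, columns reactions, both in insertion order. Rational
#' coefficients are converted to doubles here and nowhere earlier.
#'
#' @param model a [metabolic_model].
#' @return dense numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model) {
  met_ids <- metabolite_ids(model)
  rxn_ids <- reaction_ids(model)
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    rxn <- model$reactions[[j]]
    S[rxn$stoich$met, j] <- rxn$stoich$num / rxn$stoich$den
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      "  reactions: ", length(x$reactions),
      "  genes: ", length(x$genes), "\n", sep = "")
  cat("  biomass reaction: ", x$biomass_reaction_id, "\n", sep = "")
  n_ex <- sum(vapply(x$reactions, `[[`, logical(1), "is_exchange"))
  cat("  exchange/sink reactions: ", n_ex,
      "  medium entries: ", length(x$medium), "\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  print(object)
  rev <- sum(vapply(object$reactions, `[[`, logical(1), "reversible"))
  with_gpr <- sum(vapply(object$reactions, function(r) r$gpr$type != "empty", logical(1)))
  cat("  reversible reactions: ", rev,
      "  gene-associated reactions: ", with_gpr, "\n", sep = "")
  invisible(object)
}

# Replace a reaction (by id) in a copy of the model; used by curation edits.
set_reaction <- function(model, rxn) {
  i <- match(rxn$id, reaction_ids(model))
  if (is.na(i)) stop("no reaction with id '", rxn$id, "'", call. = FALSE)
  model$reactions[[i]] <- rxn
  model
}
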
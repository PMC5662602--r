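# Model serialization: a documented subset of the community COBRA JSON schema.
#
# Top-level keys: id, metabolites[], reactions[], genes[], biomass_reaction_id,
# medium{}. Reaction entries: id, name, stoichiometry{met: coeff},
# lower_bound, upper_bound, reversible, gpr (string), is_exchange.
# Coefficients are written as bare numbers when integral and as "p/q" strings
# otherwise, so write -> read is the identity on the rational representation.
# The schema ships at inst/extdata/model.schema.json.

model_to_list <- function(model) {
  list(
    id = model$id,
    metabolites = lapply(model$metabolites, function(m) {
      list(id = m$id, name = m$name, compartment = m$compartment)
    }),
    reactions = lapply(model$reactions, function(r) {
      st <- mapply(rat_serialize, r$stoich$num, r$stoich$den, SIMPLIFY = FALSE)
      names(st) <- r$stoich$met
      list(id = r$id, name = r$name, stoichiometry = st,
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           reversible = r$reversible, gpr = gpr_to_string(r$gpr),
           is_exchange = r$is_exchange)
    }),
    genes = as.list(model$genes),
    biomass_reaction_id = model$biomass_reaction_id,
    medium = as.list(model$medium)
  )
}

#' Serialize a model to its JSON text
#'
#' @param model a [metabolic_model].
#' @return a single JSON string (pretty-printed, deterministic for a given
#'   model, full double precision).
#' @export
model_to_json <- function(model) {
  as.character(jsonlite::toJSON(model_to_list(model), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE))
}

#' Write a model to a JSON file
#' @param model a [metabolic_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  writeLines(model_to_json(model), path)
  invisible(path)
}

#' Read a model from a JSON file
#'
#' Accepts the dialect written by [write_model()]; unknown reaction-level keys
#' are ignored so trimmed COBRA JSON exports with only the supported fields
#' load too. All validation problems are aggregated into one error message.
#'
#' @param path JSON file path.
#' @return a [metabolic_model].
#' @export
read_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  errors <- character(0)
  for (key in c("metabolites", "reactions", "genes", "biomass_reaction_id")) {
    if (is.null(raw[[key]])) errors <- c(errors, paste0("missing top-level key '", key, "'"))
  }
  if (length(errors) > 0) {
    stop("invalid model file:\n  - ", paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  mets <- lapply(raw$metabolites, function(m) {
    if (is.null(m$id)) { errors <<- c(errors, "metabolite entry without id"); return(NULL) }
    metabolite(m$id, m$name %||% m$id, m$compartment %||% "c")
  })
  rxns <- lapply(raw$reactions, function(r) {
    if (is.null(r$id)) { errors <<- c(errors, "reaction entry without id"); return(NULL) }
    st <- r$stoichiometry
    if (is.null(st) || length(st) == 0) st <- setNames(list(), character(0))
    coeffs <- setNames(vapply(st, function(v) as.character(v), character(1)), names(st))
    tryCatch(
      reaction(r$id,
               stoichiometry = coeffs,
               lower_bound = r$lower_bound %||% 0,
               upper_bound = r$upper_bound %||% 1000,
               reversible = r$reversible %||% ((r$lower_bound %||% 0) < 0),
               gpr = r$gpr %||% "",
               is_exchange = r$is_exchange %||% FALSE,
               name = r$name %||% r$id),
      error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL }
    )
  })
  if (length(errors) > 0) {
    stop("invalid model file:\n  - ", paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  medium <- raw$medium %||% list()
  metabolic_model(
    metabolites = mets,
    reactions = rxns,
    genes = unlist(raw$genes, use.names = FALSE) %||% character(0),
    biomass_reaction_id = raw$biomass_reaction_id,
    medium = setNames(vapply(medium, as.numeric, numeric(1)), names(medium)),
    id = raw$id %||% "model"
  )
}

#' Export a flux vector as TSV
#'
#' Two tab-separated columns (`reaction`, `flux`), one header row, fluxes with
#' 12 significant digits. Mainly a debugging aid.
#'
#' @param solution a [flux_solution][maximize_biomass].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(solution, path) {
  lines <- c("reaction\tflux",
             sprintf("%s\t%.12g", names(solution$fluxes), solution$fluxes))
  writeLines(lines, path)
  invisible(path)
}
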
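# Model curation edits.
#
# Two edits drive the polyamine analysis: (1) adding putrescine, spermidine
# and spermine as biomass components, so the screen can see the pathway at
# all; (2) removing the adenine-degrading activity mis-annotated to PNP —
# human PNP acts on guanine, hypoxanthine and uracil ribonucleosides but does
# not consume adenine, so the adenine-PNP reaction inherited from prokaryotic
# annotation is deleted. Edit (2) turns APRT from one half of a spurious
# synthetic-lethal pair into an essential gene.

#' Biomass specification
#'
#' @param additions named numeric vector: metabolite id -> positive
#'   stoichiometric demand (mmol consumed per gDW of biomass).
#' @return named numeric vector of class `biomass_spec`.
#' @export
biomass_spec <- function(additions) {
  if (length(additions) > 0) {
    if (is.null(names(additions)) || any(!nzchar(names(additions)))) {
      stop("biomass spec must be a named vector of metabolite coefficients", call. = FALSE)
    }
    if (any(additions <= 0)) {
      stop("biomass spec coefficients must be positive (they are demands)", call. = FALSE)
    }
  }
  structure(additions, class = "biomass_spec")
}

#' Default polyamine biomass additions
#'
#' Putrescine, spermidine and spermine at 0.01 mmol/gDW each — the order of
#' magnitude used for minor biomass species in published reconstructions. The
#' value is a configurable stand-in: lethality verdicts on the polyamine
#' pathway are invariant to it over several orders of magnitude (the demand
#' only has to be nonzero), and a test holds the screen to that.
#'
#' @param coefficient demand per polyamine, mmol/gDW (default 0.01).
#' @param metabolites ids of the three polyamines in the target model.
#' @return a [biomass_spec].
#' @export
polyamine_biomass_spec <- function(coefficient = 0.01,
                                   metabolites = c("ptrc_c", "spmd_c", "sprm_c")) {
  stopifnot(coefficient > 0)
  biomass_spec(setNames(rep(coefficient, length(metabolites)), metabolites))
}

#' Augment the biomass reaction
#'
#' Adds each spec metabolite to the biomass reaction as a substrate (negative
#' coefficient). The edit is a replacement, not an increment: augmenting twice
#' with the same spec equals augmenting once. No other reaction is touched;
#' the input model is returned unchanged apart from the biomass stoichiometry.
#'
#' @param model a [metabolic_model].
#' @param spec a [biomass_spec] or named numeric vector; all metabolite ids
#'   must exist in the model.
#' @return the edited model (a copy).
#' @examples
#' mod <- build_polyamine_minimodel(include_polyamines_in_biomass = FALSE)
#' mod2 <- augment_biomass(mod, polyamine_biomass_spec())
#' single_deletion_screen(mod2)$essential_genes
#' @export
augment_biomass <- function(model, spec) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!inherits(spec, "biomass_spec")) spec <- biomass_spec(spec)
  if (length(spec) == 0) return(model)
  missing <- setdiff(names(spec), metabolite_ids(model))
  if (length(missing) > 0) {
    stop("biomass spec metabolite(s) absent from the model: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  bio <- get_reaction(model, model$biomass_reaction_id)
  for (met in names(spec)) {
    rat <- as_rational(spec[[met]])
    i <- match(met, bio$stoich$met)
    if (is.na(i)) {
      bio$stoich$met <- c(bio$stoich$met, met)
      bio$stoich$num <- c(bio$stoich$num, -rat$num)
      bio$stoich$den <- c(bio$stoich$den, rat$den)
    } else {
      bio$stoich$num[i] <- -rat$num
      bio$stoich$den[i] <- rat$den
    }
  }
  set_reaction(model, bio)
}

# Direction-agnostic test: can this reaction consume `met`? Forward if the
# coefficient is negative; in reverse if the reaction is reversible and the
# coefficient is positive.
reaction_consumes <- function(rxn, met) {
  i <- match(met, rxn$stoich$met)
  if (is.na(i)) return(FALSE)
  coeff <- rxn$stoich$num[i]
  coeff < 0 || (rxn$reversible && coeff > 0)
}

find_metabolite_id <- function(model, name_pattern, candidates) {
  ids <- metabolite_ids(model)
  hit <- intersect(candidates, ids)
  if (length(hit) > 0) return(hit[1])
  names_ <- vapply(model$metabolites, `[[`, character(1), "name")
  hit <- ids[grepl(name_pattern, names_, ignore.case = TRUE)]
  if (length(hit) > 0) return(hit[1])
  NA_character_
}

#' Correct the PNP adenine mis-annotation
#'
#' Removes every reaction that is gated by the PNP gene and can consume
#' adenine (in either direction for reversible reactions). PNP reactions on
#' its genuine substrates — guanine, hypoxanthine, uracil — are retained
#' untouched. If no PNP/adenine reaction exists the model is returned as-is
#' with an explicit warning, never silently.
#'
#' @param model a [metabolic_model].
#' @param gene gene symbol carrying the annotation (default `"PNP"`; settable
#'   for models using other identifier schemes).
#' @param adenine_id metabolite id of adenine; auto-detected by id
#'   (`ade_c`/`ade`/`adenine`) or by metabolite name when `NULL`.
#' @return the edited model, with the removed reaction ids in
#'   `attr(, "removed_reactions")`.
#' @examples
#' mod <- build_polyamine_minimodel(corrected_pnp = FALSE)
#' fixed <- correct_pnp_annotation(mod)
#' attr(fixed, "removed_reactions")
#' @export
correct_pnp_annotation <- function(model, gene = "PNP", adenine_id = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(adenine_id)) {
    adenine_id <- find_metabolite_id(model, "^adenine$", c("ade_c", "ade", "adenine"))
  }
  removed <- character(0)
  if (!is.na(adenine_id)) {
    for (rxn in model$reactions) {
      if (gene %in% gpr_genes(rxn$gpr) && reaction_consumes(rxn, adenine_id)) {
        removed <- c(removed, rxn$id)
      }
    }
  }
  if (length(removed) == 0) {
    warning("no ", gene, "-associated adenine-consuming reaction found; model unchanged",
            call. = FALSE)
    attr(model, "removed_reactions") <- character(0)
    return(model)
  }
  model$reactions <- model$reactions[!(reaction_ids(model) %in% removed)]
  model$medium <- model$medium[setdiff(names(model$medium), removed)]
  validate_model(model)
  attr(model, "removed_reactions") <- removed
  model
}

#' Add the hypothetical XDH adenine-detoxification branch
#'
#' Optional exploratory edit: adds an adenine -> 2,8-dihydroxyadenine (DHA)
#' reaction gated by xanthine dehydrogenase (XDH) plus a DHA sink. DHA is a
#' poorly soluble, growth-suppressive end product, not a productive outlet, so
#' the sink ships *closed* (`dha_sink_ub = 0`): the branch is present for
#' exploration but cannot carry steady-state flux, and APRT keeps its
#' essentiality on the corrected model. Raising `dha_sink_ub` turns DHA
#' accumulation into a free drain and shows the rescue that the toxicity
#' argument rules out. Applying the edit twice is a no-op.
#'
#' @param model a [metabolic_model].
#' @param enabled apply the edit? `FALSE` returns the model unchanged.
#' @param adenine_id as in [correct_pnp_annotation()].
#' @param dha_sink_ub upper bound of the DHA sink (default 0, closed).
#' @return the (possibly) edited model.
#' @export
add_xdh_branch <- function(model, enabled = TRUE, adenine_id = NULL,
                           dha_sink_ub = 0) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!enabled) return(model)
  if ("R_XDH" %in% reaction_ids(model)) return(model)  # idempotent
  if (is.null(adenine_id)) {
    adenine_id <- find_metabolite_id(model, "^adenine$", c("ade_c", "ade", "adenine"))
  }
  if (is.na(adenine_id)) stop("model has no adenine metabolite", call. = FALSE)
  if ("dha_c" %in% metabolite_ids(model)) {
    stop("metabolite id collision: 'dha_c' already exists", call. = FALSE)
  }
  if ("SK_dha" %in% reaction_ids(model)) {
    stop("reaction id collision: 'SK_dha' already exists", call. = FALSE)
  }
  model$metabolites <- c(model$metabolites,
                         list(metabolite("dha_c", "2,8-dihydroxyadenine", "c")))
  model$genes <- sort(unique(c(model$genes, "XDH")))
  model$reactions <- c(model$reactions, list(
    reaction("R_XDH", setNames(c(-1, 1), c(adenine_id, "dha_c")),
             lower_bound = 0, upper_bound = 1000, gpr = "XDH",
             name = "xanthine dehydrogenase (adenine -> DHA)"),
    reaction("SK_dha", c(dha_c = -1), lower_bound = 0, upper_bound = dha_sink_ub,
             is_exchange = TRUE, name = "DHA sink (closed by default: DHA accumulates)")
  ))
  validate_model(model)
  model
}
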
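# Independent reachability oracle.
#
# For a restricted class of models the lethality question has an exact
# combinatorial answer that never touches an LP, which makes it a genuinely
# independent check on the FBA screen. The oracle treats the network as a
# directed hypergraph and asks two questions under a gene deletion:
#
#   1. Producibility: starting from the medium nutrients, a reaction can fire
#      once all its substrates are reachable (and its GPR is still TRUE);
#      metabolites reachable in the least fixpoint are producible.
#   2. Clearance: at steady state a reaction can only carry flux if every one
#      of its products is drained somewhere. "Drainable" is again a least
#      fixpoint: a metabolite is drainable if some active reaction consumes
#      it whose co-substrates are reachable and whose products are all
#      drainable, grounded in sinks/secretion exchanges. The least fixpoint
#      matters: two reactions that merely shuttle a metabolite back and forth
#      justify each other in a greatest fixpoint but drain nothing. Clearance
#      is the steady-state requirement that makes MTAP essential — spermidine
#      synthesis is impossible if its obligatory MTA byproduct cannot leave.
#
# Reactions failing either test are pruned and both fixpoints re-run until
# stable; biomass is producible iff the biomass reaction survives.

#' Check whether a model is inside the oracle-safe class
#'
#' Oracle-safe: every non-biomass stoichiometric coefficient is +1 or -1 (the
#' biomass reaction may use arbitrary negative demands — producibility of its
#' substrates does not depend on their magnitudes), and every reaction has
#' finite sensible bounds. The generator and the polyamine mini-model satisfy
#' this by construction.
#'
#' @param model a [metabolic_model].
#' @return `TRUE`, or a character vector of violations.
#' @export
oracle_safe <- function(model) {
  problems <- character(0)
  for (rxn in model$reactions) {
    if (identical(rxn$id, model$biomass_reaction_id)) next
    coeff <- rxn$stoich$num / rxn$stoich$den
    if (any(abs(coeff) != 1)) {
      problems <- c(problems, paste0("reaction ", rxn$id,
                                     ": non-unit stoichiometric coefficient"))
    }
  }
  if (length(problems) == 0) TRUE else problems
}

# Directed view of the active reactions: list of (id, subs, prods).
oracle_directed <- function(model, deleted) {
  dirs <- list()
  for (rxn in model$reactions) {
    if (!evaluate_gpr(rxn$gpr, deleted)) next
    coeff <- setNames(rxn$stoich$num, rxn$stoich$met)
    subs <- names(coeff)[coeff < 0]
    prods <- names(coeff)[coeff > 0]
    if (rxn$is_exchange) {
      met <- rxn$stoich$met[1]
      if (rxn$lower_bound < 0) {            # uptake: source of the metabolite
        dirs[[length(dirs) + 1]] <- list(id = paste0(rxn$id, ":in"),
                                         subs = character(0), prods = met)
      }
      if (rxn$upper_bound > 0) {            # secretion: drain for the metabolite
        dirs[[length(dirs) + 1]] <- list(id = paste0(rxn$id, ":out"),
                                         subs = met, prods = character(0))
      }
      next
    }
    if (rxn$upper_bound > 0) {
      dirs[[length(dirs) + 1]] <- list(id = paste0(rxn$id, ":fwd"),
                                       subs = subs, prods = prods)
    }
    if (rxn$reversible && rxn$lower_bound < 0) {
      dirs[[length(dirs) + 1]] <- list(id = paste0(rxn$id, ":rev"),
                                       subs = prods, prods = subs)
    }
  }
  dirs
}

#' Reachability oracle: is biomass producible under a deletion?
#'
#' LP-free steady-state producibility verdict for oracle-safe models (see
#' [oracle_safe()]); refuses — never guesses — outside that class. Agrees with
#' the FBA screen verdict (growth above vs below threshold) on every
#' oracle-safe instance; the test suite checks this exhaustively on generated
#' models and the mini-model.
#'
#' @param model an oracle-safe [metabolic_model].
#' @param deleted character vector of deleted gene ids.
#' @return logical: can the biomass reaction carry positive flux?
#' @examples
#' mod <- build_polyamine_minimodel()
#' reachability_oracle(mod, deleted = "MTAP")   # FALSE: MTA cannot be cleared
#' reachability_oracle(mod, deleted = character(0))
#' @export
reachability_oracle <- function(model, deleted = character(0)) {
  safe <- oracle_safe(model)
  if (!isTRUE(safe)) {
    stop("model is outside the oracle-safe class:\n  - ",
         paste(safe, collapse = "\n  - "), call. = FALSE)
  }
  unknown <- setdiff(deleted, model$genes)
  if (length(unknown) > 0) {
    stop("unknown gene id(s): ", paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  dirs <- oracle_directed(model, deleted)
  bio_fwd <- paste0(model$biomass_reaction_id, ":fwd")

  repeat {
    # least fixpoint 1: producible metabolites
    reachable <- character(0)
    repeat {
      grew <- FALSE
      for (d in dirs) {
        if (all(d$subs %in% reachable) && !all(d$prods %in% reachable)) {
          reachable <- union(reachable, d$prods)
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    # least fixpoint 2: drainable metabolites (grounded in product-free rxns)
    drainable <- character(0)
    repeat {
      grew <- FALSE
      for (d in dirs) {
        if (all(d$subs %in% reachable) && all(d$prods %in% drainable)) {
          new <- setdiff(d$subs, drainable)
          if (length(new) > 0) {
            drainable <- c(drainable, new)
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    keep <- vapply(dirs, function(d) {
      all(d$subs %in% reachable) && all(d$prods %in% drainable)
    }, logical(1))
    if (all(keep)) break
    dirs <- dirs[keep]
  }
  any(vapply(dirs, function(d) identical(d$id, bio_fwd), logical(1)))
}
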
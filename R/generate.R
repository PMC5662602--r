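# Seeded random-model generator with planted ground truth.
#
# Models are assembled from three motif kinds, each feeding the biomass
# reaction, so every lethality verdict is known by construction:
#   * linear chains: nutrient -> ... -> biomass substrate, every step gated by
#     its own single gene -> each chain gene is planted essential;
#   * redundant branches: one biomass substrate producible through two
#     parallel gene-gated routes -> the two branch genes form a planted
#     synthetic-lethal pair, neither essential alone;
#   * complex (AND) reactions: a bridge gated by "gA and gB" -> both subunit
#     genes planted essential.
# A gene-gated decoy reaction into a sinked dead-end byproduct is added as a
# planted non-essential gene. All coefficients are +/-1 and every byproduct
# has a sink, so the models sit inside the oracle-safe class of
# [reachability_oracle()]. All randomness (identifier tags, reaction
# shuffling, OR-rule vs parallel-reaction encoding of redundancy) flows from
# `seed`; the same seed yields byte-identical model JSON.

#' Generator parameters
#'
#' @param n_linear_chains number of essential-gene chains (default 2).
#' @param chain_length reactions (= genes) per chain (default 2).
#' @param n_redundant_branches number of planted synthetic-lethal pairs
#'   (default 2).
#' @param n_complex_reactions number of AND-gated bridges (default 1).
#' @param seed integer seed driving all randomness.
#' @return a list of class `generator_params`.
#' @export
generator_params <- function(n_linear_chains = 2, chain_length = 2,
                             n_redundant_branches = 2, n_complex_reactions = 1,
                             seed = 1) {
  stopifnot(n_linear_chains >= 0, chain_length >= 1,
            n_redundant_branches >= 0, n_complex_reactions >= 0)
  structure(list(n_linear_chains = n_linear_chains, chain_length = chain_length,
                 n_redundant_branches = n_redundant_branches,
                 n_complex_reactions = n_complex_reactions,
                 seed = as.integer(seed)),
            class = "generator_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random model with planted essentiality structure
#'
#' @param params a [generator_params].
#' @return list with `model` (a [metabolic_model]) and `truth` (class
#'   `planted_truth`: `essential_genes`, `synthetic_lethal_pairs` as `"A&B"`
#'   keys).
#' @examples
#' gm <- generate_model(generator_params(seed = 7))
#' gm$truth$essential_genes
#' @export
generate_model <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  if (params$n_linear_chains == 0 && params$n_redundant_branches == 0 &&
      params$n_complex_reactions == 0) {
    stop("degenerate parameters: no motif feeds biomass, the model cannot grow",
         call. = FALSE)
  }
  with_seed(params$seed, {
    tag <- paste(sample(letters, 4, replace = TRUE), collapse = "")
    mets <- list()
    rxns <- list()
    genes <- character(0)
    biomass_substrates <- character(0)
    essential <- character(0)
    sl_pairs <- character(0)

    add_met <- function(id) mets[[length(mets) + 1]] <<- metabolite(id)
    add_rxn <- function(r) rxns[[length(rxns) + 1]] <<- r
    ex_of <- function(met) {
      add_met(met)
      add_rxn(reaction(paste0("EX_", met), setNames(-1, met), lower_bound = -10,
                       upper_bound = 1000, reversible = TRUE, is_exchange = TRUE))
      paste0("EX_", met)
    }
    sink_of <- function(met) {
      add_met(met)
      add_rxn(reaction(paste0("SK_", met), setNames(-1, met), lower_bound = 0,
                       upper_bound = 1000, is_exchange = TRUE))
    }

    for (i in seq_len(params$n_linear_chains)) {
      prev <- sprintf("chain%d_%s_m0", i, tag)
      ex_of(prev)
      for (j in seq_len(params$chain_length)) {
        cur <- sprintf("chain%d_%s_m%d", i, tag, j)
        add_met(cur)
        g <- sprintf("gc%d_%d_%s", i, j, tag)
        genes <- c(genes, g)
        essential <- c(essential, g)
        add_rxn(reaction(sprintf("R_chain%d_%d_%s", i, j, tag),
                         setNames(c(-1, 1), c(prev, cur)), gpr = g))
        prev <- cur
      }
      biomass_substrates <- c(biomass_substrates, prev)
    }

    for (k in seq_len(params$n_redundant_branches)) {
      src <- sprintf("branch%d_%s_src", k, tag)
      dst <- sprintf("branch%d_%s_dst", k, tag)
      ex_of(src)
      add_met(dst)
      ga <- sprintf("ga%d_%s", k, tag)
      gb <- sprintf("gb%d_%s", k, tag)
      genes <- c(genes, ga, gb)
      sl_pairs <- c(sl_pairs, pair_key(ga, gb))
      if (stats::runif(1) < 0.5) {
        # two parallel reactions, one gene each
        add_rxn(reaction(sprintf("R_branch%d_a_%s", k, tag),
                         setNames(c(-1, 1), c(src, dst)), gpr = ga))
        add_rxn(reaction(sprintf("R_branch%d_b_%s", k, tag),
                         setNames(c(-1, 1), c(src, dst)), gpr = gb))
      } else {
        # one reaction with an OR rule over the two isozymes
        add_rxn(reaction(sprintf("R_branch%d_%s", k, tag),
                         setNames(c(-1, 1), c(src, dst)),
                         gpr = paste(ga, "or", gb)))
      }
      biomass_substrates <- c(biomass_substrates, dst)
    }

    for (q in seq_len(params$n_complex_reactions)) {
      src <- sprintf("cplx%d_%s_src", q, tag)
      dst <- sprintf("cplx%d_%s_dst", q, tag)
      ex_of(src)
      add_met(dst)
      g1 <- sprintf("gx%d_a_%s", q, tag)
      g2 <- sprintf("gx%d_b_%s", q, tag)
      genes <- c(genes, g1, g2)
      essential <- c(essential, g1, g2)
      add_rxn(reaction(sprintf("R_cplx%d_%s", q, tag),
                       setNames(c(-1, 1), c(src, dst)),
                       gpr = paste(g1, "and", g2)))
      biomass_substrates <- c(biomass_substrates, dst)
    }

    # decoy: gene-gated side reaction into a sinked dead end; never lethal
    decoy_src <- biomass_substrates[1]
    dead <- sprintf("decoy_%s_dead", tag)
    sink_of(dead)
    gd <- sprintf("gdecoy_%s", tag)
    genes <- c(genes, gd)
    add_rxn(reaction(sprintf("R_decoy_%s", tag), setNames(c(-1, 1), c(decoy_src, dead)),
                     gpr = gd))

    # biomass consumes every motif product
    add_rxn(reaction("R_BIOMASS", setNames(rep(-1, length(biomass_substrates)),
                                           biomass_substrates),
                     lower_bound = 0, upper_bound = 1000, name = "biomass"))

    # seed-dependent shuffle of non-biomass reaction order (insertion order is
    # the matrix order, so this varies the LP column layout across seeds)
    is_bio <- vapply(rxns, function(r) identical(r$id, "R_BIOMASS"), logical(1))
    rxns <- c(sample(rxns[!is_bio]), rxns[is_bio])

    ex_ids <- vapply(Filter(function(r) r$is_exchange && r$lower_bound < 0, rxns),
                     `[[`, character(1), "id")
    model <- metabolic_model(
      metabolites = mets, reactions = rxns, genes = genes,
      biomass_reaction_id = "R_BIOMASS",
      medium = setNames(rep(10, length(ex_ids)), sort(ex_ids)),
      id = sprintf("generated_seed%d", params$seed)
    )
    wt <- maximize_biomass(model)
    if (!identical(wt$status, "optimal") || wt$objective <= 0) {
      stop("generation error: the generated model cannot produce biomass", call. = FALSE)
    }
    truth <- structure(list(essential_genes = sort(essential),
                            synthetic_lethal_pairs = sort(sl_pairs)),
                       class = "planted_truth")
    list(model = model, truth = truth)
  })
}
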
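# Small hand-built models and utilities shared across tests.

# linear toy: A --(g1)--> B --> biomass, uptake of A capped at 5
toy_linear_model <- function() {
  metabolic_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("EX_A", c(A = -1), lower_bound = -5, upper_bound = 1000,
               reversible = TRUE, is_exchange = TRUE),
      reaction("R1", c(A = -1, B = 1), gpr = "g1"),
      reaction("R_BIO", c(B = -1), lower_bound = 0, upper_bound = 1000)
    ),
    genes = "g1",
    biomass_reaction_id = "R_BIO",
    medium = c(EX_A = 5),
    id = "toy_linear"
  )
}

# parallel toy: two routes A -> B gated by g1 / g2 (planted SL pair)
toy_parallel_model <- function() {
  metabolic_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("EX_A", c(A = -1), lower_bound = -5, upper_bound = 1000,
               reversible = TRUE, is_exchange = TRUE),
      reaction("R1a", c(A = -1, B = 1), gpr = "g1"),
      reaction("R1b", c(A = -1, B = 1), gpr = "g2"),
      reaction("R_BIO", c(B = -1), lower_bound = 0, upper_bound = 1000)
    ),
    genes = c("g1", "g2"),
    biomass_reaction_id = "R_BIO",
    medium = c(EX_A = 5),
    id = "toy_parallel"
  )
}

expect_same_set <- function(x, y) {
  expect_setequal(x, y)
  invisible(x)
}

# exhaustive LP screen vs reachability oracle comparison on one model
compare_oracle_lp <- function(model, threshold = 1e-4, config = solver_config()) {
  genes <- sort(model$genes)
  mismatches <- character(0)
  for (g in genes) {
    lp <- maximize_biomass(model, reactions_disabled_by(model, g), config)$objective >= threshold
    or <- reachability_oracle(model, g)
    if (lp != or) mismatches <- c(mismatches, g)
  }
  if (length(genes) >= 2) {
    combs <- utils::combn(genes, 2)
    for (k in seq_len(ncol(combs))) {
      pair <- combs[, k]
      lp <- maximize_biomass(model, reactions_disabled_by(model, pair), config)$objective >= threshold
      or <- reachability_oracle(model, pair)
      if (lp != or) mismatches <- c(mismatches, paste(pair, collapse = "+"))
    }
  }
  mismatches
}
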
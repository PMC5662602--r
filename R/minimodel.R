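# Curated mini-model of polyamine biosynthesis.
#
# The pathway, one compartment, with the gene associations that make the
# screen behave like the published cancer-model analysis:
#
#   methionine + ATP --MAT--> SAM            GPR: MAT1A or (MAT2A and MAT2B)
#   SAM --AMD1--> dcSAM + CO2
#   arginine --ARG1--> ornithine + urea
#   glutamate-5-semialdehyde <--OAT--> ornithine   (reversible)
#   ornithine --ODC1--> putrescine + CO2
#   putrescine + dcSAM --SRM--> spermidine + MTA
#   spermidine + dcSAM --SMS--> spermine + MTA
#   MTA + Pi --MTAP--> adenine + MTR1P
#   adenine + PRPP --APRT--> AMP + PPi
#   adenine --PNP--> adenosine                (the mis-annotation; removable)
#
# Load-bearing structural facts: MTAP is the only MTA consumer; APRT and PNP
# are the only adenine consumers before correction (APRT alone after); ARG1
# and OAT are the only ornithine producers. MTA has no sink, so at steady
# state spermidine/spermine synthesis is impossible unless MTA is drained
# through MTAP — that is what makes MTAP essential.

minimodel_metabolites <- function() {
  defs <- list(
    c("met_c", "L-methionine"), c("atp_c", "ATP"), c("sam_c", "S-adenosylmethionine"),
    c("dcsam_c", "decarboxylated SAM"), c("co2_c", "CO2"), c("ppi_c", "diphosphate"),
    c("pi_c", "phosphate"), c("arg_c", "L-arginine"), c("orn_c", "L-ornithine"),
    c("urea_c", "urea"), c("glu5sa_c", "L-glutamate 5-semialdehyde"),
    c("ptrc_c", "putrescine"), c("spmd_c", "spermidine"), c("sprm_c", "spermine"),
    c("mta_c", "5'-methylthioadenosine"), c("ade_c", "adenine"),
    c("mtr1p_c", "5-methylthioribose 1-phosphate"), c("amp_c", "AMP"),
    c("prpp_c", "PRPP"), c("adn_c", "adenosine"),
    c("prec_c", "generic biomass precursor")
  )
  lapply(defs, function(d) metabolite(d[1], d[2], "c"))
}

#' Build the curated polyamine pathway mini-model
#'
#' A deterministic, hand-curated constraint-based model of polyamine
#' biosynthesis: methionine/SAM/dcSAM supply, the ARG1/OAT ornithine
#' redundancy, the ODC1-SRM-SMS polyamine chain, MTA salvage through MTAP,
#' and adenine disposal through APRT (and, unless corrected, the
#' mis-annotated PNP adenine reaction). The biomass reaction consumes a
#' generic precursor (imported directly, so the pathway itself is dispensable
#' for baseline growth) plus, optionally, the three polyamines.
#'
#' Uptake of each medium nutrient is capped at 10 mmol/gDW/h, so wild-type
#' growth is exactly 10 gDW/h (limited by precursor intake); every lethal
#' knockout drops growth to exactly 0.
#'
#' @param corrected_pnp omit the adenine-consuming PNP reaction? (`FALSE`
#'   reproduces the mis-annotated source model; the PNP gene stays in the
#'   gene set either way.)
#' @param include_polyamines_in_biomass add putrescine, spermidine and
#'   spermine to the biomass reaction (via `polyamine_coefficient`)?
#' @param polyamine_coefficient biomass demand per polyamine, mmol/gDW.
#' @return a [metabolic_model].
#' @examples
#' mod <- build_polyamine_minimodel()
#' maximize_biomass(mod)$objective
#' @export
build_polyamine_minimodel <- function(corrected_pnp = FALSE,
                                      include_polyamines_in_biomass = TRUE,
                                      polyamine_coefficient = 0.01) {
  ex <- function(id, met) {
    reaction(id, setNames(-1, met), lower_bound = -10, upper_bound = 1000,
             reversible = TRUE, is_exchange = TRUE,
             name = paste("exchange of", met))
  }
  sink <- function(id, met) {
    reaction(id, setNames(-1, met), lower_bound = 0, upper_bound = 1000,
             is_exchange = TRUE, name = paste("sink for", met))
  }
  rxns <- list(
    ex("EX_met", "met_c"), ex("EX_arg", "arg_c"), ex("EX_glu5sa", "glu5sa_c"),
    ex("EX_pi", "pi_c"), ex("EX_prpp", "prpp_c"), ex("EX_atp", "atp_c"),
    ex("EX_prec", "prec_c"),
    reaction("R_MAT", c(met_c = -1, atp_c = -1, sam_c = 1, pi_c = 1, ppi_c = 1),
             gpr = "MAT1A or (MAT2A and MAT2B)",
             name = "methionine adenosyltransferase"),
    reaction("R_AMD1", c(sam_c = -1, dcsam_c = 1, co2_c = 1), gpr = "AMD1",
             name = "adenosylmethionine decarboxylase"),
    reaction("R_ARG1", c(arg_c = -1, orn_c = 1, urea_c = 1), gpr = "ARG1",
             name = "arginase"),
    reaction("R_OAT", c(glu5sa_c = -1, orn_c = 1), lower_bound = -1000,
             reversible = TRUE, gpr = "OAT",
             name = "ornithine transaminase (reversible)"),
    reaction("R_ODC1", c(orn_c = -1, ptrc_c = 1, co2_c = 1), gpr = "ODC1",
             name = "ornithine decarboxylase"),
    reaction("R_SRM", c(ptrc_c = -1, dcsam_c = -1, spmd_c = 1, mta_c = 1),
             gpr = "SRM", name = "spermidine synthase"),
    reaction("R_SMS", c(spmd_c = -1, dcsam_c = -1, sprm_c = 1, mta_c = 1),
             gpr = "SMS", name = "spermine synthase"),
    reaction("R_MTAP", c(mta_c = -1, pi_c = -1, ade_c = 1, mtr1p_c = 1),
             gpr = "MTAP", name = "5'-methylthioadenosine phosphorylase"),
    reaction("R_APRT", c(ade_c = -1, prpp_c = -1, amp_c = 1, ppi_c = 1),
             gpr = "APRT", name = "adenine phosphoribosyltransferase")
  )
  if (!corrected_pnp) {
    rxns <- c(rxns, list(
      reaction("R_PNP_ade", c(ade_c = -1, adn_c = 1), gpr = "PNP",
               name = "purine-nucleoside phosphorylase on adenine (mis-annotation)")
    ))
  }
  rxns <- c(rxns, list(
    sink("SK_co2", "co2_c"), sink("SK_ppi", "ppi_c"), sink("SK_urea", "urea_c"),
    sink("SK_mtr1p", "mtr1p_c"), sink("SK_amp", "amp_c"), sink("SK_adn", "adn_c")
  ))
  biomass_stoich <- c(prec_c = -1)
  if (include_polyamines_in_biomass) {
    rat <- as_rational(polyamine_coefficient)
    coeff <- paste0(-rat$num, "/", rat$den)
    biomass_stoich <- c(biomass_stoich,
                        setNames(rep(coeff, 3), c("ptrc_c", "spmd_c", "sprm_c")))
  }
  rxns <- c(rxns, list(
    reaction("R_BIOMASS", biomass_stoich, lower_bound = 0, upper_bound = 1000,
             name = "biomass")
  ))
  medium <- setNames(rep(10, 7), c("EX_met", "EX_arg", "EX_glu5sa", "EX_pi",
                                   "EX_prpp", "EX_atp", "EX_prec"))
  metabolic_model(
    metabolites = minimodel_metabolites(),
    reactions = rxns,
    genes = c("MAT1A", "MAT2A", "MAT2B", "AMD1", "ARG1", "OAT", "ODC1",
              "SRM", "SMS", "MTAP", "APRT", "PNP"),
    biomass_reaction_id = "R_BIOMASS",
    medium = medium,
    id = if (corrected_pnp) "polyamine_minimodel_corrected" else "polyamine_minimodel"
  )
}
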
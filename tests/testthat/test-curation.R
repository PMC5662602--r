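# Curation edits: biomass augmentation, PNP correction, XDH branch.

test_that("augmenting biomass with polyamines makes the pathway essential", {
  base <- build_polyamine_minimodel(include_polyamines_in_biomass = FALSE)
  aug <- augment_biomass(base, polyamine_biomass_spec())
  expect_true("ODC1" %in% single_deletion_screen(aug)$essential_genes)
  # biomass stoichiometry gained exactly the three demands
  bio <- get_reaction(aug, "R_BIOMASS")
  coeff <- reaction_coefficients(bio)
  expect_equal(unname(coeff[c("ptrc_c", "spmd_c", "sprm_c")]), rep(-0.01, 3))
  # only the biomass reaction changed
  for (id in setdiff(reaction_ids(base), "R_BIOMASS")) {
    expect_identical(get_reaction(aug, id), get_reaction(base, id))
  }
})

test_that("augmentation is idempotent and the empty spec is a no-op", {
  base <- build_polyamine_minimodel(include_polyamines_in_biomass = FALSE)
  spec <- polyamine_biomass_spec()
  once <- augment_biomass(base, spec)
  twice <- augment_biomass(once, spec)
  expect_identical(model_to_json(once), model_to_json(twice))
  expect_identical(model_to_json(augment_biomass(base, biomass_spec(setNames(numeric(0), character(0))))),
                   model_to_json(base))
  # screens of base and trivially-augmented base agree
  s1 <- single_deletion_screen(base)
  s2 <- single_deletion_screen(augment_biomass(base, setNames(numeric(0), character(0))))
  expect_identical(s1$essential_genes, s2$essential_genes)
  expect_equal(s1$single_growth, s2$single_growth)
})

test_that("augmentation validates its spec", {
  base <- build_polyamine_minimodel(include_polyamines_in_biomass = FALSE)
  expect_error(augment_biomass(base, c(nonexistent_c = 0.01)), "nonexistent_c")
  expect_error(biomass_spec(c(ptrc_c = -0.01)), "positive")
  expect_error(biomass_spec(c(ptrc_c = 0)), "positive")
})

test_that("PNP correction removes exactly the adenine reaction and reports it", {
  mod <- build_polyamine_minimodel()
  fixed <- correct_pnp_annotation(mod)
  expect_identical(attr(fixed, "removed_reactions"), "R_PNP_ade")
  expect_false("R_PNP_ade" %in% reaction_ids(fixed))
  # retained reactions keep their stoichiometry untouched
  for (id in reaction_ids(fixed)) {
    expect_identical(get_reaction(fixed, id)$stoich, get_reaction(mod, id)$stoich)
  }
  # re-correcting is an explicit no-op warning, never silent
  expect_warning(again <- correct_pnp_annotation(fixed), "model unchanged")
  expect_identical(model_to_json(again), model_to_json(fixed))
})

test_that("PNP reactions on genuine substrates are retained", {
  mod <- build_polyamine_minimodel()
  # variant where PNP also degrades guanine (its true activity)
  mod$metabolites <- c(mod$metabolites, list(metabolite("gua_c", "guanine"),
                                             metabolite("gsn_c", "guanosine")))
  mod$reactions <- c(mod$reactions, list(
    reaction("EX_gua", c(gua_c = -1), -10, 1000, TRUE, is_exchange = TRUE),
    reaction("R_PNP_gua", c(gua_c = -1, gsn_c = 1), gpr = "PNP"),
    reaction("SK_gsn", c(gsn_c = -1), 0, 1000, is_exchange = TRUE)
  ))
  validate_model(mod)
  fixed <- correct_pnp_annotation(mod)
  expect_identical(attr(fixed, "removed_reactions"), "R_PNP_ade")
  expect_true("R_PNP_gua" %in% reaction_ids(fixed))
})

test_that("a reversible PNP reaction producing adenine forward is also matched", {
  mod <- build_polyamine_minimodel(corrected_pnp = TRUE)
  # written in the producing direction but reversible -> can consume adenine
  mod$reactions <- c(mod$reactions, list(
    reaction("R_PNP_rev", c(adn_c = -1, ade_c = 1), lower_bound = -1000,
             reversible = TRUE, gpr = "PNP")
  ))
  validate_model(mod)
  fixed <- correct_pnp_annotation(mod)
  expect_identical(attr(fixed, "removed_reactions"), "R_PNP_rev")
})

test_that("essentiality calls are invariant to the polyamine coefficient over [1e-4, 1]", {
  for (coeff in c(1e-4, 1e-2, 1)) {
    mod <- build_polyamine_minimodel(polyamine_coefficient = coeff)
    scr <- double_deletion_screen(mod)
    expect_true(all(c("AMD1", "MTAP", "ODC1", "SRM") %in% scr$essential_genes),
                label = paste("coeff", coeff))
    expect_same_set(scr$synthetic_lethal_pairs,
                    c("APRT&PNP", "ARG1&OAT", "MAT1A&MAT2A", "MAT1A&MAT2B"))
    fixed <- correct_pnp_annotation(mod)
    expect_true("APRT" %in% single_deletion_screen(fixed)$essential_genes,
                label = paste("coeff", coeff))
  }
})

test_that("XDH branch is optional, idempotent and does not rescue APRT", {
  mod <- correct_pnp_annotation(build_polyamine_minimodel())
  expect_identical(model_to_json(add_xdh_branch(mod, enabled = FALSE)),
                   model_to_json(mod))
  with_xdh <- add_xdh_branch(mod, enabled = TRUE)
  expect_true("R_XDH" %in% reaction_ids(with_xdh))
  expect_identical(model_to_json(add_xdh_branch(with_xdh, enabled = TRUE)),
                   model_to_json(with_xdh))
  # the closed DHA sink means the branch carries no steady-state flux:
  # APRT remains essential on the corrected model
  scr <- single_deletion_screen(with_xdh)
  expect_true("APRT" %in% scr$essential_genes)
  # opening the sink turns DHA into a free drain and rescues APRT — the
  # scenario the toxicity argument excludes
  open <- add_xdh_branch(mod, enabled = TRUE, dha_sink_ub = 1000)
  expect_false("APRT" %in% single_deletion_screen(open)$essential_genes)
})
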
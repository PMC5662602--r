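# FBA engine: LP correctness, media, invariants, backends.

test_that("wild-type growth of the mini-model equals its hand-computed capacity", {
  # biomass is limited by the generic-precursor intake, capped at 10 mmol/gDW/h
  # with a coefficient of 1 in the biomass reaction -> optimum exactly 10
  mod <- build_polyamine_minimodel()
  sol <- maximize_biomass(mod)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  expect_gt(sol$objective, 1e-4)
  # with heavy polyamine demand the methionine supply binds: 3 dcSAM per unit
  # biomass from at most 10 methionine -> optimum 10/3
  heavy <- build_polyamine_minimodel(polyamine_coefficient = 1)
  expect_equal(maximize_biomass(heavy)$objective, 10 / 3, tolerance = 1e-8)
})

test_that("empty medium forces zero growth and AMD1 knockout is lethal", {
  mod <- build_polyamine_minimodel()
  starved <- apply_medium(mod, setNames(numeric(0), character(0)))
  expect_equal(maximize_biomass(starved)$objective, 0)
  expect_equal(maximize_biomass(mod, disabled_reactions = "R_AMD1")$objective, 0)
})

test_that("medium handling: omission closes uptake, matching medium is idempotent", {
  mod <- build_polyamine_minimodel()
  no_met <- apply_medium(mod, mod$medium[names(mod$medium) != "EX_met"])
  # methionine is the sole SAM precursor: polyamine-containing biomass collapses
  expect_equal(maximize_biomass(no_met)$objective, 0)
  same <- apply_medium(mod, mod$medium)
  expect_equal(maximize_biomass(same)$objective, maximize_biomass(mod)$objective)
  expect_error(apply_medium(mod, c(R_MAT = 5)), "not an exchange")
  expect_error(apply_medium(mod, c(EX_nope = 5)), "unknown")
})

test_that("optimal solutions satisfy the feasibility certificate", {
  mod <- build_polyamine_minimodel()
  for (disabled in list(character(0), "R_AMD1", c("R_APRT", "R_PNP_ade"), "R_MAT")) {
    sol <- maximize_biomass(mod, disabled_reactions = disabled)
    expect_identical(sol$status, "optimal")
    expect_lt(sol$residual_max, 1e-9 * max(1, max(abs(sol$fluxes))))
    for (id in disabled) expect_equal(unname(sol$fluxes[id]), 0)
    # bounds hold
    lb <- vapply(mod$reactions, `[[`, numeric(1), "lower_bound")
    ub <- vapply(mod$reactions, `[[`, numeric(1), "upper_bound")
    expect_true(all(sol$fluxes >= pmax(lb, -1000) - 1e-8))
    expect_true(all(sol$fluxes <= pmin(ub, 1000) + 1e-8))
  }
})

test_that("knockouts are monotone: disabling more reactions never raises growth", {
  mod <- build_polyamine_minimodel()
  set.seed(11)
  ids <- setdiff(reaction_ids(mod), "R_BIOMASS")
  for (i in 1:12) {
    a <- sample(ids, sample(0:3, 1))
    b <- union(a, sample(ids, sample(1:3, 1)))
    ga <- maximize_biomass(mod, a)$objective
    gb <- maximize_biomass(mod, b)$objective
    expect_lte(gb, ga + 1e-9)
  }
})

test_that("clamping a reaction to zero equals deleting its matrix column", {
  mod <- build_polyamine_minimodel()
  for (target in c("R_AMD1", "R_PNP_ade", "R_OAT")) {
    clamped <- maximize_biomass(mod, disabled_reactions = target)$objective
    pruned <- mod
    pruned$reactions <- pruned$reactions[reaction_ids(pruned) != target]
    deleted <- maximize_biomass(pruned)$objective
    expect_equal(clamped, deleted, tolerance = 1e-9)
  }
})

test_that("scaling a metabolite row leaves the optimum unchanged", {
  mod <- build_polyamine_minimodel()
  base <- maximize_biomass(mod)$objective
  scaled <- mod
  # multiply every coefficient of sam_c by 5 (exact rational scaling)
  for (i in seq_along(scaled$reactions)) {
    st <- scaled$reactions[[i]]$stoich
    j <- match("sam_c", st$met)
    if (!is.na(j)) {
      st$num[j] <- st$num[j] * 5
      scaled$reactions[[i]]$stoich <- st
    }
  }
  expect_equal(maximize_biomass(scaled)$objective, base, tolerance = 1e-8)
})

test_that("both LP backends agree within opt_tol across knockouts", {
  mod <- build_polyamine_minimodel()
  cfg_s <- solver_config(backend = "simplex")
  cfg_p <- solver_config(backend = "pracma")
  for (disabled in list(character(0), "R_AMD1", "R_MAT", c("R_APRT", "R_PNP_ade"),
                        "R_ODC1", c("R_ARG1", "R_OAT"))) {
    gs <- maximize_biomass(mod, disabled, cfg_s)$objective
    gp <- maximize_biomass(mod, disabled, cfg_p)$objective
    expect_equal(gs, gp, tolerance = 1e-7, label = paste(disabled, collapse = "+"))
  }
})

test_that("objective noise below opt_tol is snapped to exactly zero", {
  mod <- toy_linear_model()
  sol <- maximize_biomass(mod, disabled_reactions = "R1")
  expect_identical(sol$objective, 0)
})

test_that("infeasible and invalid inputs are reported, not mis-solved", {
  mod <- toy_linear_model()
  expect_error(maximize_biomass(mod, disabled_reactions = "R_NOPE"), "not in model")
  # forced positive flux through a dead branch -> infeasible
  forced <- mod
  forced$reactions[[2]]$lower_bound <- 1   # R1 must run
  forced$reactions[[1]]$lower_bound <- 0   # but A cannot be imported
  forced$reactions[[1]]$upper_bound <- 0
  sol <- maximize_biomass(forced)
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$objective))
})
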
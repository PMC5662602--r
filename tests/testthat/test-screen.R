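# Essentiality screens: single, double, differential, threshold sweep.

test_that("single screen on the polyamine model finds the pathway essentials", {
  mod <- build_polyamine_minimodel()   # polyamines in biomass, PNP uncorrected
  scr <- single_deletion_screen(mod)
  expect_true(all(c("AMD1", "MTAP", "ODC1", "SRM") %in% scr$essential_genes))
  # the listed non-essentials really are non-essential
  expect_false(any(c("MAT1A", "MAT2A", "MAT2B", "APRT", "PNP", "ARG1", "OAT")
                   %in% scr$essential_genes))
  expect_gt(scr$growth_wildtype, scr$threshold)
  # every lethal knockout in the fixture collapses completely
  expect_true(all(scr$single_growth[scr$essential_genes] == 0))
  # invariant: essential set == strict-threshold classification of growths
  expect_identical(scr$essential_genes,
                   sort(names(scr$single_growth)[scr$single_growth < scr$threshold]))
})

test_that("double screen reproduces the synthetic-lethal pairs", {
  mod <- build_polyamine_minimodel()
  scr <- double_deletion_screen(mod)
  expect_true(all(c("MAT1A&MAT2A", "MAT1A&MAT2B", "APRT&PNP", "ARG1&OAT")
                  %in% scr$synthetic_lethal_pairs))
  # members of each pair are individually non-essential
  members <- unique(unlist(strsplit(scr$synthetic_lethal_pairs, "&")))
  expect_length(intersect(members, scr$essential_genes), 0)
  # pair growth symmetric in member order by construction of the key
  expect_identical(fbagea:::pair_key("MAT2A", "MAT1A"), "MAT1A&MAT2A")
  # consistency: pair growth never exceeds either single growth
  for (key in names(scr$pair_growth)) {
    pair <- strsplit(key, "&", fixed = TRUE)[[1]]
    expect_lte(scr$pair_growth[[key]],
               min(scr$single_growth[pair]) + 1e-9)
  }
})

test_that("after PNP correction APRT is essential and the pair disappears", {
  mod <- build_polyamine_minimodel()
  fixed <- correct_pnp_annotation(mod)
  scr <- double_deletion_screen(fixed)
  expect_true("APRT" %in% scr$essential_genes)
  expect_lte(scr$single_growth[["APRT"]], 1e-4)
  expect_false("APRT&PNP" %in% scr$synthetic_lethal_pairs)
  expect_false(any(grepl("APRT", names(scr$pair_growth))))  # essential -> excluded
  # the other Table rows are unchanged
  expect_true(all(c("AMD1", "MTAP", "ODC1", "SRM") %in% scr$essential_genes))
  expect_true(all(c("MAT1A&MAT2A", "MAT1A&MAT2B", "ARG1&OAT")
                  %in% scr$synthetic_lethal_pairs))
})

test_that("without polyamines in biomass no pathway gene is essential", {
  base <- build_polyamine_minimodel(include_polyamines_in_biomass = FALSE)
  scr <- single_deletion_screen(base)
  expect_length(scr$essential_genes, 0)
  expect_true(all(scr$single_growth == scr$growth_wildtype))
})

test_that("differential report isolates the polyamine-specific hits", {
  base <- double_deletion_screen(build_polyamine_minimodel(include_polyamines_in_biomass = FALSE))
  aug <- double_deletion_screen(build_polyamine_minimodel())
  diff <- differential_essentials(base, aug)
  listed <- c("AMD1", "MTAP", "ODC1", "SRM")
  expect_same_set(intersect(diff$essential_gained, listed), listed)
  expect_same_set(diff$pairs_gained,
                  c("APRT&PNP", "ARG1&OAT", "MAT1A&MAT2A", "MAT1A&MAT2B"))
  expect_length(diff$essential_lost, 0)
  # identical inputs give an empty report
  same <- differential_essentials(aug, aug)
  expect_length(same$essential_gained, 0)
  expect_length(same$pairs_gained, 0)
  # mismatched thresholds are a contract violation
  aug2 <- double_deletion_screen(build_polyamine_minimodel(), threshold = 1e-3)
  expect_error(differential_essentials(base, aug2), "threshold")
})

test_that("screen preconditions: non-growing model and unknown candidates error", {
  starved <- apply_medium(build_polyamine_minimodel(), setNames(numeric(0), character(0)))
  expect_error(single_deletion_screen(starved), "cannot grow")
  expect_error(double_deletion_screen(build_polyamine_minimodel(),
                                      candidates = c("MAT1A", "GHOST")),
               "unknown candidate")
})

test_that("ties at the threshold are non-essential (strict inequality)", {
  # toy model where knocking out g2 leaves growth exactly at the threshold:
  # two routes to biomass, the backup capped at exactly the threshold flux
  th <- 1e-4
  mod <- metabolic_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("EX_A", c(A = -1), lower_bound = -5, upper_bound = 1000,
               reversible = TRUE, is_exchange = TRUE),
      reaction("R_main", c(A = -1, B = 1), gpr = "g2"),
      reaction("R_backup", c(A = -1, B = 1), upper_bound = th, gpr = "g3"),
      reaction("R_BIO", c(B = -1), lower_bound = 0, upper_bound = 1000)
    ),
    genes = c("g2", "g3"), biomass_reaction_id = "R_BIO", medium = c(EX_A = 5)
  )
  scr <- single_deletion_screen(mod, threshold = th)
  expect_equal(scr$single_growth[["g2"]], th)
  expect_false("g2" %in% scr$essential_genes)   # growth == threshold: not below
})

test_that("genes absent from every GPR are recorded at wild-type growth", {
  mod <- build_polyamine_minimodel(corrected_pnp = TRUE)  # PNP gene now ruleless
  scr <- single_deletion_screen(mod)
  expect_equal(scr$single_growth[["PNP"]], scr$growth_wildtype)
  expect_false("PNP" %in% scr$essential_genes)
})

test_that("memoization by disabled-reaction set matches direct solving", {
  mod <- build_polyamine_minimodel()
  scr <- double_deletion_screen(mod)
  # spot-check pair growths against fresh unmemoized LP solves
  for (key in c("APRT&PNP", "MAT1A&MAT2B", "ARG1&OAT", "MAT2A&MAT2B")) {
    pair <- strsplit(key, "&", fixed = TRUE)[[1]]
    direct <- maximize_biomass(mod, reactions_disabled_by(mod, pair))$objective
    expect_equal(scr$pair_growth[[key]], direct, tolerance = 1e-9, label = key)
  }
})

test_that("threshold sweep reuses growths and is monotone in the threshold", {
  mod <- build_polyamine_minimodel()
  sweep <- threshold_sweep(mod, c(1e-6, 1e-4, 1e-2))
  # fixture growths are exactly 0 or ~wild-type: identical sets at all levels
  expect_identical(sweep[["1e-06"]], sweep[["1e-04"]])
  expect_identical(sweep[["1e-04"]], sweep[["0.01"]])
  # chain property on a graded ladder of thresholds
  grad <- threshold_sweep(mod, c(1e-8, 1e-4, 1, 5, 9.99))
  for (i in seq_len(length(grad) - 1)) {
    expect_true(all(grad[[i]] %in% grad[[i + 1]]))
  }
  # consistency with the plain single screen at the default threshold
  scr <- single_deletion_screen(mod)
  expect_identical(threshold_sweep(mod, 1e-4)[["1e-04"]], scr$essential_genes)
  expect_error(threshold_sweep(mod, c(1e-4, 11)), "exceeds wild-type")
})

test_that("screen TSV reports are deterministic and complete", {
  mod <- build_polyamine_minimodel()
  scr <- double_deletion_screen(mod)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_screen_tsv(scr, d1)
  write_screen_tsv(double_deletion_screen(mod), d2)
  expect_identical(readLines(file.path(d1, "genes.tsv")),
                   readLines(file.path(d2, "genes.tsv")))
  expect_identical(readLines(file.path(d1, "pairs.tsv")),
                   readLines(file.path(d2, "pairs.tsv")))
  genes <- read.delim(file.path(d1, "genes.tsv"))
  expect_identical(nrow(genes), length(mod$genes))
})
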
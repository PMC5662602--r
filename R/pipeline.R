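# End-to-end pipeline: load -> medium -> curation edits -> screen -> reports.
#
# run_pipeline() is the engine behind the `gea` command-line script
# (inst/scripts/gea.R) and is equally usable from R. Reports are written
# deterministically: lexicographic row order, 12-significant-digit floats,
# so two runs with the same configuration produce byte-identical files.

#' Pipeline configuration
#'
#' Exactly one model source must be given: a model JSON `model_path` or the
#' built-in `fixture` name (`"polyamine"`, optionally screened in its
#' PNP-corrected or polyamine-free variants via the flags below).
#'
#' @param model_path path to a model JSON file, or `NULL`.
#' @param fixture built-in fixture name (`"polyamine"`), or `NULL`.
#' @param biomass optional biomass augmentation: `"+polyamines"` (adds the
#'   default polyamine demands via [polyamine_biomass_spec()]), a named
#'   numeric vector, or a path to a JSON file of metabolite -> coefficient.
#' @param threshold lethality threshold, gDW/h.
#' @param mode `"single"`, `"double"` or `"differential"` (differential runs
#'   the screen with and without the biomass augmentation and reports the
#'   difference; requires `biomass`).
#' @param correct_pnp apply [correct_pnp_annotation()] before screening?
#' @param xdh apply [add_xdh_branch()]?
#' @param config a [solver_config].
#' @param out_dir output directory for reports (`NULL` = no files written).
#' @param seed integer recorded in the summary (used by `gea simulate`).
#' @return list of class `run_config`.
#' @export
run_config <- function(model_path = NULL, fixture = NULL, biomass = NULL,
                       threshold = 1e-4, mode = c("single", "double", "differential"),
                       correct_pnp = FALSE, xdh = FALSE,
                       config = solver_config(), out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(model_path) == is.null(fixture)) {
    stop("exactly one model source (model_path or fixture) must be given", call. = FALSE)
  }
  stopifnot(threshold > 0)
  structure(list(model_path = model_path, fixture = fixture, biomass = biomass,
                 threshold = threshold, mode = mode, correct_pnp = correct_pnp,
                 xdh = xdh, config = config, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

resolve_biomass_spec <- function(biomass, model) {
  if (is.null(biomass)) return(NULL)
  if (is.character(biomass) && length(biomass) == 1) {
    if (identical(biomass, "+polyamines")) return(polyamine_biomass_spec())
    raw <- jsonlite::fromJSON(biomass, simplifyVector = FALSE)
    return(biomass_spec(setNames(vapply(raw, as.numeric, numeric(1)), names(raw))))
  }
  biomass_spec(biomass)
}

load_pipeline_model <- function(cfg) {
  if (!is.null(cfg$model_path)) return(read_model(cfg$model_path))
  switch(cfg$fixture,
         polyamine = build_polyamine_minimodel(include_polyamines_in_biomass = FALSE),
         stop("unknown fixture: ", cfg$fixture, call. = FALSE))
}

#' Run the gene-essentiality pipeline
#'
#' Stages: model load, medium application, curation edits, screen(s), report
#' writing. Progress and per-stage wall-clock go to stderr; data go to files
#' only. The summary JSON mirrors the screen result with floats at 12
#' significant digits and sorted keys, so identical configurations give
#' byte-identical summaries.
#'
#' @param cfg a [run_config].
#' @return invisibly, a list with the screen(s), the differential report (if
#'   any) and the paths written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[gea] stage %-12s %.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  model <- stage("load", load_pipeline_model(cfg))
  model <- stage("medium", apply_medium(model, model$medium))
  base_model <- model
  spec <- resolve_biomass_spec(cfg$biomass, model)
  if (!is.null(spec)) model <- stage("biomass", augment_biomass(model, spec))
  if (cfg$correct_pnp) model <- stage("pnp-correct", correct_pnp_annotation(model))
  if (cfg$xdh) model <- stage("xdh", add_xdh_branch(model, enabled = TRUE))
  message(sprintf("[gea] model %s: %d metabolites, %d reactions, %d genes (checksum %s)",
                  model$id, length(model$metabolites), length(model$reactions),
                  length(model$genes), model_checksum(model)))
  message(sprintf("[gea] threshold %g gDW/h, backend %s", cfg$threshold,
                  cfg$config$backend))

  differential <- NULL
  if (cfg$mode == "differential") {
    if (is.null(spec)) stop("differential mode requires a biomass spec", call. = FALSE)
    base_for_diff <- base_model
    if (cfg$correct_pnp) base_for_diff <- correct_pnp_annotation(base_for_diff)
    if (cfg$xdh) base_for_diff <- add_xdh_branch(base_for_diff, enabled = TRUE)
    scr_base <- stage("screen-base",
                      double_deletion_screen(base_for_diff, cfg$threshold, cfg$config))
    screen <- stage("screen-augmented",
                    double_deletion_screen(model, cfg$threshold, cfg$config))
    differential <- differential_essentials(scr_base, screen)
  } else if (cfg$mode == "double") {
    screen <- stage("screen", double_deletion_screen(model, cfg$threshold, cfg$config))
  } else {
    screen <- stage("screen", single_deletion_screen(model, cfg$threshold, cfg$config))
  }

  written <- character(0)
  if (!is.null(cfg$out_dir)) {
    written <- stage("report", {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      files <- write_screen_tsv(screen, cfg$out_dir)
      sj <- file.path(cfg$out_dir, "summary.json")
      writeLines(screen_summary_json(screen, differential, cfg), sj)
      c(files, sj)
    })
  }
  invisible(list(screen = screen, differential = differential, files = written))
}

model_checksum <- function(model) {
  txt <- model_to_json(model)
  # small deterministic content hash (djb2); avoids a digest dependency
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

num12 <- function(x) as.numeric(sprintf("%.12g", x))

screen_summary_json <- function(screen, differential, cfg) {
  s <- summary(screen)
  out <- list(
    threshold = num12(screen$threshold),
    growth_wildtype = num12(screen$growth_wildtype),
    essential_genes = as.list(screen$essential_genes),
    synthetic_lethal_pairs = as.list(screen$synthetic_lethal_pairs),
    single_growth = as.list(setNames(num12(s$genes$growth), s$genes$gene)),
    pair_growth = as.list(setNames(num12(screen$pair_growth), names(screen$pair_growth))),
    backend = cfg$config$backend,
    seed = cfg$seed
  )
  if (!is.null(differential)) {
    out$differential <- list(
      essential_gained = as.list(differential$essential_gained),
      essential_lost = as.list(differential$essential_lost),
      pairs_gained = as.list(differential$pairs_gained),
      pairs_lost = as.list(differential$pairs_lost)
    )
  }
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE))
}
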
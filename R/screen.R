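# Gene essentiality analysis.
#
# For a gene g, the reactions N(g) whose GPR turns FALSE when g is deleted are
# clamped to zero flux and the growth LP is re-solved. If the optimal biomass
# flux falls (strictly) below the lethality threshold — default 1e-4 gDW/h,
# the minimum biomass production regarded as compatible with proliferation —
# the gene is essential. Synthetic lethal pairs are pairs of individually
# non-essential genes whose joint deletion is lethal. Growth values are
# memoized by the disabled-*reaction* set, so gene knockouts that collapse to
# the same reaction knockout are solved once.

new_growth_memo <- function() new.env(parent = emptyenv())

memo_growth <- function(memo, model, disabled, config) {
  key <- paste0("k:", paste(sort(disabled), collapse = "\r"))
  hit <- get0(key, envir = memo, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  sol <- maximize_biomass(model, disabled_reactions = disabled, config = config)
  growth <- if (identical(sol$status, "optimal")) sol$objective else 0
  assign(key, growth, envir = memo)
  growth
}

pair_key <- function(a, b) {
  p <- sort(c(a, b))
  paste(p[1], p[2], sep = "&")
}

new_gea_screen <- function(threshold, growth_wildtype, single_growth,
                           essential_genes, pair_growth = setNames(numeric(0), character(0)),
                           synthetic_lethal_pairs = character(0), config, memo = NULL) {
  structure(list(
    threshold = threshold,
    growth_wildtype = growth_wildtype,
    single_growth = single_growth[order(names(single_growth))],
    essential_genes = sort(essential_genes),
    pair_growth = pair_growth[order(names(pair_growth))],
    synthetic_lethal_pairs = sort(synthetic_lethal_pairs),
    config = config,
    memo = memo
  ), class = "gea_screen")
}

#' Single gene deletion screen
#'
#' Deletes each gene in turn, disables the reactions its loss inactivates and
#' re-maximizes biomass. Genes whose deletion disables no reaction (absent
#' from every GPR, or always rescued by isozymes) are recorded at wild-type
#' growth without an LP solve. Essentiality uses the strict rule
#' `growth < threshold`; a knockout growing at exactly the threshold is
#' non-essential.
#'
#' @param model a [metabolic_model]; its wild-type growth must reach the
#'   threshold, otherwise the screen is meaningless and an error is raised.
#' @param threshold lethality threshold in gDW/h (default `1e-4`).
#' @param config a [solver_config].
#' @return an object of class `gea_screen`; see [summary.gea_screen()].
#' @examples
#' mod <- build_polyamine_minimodel()
#' scr <- single_deletion_screen(mod)
#' scr$essential_genes
#' @export
single_deletion_screen <- function(model, threshold = 1e-4, config = solver_config()) {
  stopifnot(inherits(model, "metabolic_model"), threshold > 0)
  memo <- new_growth_memo()
  wt <- memo_growth(memo, model, character(0), config)
  if (wt < threshold) {
    stop(sprintf("wild-type growth (%.3g) is below the threshold (%.3g): model cannot grow",
                 wt, threshold), call. = FALSE)
  }
  genes <- sort(model$genes)
  growth <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    disabled <- reactions_disabled_by(model, g)
    growth[g] <- if (length(disabled) == 0) wt else memo_growth(memo, model, disabled, config)
  }
  essential <- names(growth)[growth < threshold]
  new_gea_screen(threshold, wt, growth, essential, config = config, memo = memo)
}

#' Double gene deletion (synthetic lethality) screen
#'
#' Runs the single-deletion screen (or reuses one), then evaluates every
#' unordered pair of non-essential candidate genes. A pair is synthetic
#' lethal iff its joint growth is strictly below the threshold. Growth values
#' are memoized by disabled-reaction set: a pair whose joint knockout disables
#' exactly the union of the two single knockouts reuses any growth already
#' computed for that exact reaction set.
#'
#' @param model a [metabolic_model].
#' @param threshold lethality threshold in gDW/h.
#' @param config a [solver_config].
#' @param candidates optional character vector restricting the pairs screened;
#'   defaults to all non-essential genes appearing in at least one GPR.
#' @param single an optional `gea_screen` from [single_deletion_screen()] on
#'   the same model/threshold/config, to avoid recomputation.
#' @return a `gea_screen` with `pair_growth` and `synthetic_lethal_pairs`
#'   filled; pair names are `"A&B"` with members sorted.
#' @examples
#' mod <- build_polyamine_minimodel()
#' scr <- double_deletion_screen(mod)
#' scr$synthetic_lethal_pairs
#' @export
double_deletion_screen <- function(model, threshold = 1e-4, config = solver_config(),
                                   candidates = NULL, single = NULL) {
  if (is.null(single)) {
    single <- single_deletion_screen(model, threshold, config)
  } else {
    stopifnot(inherits(single, "gea_screen"), identical(single$threshold, threshold))
  }
  memo <- single$memo %||% new_growth_memo()
  if (!is.null(candidates)) {
    unknown <- setdiff(candidates, model$genes)
    if (length(unknown) > 0) {
      stop("unknown candidate gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  } else {
    in_gpr <- unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr))))
    candidates <- sort(in_gpr)
  }
  candidates <- sort(setdiff(candidates, single$essential_genes))
  n <- length(candidates)
  pair_growth <- numeric(0)
  sl <- character(0)
  if (n >= 2) {
    keys <- character(n * (n - 1) / 2)
    vals <- numeric(length(keys))
    k <- 0L
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        a <- candidates[i]; b <- candidates[j]
        disabled <- reactions_disabled_by(model, c(a, b))
        g <- memo_growth(memo, model, disabled, config)
        k <- k + 1L
        keys[k] <- pair_key(a, b)
        vals[k] <- g
      }
    }
    pair_growth <- setNames(vals, keys)
    sl <- keys[vals < threshold]
  }
  new_gea_screen(threshold, single$growth_wildtype, single$single_growth,
                 single$essential_genes, pair_growth, sl, config, memo)
}

#' @export
print.gea_screen <- function(x, ...) {
  cat("<gea_screen>  threshold: ", format(x$threshold),
      " gDW/h   wild-type growth: ", format(x$growth_wildtype), "\n", sep = "")
  cat("  genes screened: ", length(x$single_growth),
      "   essential: ", length(x$essential_genes), "\n", sep = "")
  if (length(x$essential_genes) > 0) {
    cat("  essential genes: ", paste(x$essential_genes, collapse = ", "), "\n", sep = "")
  }
  if (length(x$pair_growth) > 0) {
    cat("  pairs screened: ", length(x$pair_growth),
        "   synthetic lethal: ", length(x$synthetic_lethal_pairs), "\n", sep = "")
    if (length(x$synthetic_lethal_pairs) > 0) {
      cat("  synthetic lethal pairs: ",
          paste(x$synthetic_lethal_pairs, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Summarize a gene essentiality screen
#'
#' @param object a `gea_screen`.
#' @param ... unused.
#' @return a list with data frames `genes` (gene, growth, essential) and
#'   `pairs` (gene_a, gene_b, growth, synthetic_lethal), both in deterministic
#'   lexicographic order.
#' @export
summary.gea_screen <- function(object, ...) {
  genes <- data.frame(
    gene = names(object$single_growth),
    growth = unname(object$single_growth),
    essential = names(object$single_growth) %in% object$essential_genes,
    stringsAsFactors = FALSE
  )
  pairs <- if (length(object$pair_growth) > 0) {
    sp <- strsplit(names(object$pair_growth), "&", fixed = TRUE)
    data.frame(
      gene_a = vapply(sp, `[[`, character(1), 1),
      gene_b = vapply(sp, `[[`, character(1), 2),
      growth = unname(object$pair_growth),
      synthetic_lethal = names(object$pair_growth) %in% object$synthetic_lethal_pairs,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(gene_a = character(0), gene_b = character(0), growth = numeric(0),
               synthetic_lethal = logical(0), stringsAsFactors = FALSE)
  }
  out <- list(threshold = object$threshold, growth_wildtype = object$growth_wildtype,
              genes = genes, pairs = pairs)
  class(out) <- "summary.gea_screen"
  out
}

#' @export
print.summary.gea_screen <- function(x, ...) {
  cat("Gene essentiality screen (threshold ", format(x$threshold), " gDW/h, wild-type ",
      format(x$growth_wildtype), " gDW/h)\n\n", sep = "")
  print(x$genes, row.names = FALSE)
  if (nrow(x$pairs) > 0) {
    cat("\nPairs:\n")
    print(x$pairs[x$pairs$synthetic_lethal, , drop = FALSE], row.names = FALSE)
  }
  invisible(x)
}

#' Differential essentiality between two screens
#'
#' Compares screens of the same gene universe at the same threshold — e.g. the
#' original biomass versus the polyamine-augmented biomass — and reports the
#' hits specific to the augmented variant (augmented minus base).
#'
#' @param base,augmented `gea_screen` objects over identical gene sets and
#'   thresholds.
#' @return list of class `gea_differential`: `essential_gained`,
#'   `essential_lost`, `pairs_gained`, `pairs_lost`.
#' @export
differential_essentials <- function(base, augmented) {
  stopifnot(inherits(base, "gea_screen"), inherits(augmented, "gea_screen"))
  if (!identical(base$threshold, augmented$threshold)) {
    stop("screens use different thresholds; differential report undefined", call. = FALSE)
  }
  if (!identical(names(base$single_growth), names(augmented$single_growth))) {
    stop("screens cover different gene universes", call. = FALSE)
  }
  structure(list(
    essential_gained = sort(setdiff(augmented$essential_genes, base$essential_genes)),
    essential_lost = sort(setdiff(base$essential_genes, augmented$essential_genes)),
    pairs_gained = sort(setdiff(augmented$synthetic_lethal_pairs,
                                base$synthetic_lethal_pairs)),
    pairs_lost = sort(setdiff(base$synthetic_lethal_pairs,
                              augmented$synthetic_lethal_pairs))
  ), class = "gea_differential")
}

#' @export
print.gea_differential <- function(x, ...) {
  cat("<gea_differential>\n")
  cat("  essential gained: ", paste(x$essential_gained, collapse = ", "), "\n", sep = "")
  cat("  essential lost:   ", paste(x$essential_lost, collapse = ", "), "\n", sep = "")
  cat("  pairs gained:     ", paste(x$pairs_gained, collapse = ", "), "\n", sep = "")
  cat("  pairs lost:       ", paste(x$pairs_lost, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Threshold sensitivity sweep
#'
#' Reuses the per-gene knockout growth values of one single-deletion screen
#' (one LP per gene in total) and reclassifies at each threshold. Because the
#' growth values are fixed, the essential sets form a chain: a larger
#' threshold can only add genes.
#'
#' @param model a [metabolic_model].
#' @param thresholds positive thresholds, each at most the wild-type growth.
#' @param config a [solver_config].
#' @param single optional precomputed `gea_screen`.
#' @return named list: threshold (as given) -> character vector of essential
#'   genes.
#' @export
threshold_sweep <- function(model, thresholds, config = solver_config(), single = NULL) {
  stopifnot(all(thresholds > 0))
  if (is.null(single)) {
    single <- single_deletion_screen(model, threshold = min(thresholds), config = config)
  }
  if (any(thresholds > single$growth_wildtype)) {
    stop("threshold exceeds wild-type growth; every gene would be called essential",
         call. = FALSE)
  }
  out <- lapply(thresholds, function(th) {
    sort(names(single$single_growth)[single$single_growth < th])
  })
  names(out) <- as.character(thresholds)
  out
}

#' Write screen reports as TSV
#'
#' Writes `genes.tsv` (gene, growth, essential) and, when pairs were screened,
#' `pairs.tsv` (gene_a, gene_b, growth, synthetic_lethal), tab-separated with
#' one header row, growth with 12 significant digits, rows in lexicographic
#' order — two identical screens produce byte-identical files.
#'
#' @param screen a `gea_screen`.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_screen_tsv <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(screen)
  files <- file.path(dir, "genes.tsv")
  writeLines(c("gene\tgrowth\tessential",
               sprintf("%s\t%.12g\t%s", s$genes$gene, s$genes$growth,
                       tolower(s$genes$essential))), files[1])
  if (nrow(s$pairs) > 0) {
    f2 <- file.path(dir, "pairs.tsv")
    writeLines(c("gene_a\tgene_b\tgrowth\tsynthetic_lethal",
                 sprintf("%s\t%s\t%.12g\t%s", s$pairs$gene_a, s$pairs$gene_b,
                         s$pairs$growth, tolower(s$pairs$synthetic_lethal))), f2)
    files <- c(files, f2)
  }
  invisible(files)
}
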
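# Gene-protein-reaction (GPR) boolean rules.
#
# A GPR rule states which gene combinations keep a reaction available:
# AND joins subunits of one complex, OR joins isozymes. The AST is a nested
# list: list(type = "empty") | list(type = "gene", gene = id) |
# list(type = "and"/"or", children = list(...)). The grammar has no NOT --
# deleting genes can only remove capability -- and NOT is rejected at parse
# time, which is what makes GPR evaluation monotone in the deleted set.

GPR_EMPTY <- list(type = "empty")

gpr_leaf <- function(gene) list(type = "gene", gene = gene)

gpr_node <- function(op, children) {
  # flatten nested same-op nodes so the AST (and its serialization) is canonical
  flat <- list()
  for (ch in children) {
    if (identical(ch$type, op)) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  if (length(flat) == 1) return(flat[[1]])
  list(type = op, children = flat)
}

gpr_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      tokens[[length(tokens) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n), regexpr("^[A-Za-z0-9_.:-]+", substr(text, i, n)))
    if (length(m) == 0) {
      stop(sprintf("GPR parse error at position %d: unexpected character '%s'", i, ch),
           call. = FALSE)
    }
    word <- m[[1]]
    low <- tolower(word)
    type <- if (low %in% c("and", "or")) low else if (low == "not") "not" else "gene"
    if (type == "not") {
      stop(sprintf("GPR parse error at position %d: NOT is not part of the rule grammar", i),
           call. = FALSE)
    }
    tokens[[length(tokens) + 1L]] <- list(type = type, value = word, pos = i)
    i <- i + nchar(word)
  }
  tokens
}

#' Parse a GPR rule string
#'
#' Grammar: gene identifiers, parentheses and the connectives `and` / `or`
#' (case-insensitive), with `or` binding loosest. The empty string yields the
#' EMPTY rule, meaning the reaction needs no gene product (spontaneous or
#' unannotated) and is never disabled by deletions.
#'
#' @param rule_text rule string, e.g. `"MAT1A or (MAT2A and MAT2B)"`.
#' @param known_genes optional character vector; when supplied, every leaf must
#'   be a member, otherwise a validation error lists the offenders.
#' @return a GPR AST (nested list) of class `gpr_rule`.
#' @examples
#' r <- parse_gpr("MAT1A or (MAT2A and MAT2B)")
#' gpr_to_string(r)
#' evaluate_gpr(r, deleted = c("MAT1A", "MAT2A"))
#' @export
parse_gpr <- function(rule_text, known_genes = NULL) {
  if (is.null(rule_text) || !nzchar(trimws(rule_text))) {
    return(structure(GPR_EMPTY, class = "gpr_rule"))
  }
  tokens <- gpr_tokenize(rule_text)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  fail <- function(tok, what) {
    at <- if (is.null(tok)) nchar(rule_text) + 1L else tok$pos
    stop(sprintf("GPR parse error at position %d: %s", at, what), call. = FALSE)
  }

  parse_or <- function() {
    node <- parse_and()
    children <- list(node)
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      children[[length(children) + 1L]] <- parse_and()
    }
    gpr_node("or", children)
  }
  parse_and <- function() {
    node <- parse_atom()
    children <- list(node)
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      children[[length(children) + 1L]] <- parse_atom()
    }
    gpr_node("and", children)
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "unexpected end of rule")
    if (tok$type == "(") {
      open <- advance()
      node <- parse_or()
      close <- peek()
      if (is.null(close) || close$type != ")") {
        fail(open, "unbalanced parenthesis (no matching ')')")
      }
      advance()
      return(node)
    }
    if (tok$type == "gene") {
      advance()
      return(gpr_leaf(tok$value))
    }
    fail(tok, sprintf("unexpected token '%s'", if (!is.null(tok$value)) tok$value else tok$type))
  }

  ast <- parse_or()
  if (!is.null(peek())) {
    tok <- peek()
    fail(tok, sprintf("unexpected trailing token '%s'",
                      if (!is.null(tok$value)) tok$value else tok$type))
  }
  if (!is.null(known_genes)) {
    unknown <- setdiff(gpr_genes(ast), known_genes)
    if (length(unknown) > 0) {
      stop("GPR references genes absent from the model gene set: ",
           paste(sort(unknown), collapse = ", "), call. = FALSE)
    }
  }
  structure(ast, class = "gpr_rule")
}

#' Canonical string form of a GPR rule
#'
#' Round-trips through [parse_gpr()]: `parse_gpr(gpr_to_string(r))` reproduces
#' the AST. `or` is rendered at top precedence, `and` children that are `or`
#' nodes are parenthesized.
#'
#' @param rule a GPR AST.
#' @return a string; `""` for the EMPTY rule.
#' @export
gpr_to_string <- function(rule) {
  switch(rule$type,
    empty = "",
    gene = rule$gene,
    or = paste(vapply(rule$children, gpr_to_string, character(1)), collapse = " or "),
    and = paste(vapply(rule$children, function(ch) {
      s <- gpr_to_string(ch)
      if (identical(ch$type, "or")) paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    stop("invalid GPR node type: ", rule$type)
  )
}

#' @export
print.gpr_rule <- function(x, ...) {
  s <- gpr_to_string(x)
  cat("<GPR> ", if (nzchar(s)) s else "(no gene association)", "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR rule
#' @param rule a GPR AST.
#' @return character vector of distinct gene ids (empty for EMPTY).
#' @export
gpr_genes <- function(rule) {
  switch(rule$type,
    empty = character(0),
    gene = rule$gene,
    unique(unlist(lapply(rule$children, gpr_genes)))
  )
}

#' Evaluate a GPR rule under a set of deleted genes
#'
#' A leaf is TRUE iff its gene is not deleted; AND/OR have standard boolean
#' semantics; the EMPTY rule is always TRUE.
#'
#' @param rule a GPR AST.
#' @param deleted character vector of deleted gene ids.
#' @return logical scalar: is the reaction still available?
#' @export
evaluate_gpr <- function(rule, deleted = character(0)) {
  switch(rule$type,
    empty = TRUE,
    gene = !(rule$gene %in% deleted),
    and = all(vapply(rule$children, evaluate_gpr, logical(1), deleted = deleted)),
    or = any(vapply(rule$children, evaluate_gpr, logical(1), deleted = deleted)),
    stop("invalid GPR node type: ", rule$type)
  )
}

#' Reactions disabled by a gene deletion
#'
#' The set N(g) of the essentiality algorithm: reactions whose GPR evaluates
#' FALSE once the given genes are removed. Reactions with no gene association
#' are never disabled.
#'
#' @param model a [metabolic_model].
#' @param deleted character vector of gene ids, each present in `model$genes`.
#' @return character vector of reaction ids (possibly empty), in model order.
#' @export
reactions_disabled_by <- function(model, deleted) {
  stopifnot(inherits(model, "metabolic_model"))
  deleted <- unique(as.character(deleted))
  unknown <- setdiff(deleted, model$genes)
  if (length(unknown) > 0) {
    stop("unknown gene id(s): ", paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  ids <- character(0)
  for (rxn in model$reactions) {
    if (!evaluate_gpr(rxn$gpr, deleted)) ids <- c(ids, rxn$id)
  }
  ids
}
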
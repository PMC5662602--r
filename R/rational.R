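# Exact rational stoichiometric coefficients.
#
# Coefficients live in the model as integer numerator/denominator pairs and are
# converted to doubles only when the LP matrix is built, so serialization
# round-trips bit-exactly (including 1/3 and friends) and sign tests never see
# float noise.

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

rat_simplify <- function(num, den) {
  stopifnot(all(den != 0))
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- mapply(rat_gcd, num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

# Parse one coefficient given as a number or a string: "3", "-2", "1/3",
# "-0.25". Decimal strings expand exactly (0.01 -> 1/100); plain numerics are
# routed through their shortest decimal representation, so typical model
# coefficients stay exact.
rat_parse1 <- function(x) {
  if (is.numeric(x)) {
    if (x == round(x) && abs(x) < 2^53) return(c(x, 1))
    x <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  x <- trimws(as.character(x))
  if (grepl("^[+-]?[0-9]+$", x)) {
    return(c(as.numeric(x), 1))
  }
  if (grepl("^[+-]?[0-9]+/[0-9]+$", x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    r <- rat_simplify(as.numeric(parts[1]), as.numeric(parts[2]))
    return(c(r$num, r$den))
  }
  if (grepl("^[+-]?[0-9]*\\.[0-9]+$", x)) {
    frac <- sub("^[+-]?[0-9]*\\.", "", x)
    den <- 10^nchar(frac)
    num <- as.numeric(sub("\\.", "", x))
    r <- rat_simplify(num, den)
    return(c(r$num, r$den))
  }
  stop("cannot parse stoichiometric coefficient: ", deparse(x), call. = FALSE)
}

#' Build an exact-rational coefficient vector
#'
#' @param x numeric or character vector; strings may be integers, decimals or
#'   `"p/q"` fractions.
#' @return list with integer-valued `num` and `den` vectors.
#' @keywords internal
as_rational <- function(x) {
  if (length(x) == 0) return(list(num = numeric(0), den = numeric(0)))
  m <- vapply(x, rat_parse1, numeric(2))
  r <- rat_simplify(m[1, ], m[2, ])
  list(num = unname(r$num), den = unname(r$den))
}

rat_values <- function(stoich) {
  setNames(stoich$num / stoich$den, stoich$met)
}

# Serialize one coefficient for JSON: bare number when integral, "p/q" string
# otherwise.
rat_serialize <- function(num, den) {
  if (den == 1) num else paste0(num, "/", den)
}
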
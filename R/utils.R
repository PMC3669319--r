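#' @importFrom rlang %||% abort warn
#' @importFrom dplyr mutate filter select arrange bind_rows left_join group_by
#'   summarise ungroup across all_of row_number rename n
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2 imap pmap keep
NULL

# Parse a chemical formula string ("C6H12O6") into a named count vector.
# Returns NULL for NA/empty input.
parse_formula <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(x)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x)[[1]]
  parts <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x))[[1]]
  if (sum(nchar(parts)) != nchar(x)) {
    abort(sprintf("cannot parse chemical formula '%s'", x))
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  counts <- tapply(ct, el, sum)
  stats::setNames(as.numeric(counts), names(counts))
}

# Parse a reaction equation like "1 Glu + 2 ATP -> 1.5 Succ + W".
# Either side may be empty ("ATP ->" is a sink). Returns a named numeric
# vector of signed stoichiometric coefficients (substrates negative).
parse_equation <- function(eq) {
  if (is.na(eq) || !nzchar(trimws(eq))) abort("empty reaction equation")
  eq <- gsub("→|<->|<=>|=>", "->", eq)
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2 || !grepl("->", eq, fixed = TRUE)) {
    abort(sprintf("equation '%s' must contain exactly one '->'", eq))
  }
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) abort(sprintf("malformed term in equation '%s'", eq))
      bits <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(bits) == 1) {
        coef <- 1; id <- bits
      } else if (length(bits) == 2) {
        coef <- suppressWarnings(as.numeric(bits[1]))
        if (is.na(coef)) abort(sprintf("bad coefficient in term '%s'", tm))
        id <- bits[2]
      } else {
        abort(sprintf("malformed term '%s' in equation", tm))
      }
      prev <- if (id %in% names(out)) out[[id]] else 0
      out[id] <- prev + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  coefs <- lhs
  for (id in names(rhs)) coefs[id] <- (if (id %in% names(coefs)) coefs[id] else 0) + rhs[id]
  coefs <- coefs[coefs != 0]
  if (length(coefs) == 0) abort(sprintf("equation '%s' has no net stoichiometry", eq))
  coefs
}

# Render a signed stoichiometry vector back into an equation string.
format_equation <- function(coefs) {
  fmt <- function(v, ids) {
    if (length(ids) == 0) return("")
    paste(ifelse(v == 1, ids, paste(format(v, trim = TRUE), ids)), collapse = " + ")
  }
  neg <- coefs < 0
  paste(fmt(abs(coefs[neg]), names(coefs)[neg]), "->", fmt(coefs[!neg], names(coefs)[!neg]))
}

stop_if_duplicated <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated %s id(s): %s", what, paste(dup, collapse = ", ")))
  }
}
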
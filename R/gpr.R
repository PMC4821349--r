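#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers that states which
#' gene products make a reaction available: "and" joins members of a complex,
#' "or" joins isoenzymes. Rules are stored as recursive trees: a leaf is a
#' single gene id (character scalar), an internal node is
#' `list(op = "and"|"or", args = list(...))`, and `NULL` means the reaction
#' has no gene association.
#'
#' @param text a rule string, e.g. `"(g1 and (g2 or g3))"`. Accepts
#'   `and`/`or` case-insensitively as well as `&`/`|`.
#' @return `parse_gpr`: a GPR tree (or NULL for empty/whitespace input).
#' @examples
#' tree <- parse_gpr("(g1 and (g2 or g3))")
#' gpr_genes(tree)
#' gpr_eval(tree, c(g1 = TRUE, g2 = FALSE, g3 = TRUE))
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error near token '", st$toks[st$pos], "' in rule: ", text)
  }
  tree
}

gpr_tokenize <- function(text) {
  text <- gsub("&&", " and ", gsub("\\|\\|", " or ", text))
  text <- gsub("&", " and ", gsub("\\|", " or ", text, fixed = TRUE), fixed = TRUE)
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
gpr_take <- function(st) { t <- gpr_peek(st); st$pos <- st$pos + 1L; t }

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    gpr_take(st)
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    gpr_take(st)
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  t <- gpr_take(st)
  if (is.na(t)) stop("GPR parse error: unexpected end of rule")
  if (t == "(") {
    e <- gpr_parse_or(st)
    if (!identical(gpr_take(st), ")")) stop("GPR parse error: unbalanced parentheses")
    return(e)
  }
  if (t == ")" || tolower(t) %in% c("and", "or")) {
    stop("GPR parse error: unexpected token '", t, "'")
  }
  t
}

#' @rdname parse_gpr
#' @param tree a GPR tree.
#' @return `gpr_to_string`: the rule rendered with `and`/`or` and parentheses
#'   around compound sub-expressions; empty string for NULL.
#' @export
gpr_to_string <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- gpr_to_string(a)
    if (is.character(a)) s else paste0("(", s, ")")
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' @rdname parse_gpr
#' @return `gpr_genes`: character vector of distinct gene ids in the tree.
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' @rdname parse_gpr
#' @param state named logical vector; genes absent from it are taken as TRUE
#'   (present/functional).
#' @return `gpr_eval`: logical scalar, the truth value of the rule. An empty
#'   (NULL) rule evaluates TRUE: reactions without gene association are never
#'   silenced by deletions.
#' @export
gpr_eval <- function(tree, state) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) {
    v <- state[tree]
    return(if (is.na(v)) TRUE else unname(v))
  }
  vals <- vapply(tree$args, gpr_eval, logical(1), state = state)
  if (tree$op == "and") all(vals) else any(vals)
}

#' @rdname parse_gpr
#' @param values named numeric vector of per-gene scores (e.g. expression).
#'   Genes missing from `values` count as unevidenced and score `Inf`.
#' @return `gpr_value`: numeric score of the rule — min over "and" children,
#'   max over "or" children; `Inf` for an empty rule.
#' @export
gpr_value <- function(tree, values) {
  if (is.null(tree)) return(Inf)
  if (is.character(tree)) {
    v <- values[tree]
    return(if (is.na(v)) Inf else unname(v))
  }
  vals <- vapply(tree$args, gpr_value, numeric(1), values = values)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Compare two GPR rules as boolean functions
#'
#' Exhaustive truth-table comparison over the union of the two gene sets
#' (up to 16 genes; larger rules fall back to comparison of normalized rule
#' strings, which is sufficient for curated models where equivalent rules are
#' written identically).
#'
#' @param a,b GPR trees.
#' @return TRUE if the rules define the same boolean function.
#' @export
gpr_equivalent <- function(a, b) {
  ga <- gpr_genes(a); gb <- gpr_genes(b)
  genes <- union(ga, gb)
  k <- length(genes)
  if (k == 0) return(is.null(a) == is.null(b))
  if (k > 16L) return(identical(gpr_to_string(a), gpr_to_string(b)))
  for (mask in 0:(2^k - 1)) {
    st <- as.logical(bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L))
    names(st) <- genes
    if (gpr_eval(a, st) != gpr_eval(b, st)) return(FALSE)
  }
  TRUE
}
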
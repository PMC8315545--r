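## Gene-protein-reaction (GPR) rules.
##
## Grammar: identifiers (alphanumeric plus . _ -), operators AND / OR
## (case-insensitive), parentheses; AND binds tighter than OR. Evaluation
## follows the usual capacity semantics: an enzyme complex (AND) is limited
## by its scarcest subunit, min; isoenzymes (OR) add capacity, sum.

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean GPR string such as `"(P1 AND P2) OR P3"` into an
#' expression tree. `AND` binds tighter than `OR`; both operators are
#' case-insensitive and n-ary (chains are flattened).
#'
#' @param text A single GPR rule string.
#' @return An object of class `gpr_expression`: either a leaf
#'   (`list(op = "id", id = <protein>)`) or a node
#'   (`list(op = "and"|"or", args = <list of subtrees>)`).
#' @examples
#' parse_gpr("(P1 AND P2) OR P3")
#' @export
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    stop("GPR rule must be a single character string")
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$type))
    stop(sprintf("GPR parse error: unexpected '%s' at position %d",
                 st$toks$text[st$pos], st$toks$at[st$pos]))
  expr
}

gpr_tokenize <- function(text) {
  type <- character(0); txt <- character(0); at <- integer(0)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      type <- c(type, ch); txt <- c(txt, ch); at <- c(at, i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z0-9._-]+", substr(text, i, n)))
    if (length(m) == 0)
      stop(sprintf("GPR parse error: illegal character '%s' at position %d",
                   ch, i))
    word <- m[[1]]
    up <- toupper(word)
    type <- c(type, if (up %in% c("AND", "OR")) up else "id")
    txt <- c(txt, word); at <- c(at, i)
    i <- i + nchar(word)
  }
  list(type = type, text = txt, at = at)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$type)) NA_character_ else st$toks$type[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (identical(gpr_peek(st), "OR")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1) args[[1]]
  else structure(list(op = "or", args = args), class = "gpr_expression")
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (identical(gpr_peek(st), "AND")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1) args[[1]]
  else structure(list(op = "and", args = args), class = "gpr_expression")
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) {
    last <- length(st$toks$at)
    stop(sprintf("GPR parse error: unexpected end of rule after position %d",
                 if (last) st$toks$at[last] else 0L))
  }
  if (tk == "(") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    expr <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")"))
      stop(sprintf("GPR parse error: unbalanced parenthesis opened at position %d",
                   open_at))
    st$pos <- st$pos + 1L
    return(expr)
  }
  if (tk == "id") {
    leaf <- structure(list(op = "id", id = st$toks$text[st$pos]),
                      class = "gpr_expression")
    st$pos <- st$pos + 1L
    return(leaf)
  }
  stop(sprintf("GPR parse error: unexpected '%s' at position %d",
               st$toks$text[st$pos], st$toks$at[st$pos]))
}

#' Render a GPR expression tree back to a rule string
#'
#' @param expr A `gpr_expression`.
#' @return A single string; parsing it again yields an equivalent tree.
#' @export
deparse_gpr <- function(expr) {
  if (expr$op == "id") return(expr$id)
  parts <- vapply(expr$args, function(a) {
    s <- deparse_gpr(a)
    if (a$op == "or" && expr$op == "and") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", toupper(expr$op), " "))
}

#' Evaluate a GPR rule against protein abundances
#'
#' Computes the reaction weighting implied by quantified protein abundances:
#' an `AND` node (enzyme complex) takes the minimum over its members, an
#' `OR` node (isoenzymes) the sum. A complex with any unquantified member is
#' unobserved (the data cannot bound its capacity); an `OR` node drops
#' unobserved branches and is unobserved only if all branches are. Proteins
#' quantified at zero abundance are valid observations with weighting 0.
#'
#' @param expr A `gpr_expression` from [parse_gpr()].
#' @param abundances Named numeric vector (or list) of non-negative protein
#'   abundances; proteins absent from it are treated as unquantified.
#' @param partial_and How to score a complex with some members unquantified:
#'   `"drop"` (default) marks the reaction unobserved, `"min"` takes the
#'   minimum over the quantified members.
#' @return A non-negative number, or `NA_real_` when the rule is unobserved.
#' @examples
#' e <- parse_gpr("(P1 AND P2) OR P3")
#' evaluate_gpr(e, c(P1 = 0.2, P2 = 0.5, P3 = 0.1)) # min(0.2, 0.5) + 0.1
#' @export
evaluate_gpr <- function(expr, abundances, partial_and = c("drop", "min")) {
  partial_and <- match.arg(partial_and)
  ab <- unlist(abundances)
  if (length(ab) && any(ab < 0, na.rm = TRUE))
    stop("protein abundances must be non-negative")
  gpr_eval(expr, ab, partial_and)
}

gpr_eval <- function(expr, ab, partial_and) {
  if (expr$op == "id") {
    if (expr$id %in% names(ab)) return(unname(ab[[expr$id]]))
    return(NA_real_)
  }
  vals <- vapply(expr$args, gpr_eval, numeric(1), ab = ab,
                 partial_and = partial_and)
  if (expr$op == "and") {
    if (anyNA(vals)) {
      if (partial_and == "drop" || all(is.na(vals))) return(NA_real_)
      return(min(vals, na.rm = TRUE))
    }
    return(min(vals))
  }
  ## "or": unobserved branches contribute nothing
  if (all(is.na(vals))) return(NA_real_)
  sum(vals, na.rm = TRUE)
}

#' @export
print.gpr_expression <- function(x, ...) {
  cat("gpr_expression:", deparse_gpr(x), "\n")
  invisible(x)
}

#' Map a proteomic sample onto reaction weightings
#'
#' Evaluates every GPR rule of the model against one sample's protein
#' abundances, producing the reaction-indexed enzyme profile that enters the
#' prediction objective. Reactions whose rule is unobserved (see
#' [evaluate_gpr()]) or that carry no rule are excluded from the observed
#' set.
#'
#' @param model A [metabolic_model()].
#' @param protein_table Named numeric vector/list of protein abundances for
#'   one sample, or a proteins-x-samples matrix/data.frame (rownames =
#'   proteins) combined with `sample_id`.
#' @param sample_id Column to use when `protein_table` has several samples.
#' @param partial_and Passed to [evaluate_gpr()].
#' @return An `enzyme_profile`: list with `weightings` (named numeric,
#'   observed reactions only), `observed_mask` (logical length-`N`, the
#'   indicator of observed reactions) and `sample_id`.
#' @export
map_proteome <- function(model, protein_table, sample_id = NULL,
                         partial_and = c("drop", "min")) {
  partial_and <- match.arg(partial_and)
  if (is.matrix(protein_table) || is.data.frame(protein_table)) {
    if (is.null(sample_id)) sample_id <- colnames(protein_table)[1]
    ab <- stats::setNames(as.numeric(protein_table[, sample_id]),
                          rownames(protein_table))
  } else {
    ab <- unlist(protein_table)
  }
  ab <- ab[!is.na(ab)]
  w <- numeric(0)
  for (rid in names(model$gpr)) {
    val <- evaluate_gpr(model$gpr[[rid]], ab, partial_and = partial_and)
    if (!is.na(val)) w[rid] <- val
  }
  enzyme_profile(model, w, sample_id = sample_id)
}

#' Construct an enzyme profile
#'
#' @param model A [metabolic_model()].
#' @param weightings Named non-negative numeric vector of reaction
#'   weightings (names must be model reactions).
#' @param sample_id Optional sample label.
#' @return An object of class `enzyme_profile`.
#' @export
enzyme_profile <- function(model, weightings, sample_id = NULL) {
  if (length(weightings)) {
    unknown <- setdiff(names(weightings), model$reaction_ids)
    if (length(unknown))
      stop("enzyme weighting for unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    if (any(weightings < 0))
      stop("enzyme weightings must be non-negative")
  }
  structure(
    list(
      weightings = weightings,
      observed_mask = model$reaction_ids %in% names(weightings),
      sample_id = sample_id
    ),
    class = "enzyme_profile"
  )
}

#' @export
print.enzyme_profile <- function(x, ...) {
  cat(sprintf("enzyme_profile: %d observed reactions", length(x$weightings)))
  if (!is.null(x$sample_id)) cat(" (sample ", x$sample_id, ")", sep = "")
  cat("\n")
  invisible(x)
}
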
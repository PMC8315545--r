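#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` bundles the stoichiometric matrix `S` (metabolites in
#' rows, reactions in columns), flux bounds, reversibility and exchange flags,
#' and parsed gene-protein-reaction (GPR) rules. Steady-state mass balance
#' `S v = mdot` together with the box `v_inf <= v <= v_sup` defines the
#' feasible flux polytope every downstream computation works on.
#'
#' @param metabolite_ids Character vector of unique metabolite identifiers
#'   (length `M`).
#' @param reaction_ids Character vector of unique reaction identifiers
#'   (length `N`).
#' @param S Numeric `M x N` matrix of stoichiometric coefficients.
#' @param v_inf,v_sup Numeric length-`N` lower and upper flux bounds
#'   (nominally mmol gDW^-1 h^-1).
#' @param exchange Logical length-`N` vector flagging boundary (exchange)
#'   reactions. Defaults to all `FALSE`.
#' @param gpr Named list mapping a subset of `reaction_ids` to GPR rule
#'   strings (see [parse_gpr()]) or parsed `gpr_expression` trees.
#' @return An object of class `metabolic_model` with elements
#'   `metabolite_ids`, `reaction_ids`, `S`, `v_inf`, `v_sup`, `reversible`,
#'   `exchange`, `gpr` (parsed trees) and `gpr_text` (rule strings).
#'   A reaction is reversible iff both bounds are nonzero with
#'   `v_inf < 0 < v_sup`; irreversibility is encoded as `v_inf = 0` (forward
#'   convention) or `v_sup = 0` (reverse convention).
#' @examples
#' m <- metabolic_model(
#'   metabolite_ids = "A",
#'   reaction_ids = c("r1", "r2"),
#'   S = matrix(c(1, -1), 1, 2),
#'   v_inf = c(0, 0), v_sup = c(1, 1)
#' )
#' reversibility_summary(m)
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, S, v_inf, v_sup,
                            exchange = NULL, gpr = list()) {
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (is.null(exchange)) exchange <- rep(FALSE, length(reaction_ids))
  gpr_text <- character(0)
  gpr_trees <- list()
  for (rid in names(gpr)) {
    g <- gpr[[rid]]
    if (is.character(g)) {
      gpr_text[rid] <- g
      gpr_trees[[rid]] <- parse_gpr(g)
    } else {
      gpr_text[rid] <- deparse_gpr(g)
      gpr_trees[[rid]] <- g
    }
  }
  m <- structure(
    list(
      metabolite_ids = metabolite_ids,
      reaction_ids = reaction_ids,
      S = S,
      v_inf = as.numeric(v_inf),
      v_sup = as.numeric(v_sup),
      reversible = as.numeric(v_inf) < 0 & as.numeric(v_sup) > 0,
      exchange = as.logical(exchange),
      gpr = gpr_trees,
      gpr_text = gpr_text
    ),
    class = "metabolic_model"
  )
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks dimensional consistency, bound ordering, uniqueness of identifiers
#' and agreement of the reversibility flags with the bounds.
#'
#' @param model A [metabolic_model()].
#' @return The model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  M <- length(model$metabolite_ids)
  N <- length(model$reaction_ids)
  if (anyDuplicated(model$metabolite_ids))
    stop("duplicate metabolite identifiers: ",
         paste(unique(model$metabolite_ids[duplicated(model$metabolite_ids)]),
               collapse = ", "))
  if (anyDuplicated(model$reaction_ids))
    stop("duplicate reaction identifiers: ",
         paste(unique(model$reaction_ids[duplicated(model$reaction_ids)]),
               collapse = ", "))
  if (!all(dim(model$S) == c(M, N)))
    stop(sprintf("stoichiometric matrix is %d x %d but model lists %d metabolites and %d reactions",
                 nrow(model$S), ncol(model$S), M, N))
  if (length(model$v_inf) != N || length(model$v_sup) != N)
    stop("flux bound vectors must have one entry per reaction")
  if (anyNA(model$v_inf) || anyNA(model$v_sup))
    stop("flux bounds must be numeric (NA/NaN not allowed)")
  bad <- which(model$v_inf > model$v_sup)
  if (length(bad))
    stop("empty flux interval (v_inf > v_sup) for reaction(s): ",
         paste(model$reaction_ids[bad], collapse = ", "))
  if (length(model$exchange) != N)
    stop("exchange flags must have one entry per reaction")
  if (!all(names(model$gpr) %in% model$reaction_ids))
    stop("GPR rule attached to unknown reaction(s): ",
         paste(setdiff(names(model$gpr), model$reaction_ids), collapse = ", "))
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  n_rev <- sum(x$reversible)
  cat(sprintf("metabolic_model: %d metabolites x %d reactions\n",
              length(x$metabolite_ids), length(x$reaction_ids)))
  cat(sprintf("  reversible: %d, exchange: %d, with GPR: %d\n",
              n_rev, sum(x$exchange), length(x$gpr)))
  invisible(x)
}

#' @export
dim.metabolic_model <- function(x) dim(x$S)

#' Count reversible and irreversible reactions
#'
#' Partitions reactions with a nonzero admissible flux range into reversible
#' (`v_inf < 0 < v_sup`) and irreversible; reactions pinned to zero
#' (`v_inf = v_sup = 0`) are reported separately and belong to neither count.
#'
#' @param model A [metabolic_model()].
#' @return A list with integer counts `n_reversible`, `n_irreversible`,
#'   `n_zeroed`.
#' @export
reversibility_summary <- function(model) {
  zeroed <- model$v_inf == 0 & model$v_sup == 0
  rev <- model$reversible & !zeroed
  list(
    n_reversible = sum(rev),
    n_irreversible = sum(!rev & !zeroed),
    n_zeroed = sum(zeroed)
  )
}

#' Specify additional constraints on a model
#'
#' Collects the constraint set used to adapt a generic model to a particular
#' physiological context: reactions forced irreversible, reactions switched
#' off entirely, and experimentally observed exchange fluxes `v_i ~
#' N(v_obs, sigma^2)` that later condition the flux posterior.
#'
#' @param irreversible Character vector of reaction ids forced to
#'   `v_inf = 0`.
#' @param zeroed Character vector of reaction ids forced to
#'   `v_inf = v_sup = 0`.
#' @param fixed_exchanges Named list `reaction_id = c(value, sigma)` of
#'   observed exchange fluxes with their measurement scale `sigma > 0`.
#' @return An object of class `constraint_spec`.
#' @seealso [apply_constraints()], [condition_on_observed_flux()]
#' @export
constraint_spec <- function(irreversible = character(0),
                            zeroed = character(0),
                            fixed_exchanges = list()) {
  for (rid in names(fixed_exchanges)) {
    fe <- fixed_exchanges[[rid]]
    if (length(fe) != 2 || !is.numeric(fe))
      stop("fixed_exchanges entries must be numeric c(value, sigma)")
    if (fe[2] <= 0)
      stop("observation sigma must be > 0 for reaction ", rid)
  }
  structure(
    list(irreversible = as.character(irreversible),
         zeroed = as.character(zeroed),
         fixed_exchanges = fixed_exchanges),
    class = "constraint_spec"
  )
}

#' Apply a constraint specification to a model
#'
#' Narrows flux bounds according to the spec: reactions in
#' `spec$irreversible` get `v_inf = 0`, reactions in `spec$zeroed` get
#' `v_inf = v_sup = 0`. Observed exchange fluxes are recorded on the model
#' (attribute `fixed_exchanges`) for downstream posterior conditioning but do
#' not alter the bounds. Reversibility flags are recomputed from the new
#' bounds. Bounds are only ever narrowed, never widened.
#'
#' @param model A [metabolic_model()].
#' @param spec A [constraint_spec()].
#' @return A new `metabolic_model` with narrowed bounds; stops if a
#'   tightening empties a flux interval or references an unknown reaction.
#' @export
apply_constraints <- function(model, spec) {
  all_ids <- c(spec$irreversible, spec$zeroed, names(spec$fixed_exchanges))
  unknown <- setdiff(all_ids, model$reaction_ids)
  if (length(unknown))
    stop("constraint references unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  v_inf <- model$v_inf
  v_sup <- model$v_sup
  idx <- match(spec$irreversible, model$reaction_ids)
  v_inf[idx] <- pmax(v_inf[idx], 0)
  idx <- match(spec$zeroed, model$reaction_ids)
  v_inf[idx] <- pmax(v_inf[idx], 0)
  v_sup[idx] <- pmin(v_sup[idx], 0)
  bad <- which(v_inf > v_sup)
  if (length(bad))
    stop("constraints empty the flux interval of reaction(s): ",
         paste(model$reaction_ids[bad], collapse = ", "))
  out <- model
  out$v_inf <- v_inf
  out$v_sup <- v_sup
  out$reversible <- v_inf < 0 & v_sup > 0
  attr(out, "fixed_exchanges") <- spec$fixed_exchanges
  validate_model(out)
  out
}
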
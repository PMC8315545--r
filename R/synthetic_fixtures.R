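## Synthetic constraint-based models and proteomes.
##
## Small modular models with a single input flux and several outputs, plus
## enzyme-abundance tables generated from hidden flux vectors, emulating the
## structure of a curated central-carbon model coupled to a quantitative
## proteomic dataset. Everything is generated in code, deterministically
## from a seed.

#' Built-in toy metabolic models
#'
#' A named collection of small models used throughout the tests and
#' examples:
#' \describe{
#'   \item{segment}{1 metabolite, 2 reactions (`in -> A -> out`); the
#'     feasible set is the unit segment `v1 = v2` in `[0, 1]`.}
#'   \item{branch}{`v1 = v2 + v3`, all in `[0, 1]`.}
#'   \item{diamond}{two parallel routes between an entry and an exit
#'     metabolite.}
#'   \item{toy_central_carbon}{a 14-reaction caricature of yeast central
#'     carbon metabolism: a glycolysis-like trunk from a single glucose
#'     input, a pentose-phosphate-like bypass, a fermentation branch to
#'     ethanol, a glycerol branch and an oxidative CO2 branch, with GPR
#'     rules (including complexes and isoenzymes) on most reactions.}
#' }
#'
#' @return Named list of [metabolic_model()] objects.
#' @export
toy_models <- function() {
  segment <- metabolic_model(
    metabolite_ids = "A",
    reaction_ids = c("r1", "r2"),
    S = matrix(c(1, -1), 1, 2),
    v_inf = c(0, 0), v_sup = c(1, 1),
    exchange = c(TRUE, TRUE),
    gpr = list(r1 = "P1", r2 = "P2")
  )
  branch <- metabolic_model(
    metabolite_ids = "A",
    reaction_ids = c("v1", "v2", "v3"),
    S = matrix(c(1, -1, -1), 1, 3),
    v_inf = c(0, 0, 0), v_sup = c(1, 1, 1),
    exchange = c(TRUE, TRUE, TRUE),
    gpr = list(v1 = "P1", v2 = "P2 OR P3")
  )
  diamond <- metabolic_model(
    metabolite_ids = c("A", "B"),
    reaction_ids = c("in", "up", "down", "out"),
    S = matrix(c(
      1, -1, -1, 0,
      0, 1, 1, -1
    ), 2, 4, byrow = TRUE),
    v_inf = c(0, 0, 0, 0), v_sup = c(1, 1, 1, 1),
    exchange = c(TRUE, FALSE, FALSE, TRUE),
    gpr = list(up = "P1 AND P2", down = "P3", out = "P4")
  )
  ## toy central carbon: GLC -> G6P -> ... -> ethanol / glycerol / CO2
  mets <- c("G6P", "F6P", "FBP", "T3P", "PEP", "PYR", "ACA", "ETH",
            "GLY", "CO2")
  rxns <- c("GLC_in", "PGI", "PFK", "FBA", "GAPDH", "PYK", "PDC", "ADH",
            "ETH_out", "PPP", "GPD", "GLY_out", "TCA", "CO2_out")
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  add <- function(r, ...) {
    st <- c(...)
    S[names(st), r] <<- st
  }
  add("GLC_in", G6P = 1)
  add("PGI", G6P = -1, F6P = 1)
  add("PFK", F6P = -1, FBP = 1)
  add("FBA", FBP = -1, T3P = 2)
  add("GAPDH", T3P = -1, PEP = 1)
  add("PYK", PEP = -1, PYR = 1)
  add("PDC", PYR = -1, ACA = 1, CO2 = 1)
  add("ADH", ACA = -1, ETH = 1)
  add("ETH_out", ETH = -1)
  add("PPP", G6P = -1, T3P = 1, CO2 = 1)
  add("GPD", T3P = -1, GLY = 1)
  add("GLY_out", GLY = -1)
  add("TCA", PYR = -1, CO2 = 3)
  add("CO2_out", CO2 = -1)
  dimnames(S) <- NULL
  tcc <- metabolic_model(
    metabolite_ids = mets,
    reaction_ids = rxns,
    S = S,
    v_inf = rep(0, length(rxns)),
    v_sup = c(1, rep(2, 7), 2, 2, 2, 2, 2, 8),
    exchange = rxns %in% c("GLC_in", "ETH_out", "GLY_out", "CO2_out"),
    gpr = list(
      PGI = "PGI1",
      PFK = "PFK1 AND PFK2",
      FBA = "FBA1",
      GAPDH = "TDH1 OR TDH2 OR TDH3",
      PYK = "CDC19",
      PDC = "PDC1 OR PDC5",
      ADH = "ADH1 OR ADH3",
      PPP = "ZWF1",
      GPD = "GPD1 AND GPP1",
      TCA = "CIT1"
    )
  )
  list(segment = segment, branch = branch, diamond = diamond,
       toy_central_carbon = tcc)
}

#' Specification for a random synthetic model
#'
#' @param n_metabolites,n_reactions Network size; `n_reactions` must exceed
#'   `n_metabolites` so the model typically has free degrees of freedom.
#' @param n_pathways Number of planted parallel pathways (chains sharing
#'   hub metabolites).
#' @param n_exchanges Number of exchange reactions (>= 2: one input plus
#'   outputs).
#' @param reversible_fraction Fraction of internal reactions given
#'   symmetric bounds `[-bound_width, bound_width]`.
#' @param bound_width Half-width of the flux box.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_metabolites = 12, n_reactions = 20,
                           n_pathways = 3, n_exchanges = 4,
                           reversible_fraction = 0.2, bound_width = 1,
                           seed = 1L) {
  stopifnot(n_reactions > n_metabolites, n_exchanges >= 2,
            n_pathways >= 1, reversible_fraction >= 0,
            reversible_fraction <= 1, bound_width > 0)
  structure(
    list(n_metabolites = n_metabolites, n_reactions = n_reactions,
         n_pathways = n_pathways, n_exchanges = n_exchanges,
         reversible_fraction = reversible_fraction,
         bound_width = bound_width, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a random modular constraint-based model
#'
#' Builds `n_pathways` chains of unit-stoichiometry reactions running from
#' a shared input hub metabolite to a shared output hub (the planted
#' pathway partition, recorded in attribute `pathways`), adds one input
#' exchange and `n_exchanges - 1` output exchanges, tops the network up to
#' `n_reactions` with duplicate parallel reactions of randomly chosen chain
#' edges (which creates within-pathway degrees of freedom), assigns bounds
#' `[0, bound_width]` or `[-bound_width, bound_width]` according to
#' `reversible_fraction`, and attaches a single-protein GPR to every
#' internal reaction. The zero flux vector is always feasible, and the
#' model is deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [metabolic_model()] with attribute `pathways` (named integer
#'   vector over internal chain reactions; exchanges carry `NA`).
#' @export
random_cbm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    P <- spec$n_pathways
    n_int_mets <- spec$n_metabolites - 2L # hubs: HUB_in, HUB_out
    if (n_int_mets < P)
      stop("need at least n_pathways + 2 metabolites")
    ## split internal metabolites over pathways (each gets >= 1)
    alloc <- rep(seq_len(P), length.out = n_int_mets)
    alloc <- sort(alloc)
    mets <- c("HUB_in", "HUB_out",
              unlist(lapply(seq_len(P), function(p)
                sprintf("M%d_%d", p, seq_len(sum(alloc == p))))))
    edges <- list() # list of c(from, to, pathway)
    for (p in seq_len(P)) {
      chain <- c("HUB_in", sprintf("M%d_%d", p, seq_len(sum(alloc == p))),
                 "HUB_out")
      for (i in seq_len(length(chain) - 1))
        edges[[length(edges) + 1]] <- list(from = chain[i],
                                           to = chain[i + 1], pw = p)
    }
    n_chain <- length(edges)
    n_exch <- spec$n_exchanges
    n_extra <- spec$n_reactions - n_chain - n_exch
    if (n_extra < 0)
      stop(sprintf(
        "spec infeasible: %d chain reactions + %d exchanges exceed n_reactions = %d",
        n_chain, n_exch, spec$n_reactions))
    if (n_extra > 0) {
      dup <- sample(n_chain, n_extra, replace = TRUE)
      for (k in dup)
        edges[[length(edges) + 1]] <- edges[[k]]
    }
    rxn_ids <- sprintf("R%02d_p%d", seq_along(edges),
                       vapply(edges, `[[`, numeric(1), "pw"))
    pathways <- vapply(edges, `[[`, numeric(1), "pw")
    S <- matrix(0, length(mets), length(edges) + n_exch,
                dimnames = list(mets, NULL))
    for (j in seq_along(edges)) {
      S[edges[[j]]$from, j] <- -1
      S[edges[[j]]$to, j] <- 1
    }
    exch_ids <- c("EX_in", sprintf("EX_out%d", seq_len(n_exch - 1L)))
    S["HUB_in", length(edges) + 1L] <- 1
    for (e in seq_len(n_exch - 1L))
      S["HUB_out", length(edges) + 1L + e] <- -1
    dimnames(S) <- NULL
    ids <- c(rxn_ids, exch_ids)
    Nrx <- length(ids)
    w <- spec$bound_width
    rev <- c(stats::runif(length(edges)) < spec$reversible_fraction,
             rep(FALSE, n_exch))
    v_inf <- ifelse(rev, -w, 0)
    v_sup <- rep(w, Nrx)
    gpr <- stats::setNames(as.list(paste0("Pr_", rxn_ids)), rxn_ids)
    m <- metabolic_model(
      metabolite_ids = mets, reaction_ids = ids, S = S,
      v_inf = v_inf, v_sup = v_sup,
      exchange = ids %in% exch_ids, gpr = gpr
    )
    attr(m, "pathways") <- stats::setNames(
      c(pathways, rep(NA_real_, n_exch)), ids)
    m
  })
}

#' Generate a synthetic proteome with hidden ground-truth fluxes
#'
#' For each of `n_samples` samples, draws a hidden flux vector from the
#' feasible space, converts it to enzyme abundances for every GPR-bearing
#' reaction through the chosen kinetic relation, and perturbs abundances
#' with multiplicative log-normal noise of log-scale standard deviation
#' `noise_sd` (`noise_sd = 0` reproduces noiseless simulations). For
#' single-protein GPR rules the protein row is named after the rule's
#' protein, so mapping the table back through [map_proteome()] recovers
#' the weightings.
#'
#' @param model A feasible [metabolic_model()] with GPR rules.
#' @param relation Kinetic relation tag (see [enzymes_from_fluxes()]).
#' @param noise_sd Standard deviation of the log-normal noise (log scale).
#' @param n_samples Number of samples (columns).
#' @param seed Integer seed; tables are bit-reproducible.
#' @param posterior Optional prefitted `flux_posterior`.
#' @param ... Passed to [enzymes_from_fluxes()].
#' @return A list with `abundance` (proteins x samples matrix),
#'   `fluxes` (reactions x samples matrix of hidden ground truth) and
#'   `protein_reaction` (map from protein row to reaction).
#' @export
synthetic_proteome <- function(model, relation = "identity", noise_sd = 0,
                               n_samples = 10, seed = 1L, posterior = NULL,
                               ...) {
  stopifnot(noise_sd >= 0, n_samples >= 1)
  if (is.null(posterior)) posterior <- ep_fit(model)
  gpr_rxns <- names(model$gpr)
  if (length(gpr_rxns) == 0) stop("model has no GPR rules")
  draw <- sample_posterior(posterior, n_samples, seed = seed)
  v_ok <- vapply(seq_len(n_samples), function(s) {
    v <- draw$fluxes[s, ]
    tryCatch({
      enzymes_from_fluxes(v, relation, seed = seed + s,
                          reactions = gpr_rxns, ...)
      TRUE
    }, error = function(e) FALSE)
  }, logical(1))
  ## resample any draw violating a singularity guard
  for (s in which(!v_ok)) {
    draw$fluxes[s, ] <- draw_valid_initial(
      posterior, draw$fluxes[s, ], relation, seed + 7919L * s, ...)
  }
  ## proteins realized per reaction so the rule evaluates back to E:
  ## all members of a complex get E (min = E); only the first branch of an
  ## OR is quantified (sum over observed branches = E)
  prot_map <- lapply(gpr_rxns, function(rid)
    gpr_realized_proteins(model$gpr[[rid]]))
  names(prot_map) <- gpr_rxns
  proteins <- unique(unlist(prot_map))
  ab <- matrix(NA_real_, length(proteins), n_samples,
               dimnames = list(proteins,
                               sprintf("sample_%02d", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    E <- enzymes_from_fluxes(draw$fluxes[s, ], relation, seed = seed + s,
                             reactions = gpr_rxns, ...)
    if (noise_sd > 0) {
      eps <- with_seed(seed + 2L * s + 1L,
                       stats::rnorm(length(E), 0, noise_sd))
      E <- E * exp(eps)
    }
    for (rid in gpr_rxns) ab[prot_map[[rid]], s] <- E[[rid]]
  }
  fl <- t(draw$fluxes)
  colnames(fl) <- colnames(ab)
  list(abundance = ab, fluxes = fl, protein_reaction = prot_map)
}

## Proteins to quantify so that evaluating the rule returns exactly the
## planted reaction weighting: every AND member, the first OR branch only.
gpr_realized_proteins <- function(expr) {
  if (expr$op == "id") return(expr$id)
  if (expr$op == "and")
    return(unique(unlist(lapply(expr$args, gpr_realized_proteins))))
  gpr_realized_proteins(expr$args[[1]])
}
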
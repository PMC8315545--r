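#' Read a metabolic model from disk
#'
#' Supports two formats: a compact JSON dialect (see Details) and SBML
#' Level 3 with the `fbc` flux-bounds/GPR extension.
#'
#' @details The JSON dialect is
#' ```
#' {"metabolites": [{"id": "A"}, ...],
#'  "reactions": [{"id": "r1", "stoich": {"A": 1.0, ...},
#'                 "lb": 0.0, "ub": 1.0,
#'                 "gpr": "P1 AND P2" | null, "exchange": false}, ...]}
#' ```
#' `stoich` maps metabolite ids to signed coefficients (products positive,
#' substrates negative). Every metabolite referenced by a reaction must
#' appear in the metabolite list.
#'
#' @param path Path to the model file.
#' @param format `"json"` or `"sbml"`; `NULL` guesses from the extension.
#' @return A [metabolic_model()].
#' @seealso [write_model()]
#' @export
read_model <- function(path, format = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  format <- match.arg(format, c("json", "sbml"))
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("malformed model JSON: top-level 'metabolites' and 'reactions' required")
  met_ids <- vapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed model JSON: metabolite without 'id'")
    as.character(m$id)
  }, character(1))
  N <- length(doc$reactions)
  rxn_ids <- character(N)
  lb <- numeric(N); ub <- numeric(N); exch <- logical(N)
  S <- matrix(0, length(met_ids), N, dimnames = list(met_ids, NULL))
  gpr <- list()
  for (j in seq_len(N)) {
    r <- doc$reactions[[j]]
    if (is.null(r$id)) stop("malformed model JSON: reaction without 'id'")
    rxn_ids[j] <- as.character(r$id)
    if (is.null(r$lb) || is.null(r$ub))
      stop("malformed model JSON: reaction '", r$id, "' lacks lb/ub bounds")
    lb[j] <- as.numeric(r$lb); ub[j] <- as.numeric(r$ub)
    exch[j] <- isTRUE(r$exchange)
    for (met in names(r$stoich)) {
      if (!met %in% met_ids)
        stop("reaction '", r$id, "' references unknown metabolite '",
             met, "'")
      S[met, j] <- as.numeric(r$stoich[[met]])
    }
    if (!is.null(r$gpr) && !is.na(r$gpr) && nzchar(r$gpr))
      gpr[[rxn_ids[j]]] <- as.character(r$gpr)
  }
  dimnames(S) <- NULL
  metabolic_model(met_ids, rxn_ids, S, lb, ub, exchange = exch, gpr = gpr)
}

#' Write a metabolic model to the package JSON dialect
#'
#' Inverse of [read_model()] for the JSON format: `read_model(write_model(m))`
#' reproduces `m` (ids, stoichiometry, bounds, exchange flags and GPR rules
#' up to whitespace).
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  mets <- lapply(model$metabolite_ids, function(id) list(id = id))
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    rid <- model$reaction_ids[j]
    nz <- which(model$S[, j] != 0)
    stoich <- as.list(model$S[nz, j])
    names(stoich) <- model$metabolite_ids[nz]
    list(
      id = rid,
      stoich = stoich,
      lb = model$v_inf[j],
      ub = model$v_sup[j],
      gpr = if (rid %in% names(model$gpr_text)) model$gpr_text[[rid]] else NULL,
      exchange = model$exchange[j]
    )
  })
  json <- jsonlite::toJSON(list(metabolites = mets, reactions = rxns),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) stop("cannot write model to '", path,
                                          "': ", conditionMessage(e)))
  invisible(path)
}

## SBML Level 3 + fbc import. Maps species -> metabolites, reactions with
## speciesReference stoichiometries, fbc bound parameters and
## geneProductAssociation trees onto the same metabolic_model type.
## Queries use local-name() so any namespace prefixing (core, fbc) works.
ln <- function(name) sprintf("*[local-name()='%s']", name)

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  species <- xml2::xml_find_all(doc, sprintf(".//%s/%s", ln("listOfSpecies"),
                                             ln("species")))
  keep <- !vapply(species, function(s)
    identical(xml2::xml_attr(s, "boundaryCondition"), "true"), logical(1))
  species <- species[keep]
  met_ids <- vapply(species, xml2::xml_attr, character(1), attr = "id")

  params <- xml2::xml_find_all(doc, sprintf(".//%s/%s",
                                            ln("listOfParameters"),
                                            ln("parameter")))
  pval <- stats::setNames(
    as.numeric(vapply(params, xml2::xml_attr, character(1), attr = "value")),
    vapply(params, xml2::xml_attr, character(1), attr = "id"))

  gp_nodes <- xml2::xml_find_all(doc, sprintf(".//%s", ln("geneProduct")))
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(g) {
      lab <- xml2::xml_attr(g, "label")
      if (is.na(lab)) xml2::xml_attr(g, "id") else lab
    }, character(1)),
    vapply(gp_nodes, xml2::xml_attr, character(1), attr = "id"))

  rxn_nodes <- xml2::xml_find_all(doc, sprintf(".//%s/%s",
                                               ln("listOfReactions"),
                                               ln("reaction")))
  N <- length(rxn_nodes)
  rxn_ids <- vapply(rxn_nodes, xml2::xml_attr, character(1), attr = "id")
  S <- matrix(0, length(met_ids), N, dimnames = list(met_ids, NULL))
  lb <- numeric(N); ub <- numeric(N); exch <- logical(N)
  gpr <- list()
  for (j in seq_len(N)) {
    rx <- rxn_nodes[[j]]
    n_boundary <- 0L
    for (sr in xml2::xml_find_all(rx, sprintf("./%s/%s",
                                              ln("listOfReactants"),
                                              ln("speciesReference")))) {
      sid <- xml2::xml_attr(sr, "species")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      if (sid %in% met_ids) S[sid, j] <- S[sid, j] - coef
      else n_boundary <- n_boundary + 1L
    }
    for (sr in xml2::xml_find_all(rx, sprintf("./%s/%s",
                                              ln("listOfProducts"),
                                              ln("speciesReference")))) {
      sid <- xml2::xml_attr(sr, "species")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      if (sid %in% met_ids) S[sid, j] <- S[sid, j] + coef
      else n_boundary <- n_boundary + 1L
    }
    lbp <- xml2::xml_attr(rx, "lowerFluxBound")
    ubp <- xml2::xml_attr(rx, "upperFluxBound")
    rev_attr <- identical(xml2::xml_attr(rx, "reversible"), "true")
    lb[j] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]]
             else if (rev_attr) -1000 else 0
    ub[j] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    ## exchange: touches the boundary, or only one side of the reaction
    exch[j] <- n_boundary > 0L || sum(S[, j] != 0) <= 1L
    ga <- xml2::xml_find_first(
      rx, sprintf("./%s/*", ln("geneProductAssociation")))
    if (!inherits(ga, "xml_missing")) {
      tree <- sbml_gpr_tree(ga, gp_label)
      if (!is.null(tree)) gpr[[rxn_ids[j]]] <- tree
    }
  }
  dimnames(S) <- NULL
  metabolic_model(met_ids, rxn_ids, S, lb, ub, exchange = exch, gpr = gpr)
}

sbml_gpr_tree <- function(node, gp_label) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    id <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
    return(structure(list(op = "id", id = id), class = "gpr_expression"))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), sbml_gpr_tree,
                   gp_label = gp_label)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (length(kids) == 0) return(NULL)
    if (length(kids) == 1) return(kids[[1]])
    return(structure(list(op = nm, args = kids), class = "gpr_expression"))
  }
  NULL
}

#' Read a proteome abundance table
#'
#' Reads a tab-separated table with protein identifiers in the first column
#' and one column of relative abundances per sample (header row required).
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, proteins in rows (rownames), samples in columns.
#' @export
read_proteome <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("proteome table needs a protein-id column plus >= 1 sample column")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  mat
}

#' Write a proteome abundance table
#'
#' @param mat Numeric matrix, proteins in rows, samples in columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(mat, path) {
  df <- data.frame(protein = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
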
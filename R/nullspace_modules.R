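## Modular decomposition of the metabolic network from the null space of S.
##
## Each reaction is a row vector in an orthonormal kernel basis K of the
## stoichiometric matrix. Reactions whose row vectors are (anti)parallel are
## strictly coupled; angles between row vectors measure how independently
## two reactions can vary, and hierarchical clustering on the angle matrix
## recovers the pathway structure without enumerating elementary modes.

#' Angles between reaction vectors in the null space
#'
#' Computes the symmetric matrix of angles (degrees) between the kernel row
#' vectors of all reaction pairs, under the acute-angle convention
#' `angle(i, j) = acos(|<k_i, k_j>| / (||k_i|| ||k_j||))` so that reactions
#' coupled with opposite signs coincide at angle 0. Reactions with a
#' (near-)zero kernel row are fully determined by the constraints; they are
#' flagged and assigned 90 degrees to every other reaction.
#'
#' @param K A [kernel_basis()] (or the `N x d` kernel matrix itself).
#' @param zero_tol Row-norm threshold below which a reaction counts as
#'   fully determined.
#' @return An `N x N` numeric matrix of angles in `[0, 90]` with zero
#'   diagonal, reaction ids as dimnames when available, and the integer
#'   indices of determined reactions in attribute `determined`.
#' @export
reaction_angles <- function(K, zero_tol = 1e-10) {
  kb <- if (inherits(K, "kernel_basis")) K else
    structure(list(K = as.matrix(K), d = ncol(K),
                   reaction_ids = rownames(K)), class = "kernel_basis")
  if (kb$d == 0)
    stop("model has no degrees of freedom (kernel dimension 0)")
  Km <- kb$K
  N <- nrow(Km)
  norms <- sqrt(rowSums(Km^2))
  determined <- unname(which(norms < zero_tol))
  U <- Km / pmax(norms, zero_tol)
  C <- abs(tcrossprod(U))
  C[C > 1] <- 1
  ang <- acos(C) * 180 / pi
  diag(ang) <- 0
  if (length(determined)) {
    ang[determined, ] <- 90
    ang[, determined] <- 90
    ang[determined, determined] <- 90
    diag(ang) <- 0
  }
  if (!is.null(kb$reaction_ids))
    dimnames(ang) <- list(kb$reaction_ids, kb$reaction_ids)
  attr(ang, "determined") <- determined
  ang
}

#' Cluster reactions into metabolic modules
#'
#' Agglomerative hierarchical clustering of reactions using the null-space
#' angle matrix as the metric, cut at a user-chosen number of modules.
#' Fully determined reactions (zero kernel rows) are reported separately
#' rather than forced into modules; their label is `NA`.
#'
#' @param angles Angle matrix from [reaction_angles()].
#' @param n_modules Number of modules to cut the dendrogram into.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return A `module_decomposition`: list with `labels` (named integer
#'   vector, `NA` for determined reactions), `n_modules`, `linkage`,
#'   `hclust` (the dendrogram over free reactions), `determined` (ids) and
#'   `angles`.
#' @export
cluster_reactions <- function(angles, n_modules,
                              linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  N <- nrow(angles)
  determined <- attr(angles, "determined")
  if (is.null(determined)) determined <- integer(0)
  free <- setdiff(seq_len(N), determined)
  if (n_modules > length(free))
    stop(sprintf("n_modules (%d) exceeds the number of free reactions (%d)",
                 n_modules, length(free)))
  hc <- stats::hclust(stats::as.dist(angles[free, free, drop = FALSE]),
                      method = linkage)
  lab_free <- stats::cutree(hc, k = n_modules)
  labels <- rep(NA_integer_, N)
  labels[free] <- lab_free
  ids <- rownames(angles)
  if (!is.null(ids)) names(labels) <- ids
  structure(
    list(labels = labels, n_modules = n_modules, linkage = linkage,
         hclust = hc,
         determined = if (!is.null(ids)) ids[determined] else determined,
         angles = angles),
    class = "module_decomposition"
  )
}

#' @export
print.module_decomposition <- function(x, ...) {
  cat(sprintf("module_decomposition: %d modules over %d reactions (%s linkage)\n",
              x$n_modules, length(x$labels), x$linkage))
  if (length(x$determined))
    cat("  fully determined (unclustered):",
        paste(x$determined, collapse = ", "), "\n")
  invisible(x)
}

#' Proteome coverage of metabolic modules
#'
#' Tabulates, per module, how many reactions carry an observed enzyme
#' abundance -- the check that observations are spread over the main
#' pathways rather than concentrated in one.
#'
#' @param decomp A `module_decomposition`.
#' @param observed Character vector of observed reaction ids (or an
#'   `enzyme_profile`, whose weighting names are used).
#' @return A data frame with one row per module (plus one for determined
#'   reactions, when present): `module`, `n_reactions`, `n_observed`,
#'   `fraction`, `flag_uncovered`.
#' @export
coverage_report <- function(decomp, observed) {
  if (inherits(observed, "enzyme_profile"))
    observed <- names(observed$weightings)
  ids <- names(decomp$labels)
  if (is.null(ids))
    stop("module decomposition carries no reaction ids")
  unknown <- setdiff(observed, ids)
  if (length(unknown))
    stop("unknown reaction id(s) in observed set: ",
         paste(unknown, collapse = ", "))
  grp <- ifelse(is.na(decomp$labels), "determined",
                paste0("module_", decomp$labels))
  mods <- unique(grp[order(decomp$labels, na.last = TRUE)])
  out <- do.call(rbind, lapply(mods, function(m) {
    members <- ids[grp == m]
    n_obs <- sum(members %in% observed)
    data.frame(module = m, n_reactions = length(members),
               n_observed = n_obs,
               fraction = n_obs / length(members),
               flag_uncovered = n_obs == 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export a module dendrogram in Newick format
#'
#' @param decomp A `module_decomposition`.
#' @return A single Newick string with branch lengths in angle units.
#' @export
modules_newick <- function(decomp) {
  hc <- decomp$hclust
  lab <- hc$labels
  if (is.null(lab)) lab <- as.character(seq_along(hc$order))
  rec <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%g", lab[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%g",
              rec(hc$merge[i, 1], h), rec(hc$merge[i, 2], h),
              parent_h - h)
    }
  }
  n <- length(hc$height)
  paste0("(", rec(hc$merge[n, 1], hc$height[n]), ",",
         rec(hc$merge[n, 2], hc$height[n]), ");")
}
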
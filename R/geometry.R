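## Polytope geometry shared by the EP fit and both samplers.
##
## The feasible set L = { v : S v = mdot, v_inf <= v <= v_sup } is handled
## through an exact affine parameterization v = v_p + K x, where v_p is the
## minimum-norm particular solution of S v = mdot and the columns of K form
## an orthonormal basis of null(S). All sampling happens in the x
## coordinates, so mass balance holds to machine precision by construction.

#' Orthonormal null-space basis of the stoichiometric matrix
#'
#' Computes rank and kernel of `S` by singular value decomposition. The
#' kernel dimension `d = N - rank(S)` is the number of degrees of freedom of
#' the metabolic model; the rows of `K` are the reaction vectors whose
#' mutual angles define the modular decomposition (see [reaction_angles()]).
#'
#' @param model A [metabolic_model()] (or a plain matrix taken as `S`).
#' @param tol Relative singular-value tolerance: singular values below
#'   `tol * max(sv)` count as zero.
#' @return An object of class `kernel_basis`: list with `K` (`N x d`,
#'   orthonormal columns), `d`, `rank`, `sv_tolerance` and `reaction_ids`.
#' @export
kernel_basis <- function(model, tol = 1e-10) {
  S <- if (inherits(model, "metabolic_model")) model$S else as.matrix(model)
  rids <- if (inherits(model, "metabolic_model")) model$reaction_ids
          else colnames(S)
  N <- ncol(S)
  if (nrow(S) == 0 || all(S == 0)) {
    K <- diag(N)
    r <- 0L
  } else {
    sv <- svd(S, nu = 0, nv = N)
    thr <- tol * max(sv$d)
    r <- sum(sv$d > thr)
    K <- sv$v[, seq_len(N) > r, drop = FALSE]
  }
  structure(
    list(K = K, d = N - r, rank = r, sv_tolerance = tol,
         reaction_ids = rids),
    class = "kernel_basis"
  )
}

#' @export
print.kernel_basis <- function(x, ...) {
  cat(sprintf("kernel_basis: rank %d, kernel dimension %d (N = %d)\n",
              x$rank, x$d, nrow(x$K)))
  invisible(x)
}

## Geometry of the sampling problem: reactions pinned to a point
## (v_inf == v_sup) are equalities, not box constraints, so they join the
## stoichiometric rows before the null space is taken. Otherwise the pinned
## face is invisible to the null-space parameterization and chains freeze
## or degenerate on it.
polytope_geometry <- function(model, mdot = NULL) {
  M <- length(model$metabolite_ids)
  N <- length(model$reaction_ids)
  if (is.null(mdot)) mdot <- numeric(M)
  pinned <- which(model$v_inf == model$v_sup)
  S_aug <- model$S
  rhs <- mdot
  if (length(pinned)) {
    E <- matrix(0, length(pinned), N)
    E[cbind(seq_along(pinned), pinned)] <- 1
    S_aug <- rbind(model$S, E)
    rhs <- c(mdot, model$v_inf[pinned])
  }
  kb <- kernel_basis(S_aug)
  kb$reaction_ids <- model$reaction_ids
  vp <- particular_solution(S_aug, rhs)
  list(kb = kb, vp = vp, mdot = mdot, pinned = pinned)
}

## Minimum-norm particular solution of S v = mdot (v_p = pinv(S) mdot).
particular_solution <- function(S, mdot) {
  if (nrow(S) == 0 || all(mdot == 0)) return(numeric(ncol(S)))
  sv <- svd(S)
  thr <- 1e-10 * max(sv$d)
  pos <- sv$d > thr
  vp <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], mdot)) / sv$d[pos])
  resid <- max(abs(S %*% vp - mdot))
  if (resid > 1e-8 * max(1, max(abs(mdot))))
    stop("mdot is not attainable: S v = mdot has no solution (residual ",
         format(resid), ")")
  as.numeric(vp)
}

#' Feasibility check and interior point for the flux polytope
#'
#' Phase-I feasibility solve: minimizes the squared box violation of
#' `v = v_p + K x` over the null-space coordinates `x` with L-BFGS-B. The
#' objective is convex and continuously differentiable, and its minimum is
#' zero exactly when the polytope is nonempty, in which case the minimizer
#' is returned as a feasible starting point for the samplers. After the
#' solve the point is nudged toward the box center to move it off any active
#' facet.
#'
#' @param model A [metabolic_model()].
#' @param mdot Metabolite input/output rates (defaults to steady state, 0).
#' @param geom Optional precomputed geometry (internal).
#' @param tol Feasibility tolerance on the residual box violation.
#' @return List with `feasible` (logical), `x0` (null-space coordinates of
#'   the feasible point), `v0` (the point itself) and `violation`.
#' @export
feasible_point <- function(model, mdot = NULL, geom = NULL, tol = 1e-7) {
  N <- length(model$reaction_ids)
  if (is.null(geom)) geom <- polytope_geometry(model, mdot)
  kb <- geom$kb
  vp <- geom$vp
  K <- kb$K
  lo <- model$v_inf
  hi <- model$v_sup
  ## finite surrogate bounds for the centering pass
  span <- max(hi[is.finite(hi)] - lo[is.finite(lo)], 1)
  lo_f <- ifelse(is.finite(lo), lo, -10 * span)
  hi_f <- ifelse(is.finite(hi), hi, 10 * span)
  mid <- (lo_f + hi_f) / 2

  obj <- function(x, target) {
    v <- vp + as.numeric(K %*% x)
    d <- pmax(lo - v, 0) + pmin(hi - v, 0)
    sum(d * d)
  }
  grad <- function(x, target) {
    v <- vp + as.numeric(K %*% x)
    r <- -2 * (pmax(lo - v, 0) + pmin(hi - v, 0))
    as.numeric(crossprod(K, r))
  }
  if (kb$d == 0) {
    viol <- sqrt(sum((pmax(lo - vp, 0) + pmin(hi - vp, 0))^2))
    return(list(feasible = viol <= tol, x0 = numeric(0), v0 = vp,
                violation = viol))
  }
  x0 <- as.numeric(crossprod(K, mid - vp))
  fit <- stats::optim(x0, fn = obj, gr = grad, target = mid,
                      method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 10))
  viol <- sqrt(fit$value)
  x <- fit$par
  feas <- viol <= tol
  if (feas) {
    ## pull toward the box center to leave the boundary (stays feasible:
    ## the target of the pull is a convex combination inside the box)
    x <- interior_nudge(x, vp, K, lo, hi, mid)
  }
  list(feasible = feas, x0 = x, v0 = vp + as.numeric(K %*% x),
       violation = viol)
}

## Move x part-way toward the projection of the box center onto the affine
## subspace while staying inside the box: line search on the segment.
interior_nudge <- function(x, vp, K, lo, hi, mid) {
  xc <- as.numeric(crossprod(K, mid - vp))
  dir <- xc - x
  if (sqrt(sum(dir^2)) < 1e-12) return(x)
  v <- vp + as.numeric(K %*% x)
  w <- as.numeric(K %*% dir)
  ## largest t in [0,1] with v + t w still in the box
  tmax <- 1
  nz <- abs(w) > 1e-14
  if (any(nz)) {
    t_hi <- ifelse(w > 0, (hi - v) / w, (lo - v) / w)
    tmax <- max(0, min(1, min(t_hi[nz], na.rm = TRUE)))
  }
  x + 0.5 * tmax * dir
}
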
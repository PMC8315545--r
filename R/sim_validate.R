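## Simulation study: can hidden fluxes be recovered from enzyme abundances?
##
## A hidden flux vector v_initial is drawn from the feasible space, enzyme
## abundances are computed from it through an assumed kinetic relationship
## (the inverse problem), and the prediction machinery is asked to recover
## v_initial from those abundances alone. Accuracy is the Pearson
## correlation between v_initial and v_predicted over all reactions.

#' Kinetic relations linking enzyme abundance to flux
#'
#' Computes per-reaction enzyme abundances from a flux vector under one of
#' four relations:
#' \describe{
#'   \item{hyperbolic}{`E_i = |v_i / (1 - v_i)|` -- the metabolic control
#'     formalism with unit coupling constants.}
#'   \item{linear}{`E_i = k_i |v_i|` with slopes `k_i ~ U(0.1, 3)` drawn
#'     once per reaction.}
#'   \item{hill}{`E_i = |v_i^n / (1 - v_i^n)|` with Hill coefficients `n_i`
#'     drawn per reaction from the admissible set (default `{2,3,4,5}`).}
#'   \item{identity}{`E_i = |v_i|` (noiseless exact-recovery check).}
#' }
#'
#' @param v Named length-`N` flux vector.
#' @param relation One of `"hyperbolic"`, `"linear"`, `"hill"`,
#'   `"identity"`.
#' @param seed Integer seed for the per-reaction draws of `k` / `n`.
#' @param reactions Optional subset of reaction names to compute (defaults
#'   to all of `v`).
#' @param k_range Slope interval for the linear relation.
#' @param hill_set Admissible Hill coefficients.
#' @param singular_tol Guard around the hyperbolic/Hill pole: every
#'   component must satisfy `|1 - v_i| >= singular_tol` (respectively
#'   `|1 - v_i^n|`); violations raise an error instructing the caller to
#'   resample the flux vector.
#' @return Named non-negative abundance vector over `reactions`.
#' @export
enzymes_from_fluxes <- function(v, relation = c("hyperbolic", "linear",
                                                "hill", "identity"),
                                seed = 1L, reactions = NULL,
                                k_range = c(0.1, 3),
                                hill_set = c(2, 3, 4, 5),
                                singular_tol = 1e-6) {
  relation <- match.arg(relation)
  if (is.null(names(v))) stop("flux vector must be named by reaction id")
  if (is.null(reactions)) reactions <- names(v)
  vi <- v[reactions]
  n <- length(vi)
  E <- switch(relation,
    identity = abs(vi),
    hyperbolic = {
      if (any(abs(1 - vi) < singular_tol))
        stop("flux vector too close to the hyperbolic singularity at v = 1; resample it")
      abs(vi / (1 - vi))
    },
    linear = {
      k <- with_seed(seed, stats::runif(n, k_range[1], k_range[2]))
      k * abs(vi)
    },
    hill = {
      ns <- with_seed(seed,
                      hill_set[sample.int(length(hill_set), n,
                                          replace = TRUE)])
      vn <- vi^ns
      if (any(abs(1 - vn) < singular_tol))
        stop("flux vector too close to the Hill singularity at v^n = 1; resample it")
      abs(vn / (1 - vn))
    }
  )
  stats::setNames(as.numeric(E), reactions)
}

#' Flux-recovery simulation experiment
#'
#' Per replicate: draws `N_s` feasible points plus one extra hidden vector
#' `v_initial` from the posterior, computes enzyme abundances on a random
#' subset of `N_obs` reactions through the chosen relation, predicts the
#' flux vector by minimizing `Z`, and records the Pearson correlation
#' between `v_initial` and `v_predicted` over **all** reactions (the goal
#' is predicting the unobserved ones). Hidden vectors violating the
#' hyperbolic/Hill singularity guard are resampled (up to 100 times).
#'
#' @param model A [metabolic_model()].
#' @param N_s Sampled points per replicate. May be a vector: each replicate
#'   then draws `max(N_s)` points once and evaluates every `N_s` value on
#'   the corresponding prefix (a paired design that isolates the effect of
#'   the number of sampled points from replicate-to-replicate noise).
#' @param N_obs Number of observed reactions, or `"all"`.
#' @param relation Kinetic relation tag (see [enzymes_from_fluxes()]).
#' @param replicates Number of replicates.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param posterior Optional prefitted `flux_posterior` (saves refitting).
#' @param ... Passed to [enzymes_from_fluxes()].
#' @return A data frame of recovery records: `replicate`, `N_s`, `N_obs`,
#'   `relation`, `pearson_r`, `seed`. Failed replicates are dropped with a
#'   warning naming them.
#' @export
recovery_experiment <- function(model, N_s = 1000, N_obs = "all",
                                relation = "hyperbolic", replicates = 10,
                                seed = 1L, posterior = NULL, ...) {
  if (is.null(posterior)) posterior <- ep_fit(model)
  N <- length(model$reaction_ids)
  n_obs <- if (identical(N_obs, "all")) N else as.integer(N_obs)
  stopifnot(n_obs >= 1, n_obs <= N, replicates >= 1, all(N_s >= 1))
  ns_grid <- sort(unique(as.integer(N_s)))
  ns_max <- max(ns_grid)
  out <- vector("list", replicates)
  failures <- character(0)
  for (r in seq_len(replicates)) {
    rs <- seed + r
    rec <- tryCatch({
      draw <- sample_posterior(posterior, ns_max + 1, seed = rs)
      v_init <- draw_valid_initial(posterior, draw$fluxes[ns_max + 1, ],
                                   relation, rs, ...)
      obs_rx <- with_seed(rs * 2 + 1,
                          sample(model$reaction_ids, n_obs))
      E <- enzymes_from_fluxes(v_init, relation, seed = rs,
                               reactions = obs_rx, ...)
      prof <- enzyme_profile(model, E)
      do.call(rbind, lapply(ns_grid, function(ns) {
        smp <- new_sample_set(draw$fluxes[seq_len(ns), , drop = FALSE],
                              draw$log_density[seq_len(ns)], rs, "ep")
        pred <- predict_fluxes(posterior, smp, prof)
        data.frame(replicate = r, N_s = ns, N_obs = n_obs,
                   relation = relation,
                   pearson_r = stats::cor(v_init, pred$v_predicted),
                   seed = rs, stringsAsFactors = FALSE)
      }))
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(rec)))
    } else out[[r]] <- rec
  }
  if (length(failures))
    warning("failed replicates skipped:\n  ",
            paste(failures, collapse = "\n  "))
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

## Redraw the hidden vector until it clears the singularity guards of the
## chosen relation (at most 100 extra draws).
draw_valid_initial <- function(posterior, v_init, relation, seed,
                               singular_tol = 1e-6, hill_set = c(2, 3, 4, 5),
                               ...) {
  ok <- function(v) {
    if (relation == "hyperbolic") all(abs(1 - v) >= singular_tol)
    else if (relation == "hill")
      all(abs(1 - outer(v, hill_set, `^`)) >= singular_tol)
    else TRUE
  }
  tries <- 0L
  while (!ok(v_init)) {
    tries <- tries + 1L
    if (tries > 100L)
      stop("could not draw a hidden flux vector clearing the singularity guard")
    v_init <- sample_posterior(posterior, 1, seed = seed + 1000L * tries,
                               burn_in = 50)$fluxes[1, ]
  }
  v_init
}

#' Incremental one-by-one protein inclusion
#'
#' Mirrors the incremental design for probing how the number of observed
#' proteins shapes recovery: proteins are added one at a time in a seeded
#' random order, and after each addition `Z` is re-minimized over the
#' *same* fixed sample set, recording the correlation between the hidden
#' vector and the prediction. Stability is expected once the number of
#' observed proteins exceeds the kernel dimension (the model's degrees of
#' freedom).
#'
#' @param model A [metabolic_model()].
#' @param N_s Size of the fixed sample set.
#' @param relation Kinetic relation tag.
#' @param seed Integer seed (drives the sample set, the hidden vector and
#'   the inclusion order).
#' @param order_seed Optional separate seed for the inclusion order
#'   (defaults to `seed`), letting several orders share one sample set.
#' @param samples,v_initial Optional precomputed fixed sample set and
#'   hidden vector (as returned in the attributes of a previous call),
#'   shared across orders.
#' @param posterior Optional prefitted posterior.
#' @param ... Passed to [enzymes_from_fluxes()].
#' @return A data frame with one row per inclusion step: `N_obs` (1..N),
#'   `reaction` (the reaction added at that step) and `pearson_r`.
#'   Attributes `samples` and `v_initial` carry the fixed inputs for reuse.
#' @export
incremental_inclusion <- function(model, N_s = 1000, relation = "hyperbolic",
                                  seed = 1L, order_seed = NULL,
                                  samples = NULL, v_initial = NULL,
                                  posterior = NULL, ...) {
  if (is.null(posterior)) posterior <- ep_fit(model)
  if (is.null(order_seed)) order_seed <- seed
  N <- length(model$reaction_ids)
  if (is.null(samples) || is.null(v_initial)) {
    draw <- sample_posterior(posterior, N_s + 1, seed = seed)
    v_initial <- draw_valid_initial(posterior, draw$fluxes[N_s + 1, ],
                                    relation, seed, ...)
    samples <- new_sample_set(draw$fluxes[seq_len(N_s), , drop = FALSE],
                              draw$log_density[seq_len(N_s)], seed, "ep")
  }
  E_all <- enzymes_from_fluxes(v_initial, relation, seed = seed,
                               reactions = model$reaction_ids, ...)
  ord <- with_seed(order_seed * 2 + 1, sample(model$reaction_ids))
  ## squared residual of every sample against every enzyme, accumulated in
  ## inclusion order; the density weight is shared by all prefixes
  D <- abs(samples$fluxes[, ord, drop = FALSE])
  D <- sweep(D, 2, E_all[ord])
  D <- D * D
  w <- exp(samples$log_density - max(samples$log_density))
  cum <- 0
  r <- numeric(N)
  for (i in seq_len(N)) {
    cum <- cum + D[, i]
    k <- which.min(cum / w)
    r[i] <- stats::cor(v_initial, samples$fluxes[k, ])
  }
  out <- data.frame(N_obs = seq_len(N), reaction = ord, pearson_r = r,
                    stringsAsFactors = FALSE)
  attr(out, "samples") <- samples
  attr(out, "v_initial") <- v_initial
  out
}

#' Summarize recovery records
#'
#' Five-number summary of the recovery correlation per
#' `(N_s, N_obs, relation)` group, in the shape of the usual boxplot
#' representation.
#'
#' @param records A nonempty data frame of recovery records (see
#'   [recovery_experiment()]).
#' @return A data frame with one row per group: `N_s`, `N_obs`, `relation`,
#'   `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
summarize_recovery <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("no recovery records to summarize")
  key <- interaction(records$N_s, records$N_obs, records$relation,
                     drop = TRUE)
  groups <- split(records, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    q <- stats::quantile(g$pearson_r, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(N_s = g$N_s[1], N_obs = g$N_obs[1], relation = g$relation[1],
               n = nrow(g), min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$relation, out$N_s, out$N_obs), ]
}
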
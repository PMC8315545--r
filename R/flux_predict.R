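## Selection of a unique flux vector from the sampled feasible space.
##
## Among N_s sampled feasible points v^(k) with posterior densities p_v^(k),
## the predicted flux vector minimizes
##   Z^(k) = (1 / p_v^(k)) * sum_{i in obs} (E_i - |v_i^(k)|)^2 ,
## the squared Euclidean distance between observed enzyme abundances and
## absolute flux values, inversely weighted by the posterior density.

#' Density-weighted distance between a flux vector and enzyme abundances
#'
#' Computes `Z = (1 / p_v) * sum_{i in obs} (E_i - |v_i|)^2`, where `p_v`
#' is the posterior density of the flux vector relative to the densest
#' point of its batch: `p_v = exp(log_p - log_p_max)`. Normalizing against
#' the batch maximum is a pure rescaling that keeps the exponential in
#' range without changing which sample attains the minimum.
#'
#' @param v Length-`N` flux vector (named by reaction, or in model order
#'   matching the profile's mask).
#' @param log_p Unnormalized log density of `v` (see [log_density()]).
#' @param enzymes An `enzyme_profile` with at least one observed reaction.
#' @param log_p_max Reference log density of the batch `v` belongs to
#'   (default 0, i.e. `log_p` is already relative).
#' @return The non-negative objective value.
#' @export
objective_Z <- function(v, log_p, enzymes, log_p_max = 0) {
  E <- enzymes$weightings
  if (length(E) == 0) stop("no observed enzymes")
  vi <- if (!is.null(names(v))) v[names(E)] else
    stop("flux vector must be named by reaction id")
  sum((E - abs(vi))^2) / exp(log_p - log_p_max)
}

#' Predict the flux vector best matching observed enzyme abundances
#'
#' Evaluates the objective `Z` for every sampled flux vector and returns
#' the row attaining the minimum (ties broken by lowest sample index).
#' Deterministic given its inputs.
#'
#' @param posterior A `flux_posterior` (provenance; densities are taken
#'   from the sample set).
#' @param samples A nonempty `sample_set` whose columns are named by
#'   reaction.
#' @param enzymes An `enzyme_profile` with at least one observed reaction
#'   present among the sample columns.
#' @return A `prediction_result`: list with `v_predicted` (named flux
#'   vector), `Z_value`, `sample_index`, `log_density_at_min`, `n_observed`.
#' @export
predict_fluxes <- function(posterior, samples, enzymes) {
  if (!inherits(samples, "sample_set") || nrow(samples$fluxes) == 0)
    stop("samples must be a nonempty sample_set")
  E <- enzymes$weightings
  if (length(E) == 0) stop("no observed enzymes")
  obs <- match(names(E), colnames(samples$fluxes))
  if (anyNA(obs))
    stop("enzyme profile references reactions absent from the samples: ",
         paste(names(E)[is.na(obs)], collapse = ", "))
  Z <- objective_Z_rows(samples, obs, E)
  k <- which.min(Z) # which.min returns the first (lowest-index) minimum
  structure(
    list(
      v_predicted = samples$fluxes[k, ],
      Z_value = Z[k],
      sample_index = k,
      log_density_at_min = samples$log_density[k],
      n_observed = length(E)
    ),
    class = "prediction_result"
  )
}

## Z for every row of a sample set: squared distance on the observed columns
## divided by the batch-stabilized density.
objective_Z_rows <- function(samples, obs_idx, E) {
  D <- abs(samples$fluxes[, obs_idx, drop = FALSE])
  D <- sweep(D, 2, E)          # |v_i| - E_i
  ss <- rowSums(D * D)
  lp <- samples$log_density
  ss / exp(lp - max(lp))
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: Z = %.6g at sample %d (N_obs = %d)\n",
              x$Z_value, x$sample_index, x$n_observed))
  invisible(x)
}

#' Predict fluxes for every sample of a proteomic dataset
#'
#' Batch driver for [predict_fluxes()]: for each sample column of the
#' abundance table, maps the proteome onto reaction weightings, conditions
#' the posterior on that sample's observed exchange fluxes (if any), draws
#' `N_s` feasible points with a per-sample seed derived as
#' `seed + column index`, and selects the minimum-`Z` flux vector. Samples
#' with no mapped reactions are recorded as failed and skipped, never
#' silently dropped.
#'
#' @param model A [metabolic_model()].
#' @param abundance_table Proteins-x-samples numeric matrix (rownames =
#'   protein ids) or path to a proteome TSV (see [read_proteome()]).
#' @param exchange_obs Optional per-sample observed exchange fluxes: a named
#'   list mapping sample ids to named lists `reaction_id = c(value, sigma)`.
#' @param N_s Number of feasible points sampled per sample column.
#' @param seed Base integer seed.
#' @param partial_and Passed to [map_proteome()].
#' @param ... Further arguments to [ep_fit()].
#' @return A list with `fluxes` (`N` reactions x n samples matrix, `NA`
#'   columns for failed samples) and `log` (per-sample data frame with
#'   `sample`, `Z`, `n_observed`, `sample_index`, `converged`, `status`).
#' @export
predict_dataset <- function(model, abundance_table, exchange_obs = NULL,
                            N_s = 10000, seed = 1L,
                            partial_and = c("drop", "min"), ...) {
  partial_and <- match.arg(partial_and)
  if (is.character(abundance_table))
    abundance_table <- read_proteome(abundance_table)
  abundance_table <- as.matrix(abundance_table)
  n_samp <- ncol(abundance_table)
  N <- length(model$reaction_ids)
  fluxes <- matrix(NA_real_, N, n_samp,
                   dimnames = list(model$reaction_ids,
                                   colnames(abundance_table)))
  log_df <- data.frame(
    sample = colnames(abundance_table) %||% character(0),
    Z = rep(NA_real_, n_samp), n_observed = rep(NA_integer_, n_samp),
    sample_index = rep(NA_integer_, n_samp),
    converged = rep(NA, n_samp),
    status = rep("", n_samp), stringsAsFactors = FALSE
  )
  if (n_samp == 0) {
    warning("abundance table has no sample columns; empty prediction")
    return(list(fluxes = fluxes, log = log_df))
  }
  base_post <- NULL
  for (s in seq_len(n_samp)) {
    sid <- colnames(abundance_table)[s]
    prof <- map_proteome(model, abundance_table, sample_id = sid,
                         partial_and = partial_and)
    if (length(prof$weightings) == 0) {
      log_df$status[s] <- "failed: no reactions mapped"
      next
    }
    obs <- if (!is.null(exchange_obs)) exchange_obs[[sid]] else NULL
    if (is.null(obs)) {
      if (is.null(base_post))
        base_post <- tryCatch(ep_fit(model, ...), error = function(e) e)
      post <- base_post
    } else {
      post <- tryCatch(ep_fit(model, observations = obs, ...),
                       error = function(e) e)
    }
    if (inherits(post, "error")) {
      log_df$status[s] <- paste("failed:", conditionMessage(post))
      next
    }
    smp <- sample_posterior(post, N_s, seed = seed + s)
    pred <- predict_fluxes(post, smp, prof)
    fluxes[, s] <- pred$v_predicted
    log_df$Z[s] <- pred$Z_value
    log_df$n_observed[s] <- pred$n_observed
    log_df$sample_index[s] <- pred$sample_index
    log_df$converged[s] <- post$converged
    log_df$status[s] <- "ok"
  }
  list(fluxes = fluxes, log = log_df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
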
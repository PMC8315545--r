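# Shared fixtures and independent oracles used across the test files.

toys <- toy_models()

# Independent brute-force GPR evaluator: direct min/sum recursion written
# against the rule semantics, not sharing code with evaluate_gpr().
brute_gpr <- function(expr, ab) {
  if (expr$op == "id") {
    if (expr$id %in% names(ab)) return(ab[[expr$id]])
    return(NA_real_)
  }
  vals <- vapply(expr$args, brute_gpr, numeric(1), ab = ab)
  if (expr$op == "and") {
    if (anyNA(vals)) return(NA_real_)
    return(min(vals))
  }
  if (all(is.na(vals))) return(NA_real_)
  sum(vals, na.rm = TRUE)
}

# Random GPR expression tree of bounded depth over a protein pool.
random_gpr_tree <- function(depth, pool) {
  if (depth == 0 || runif(1) < 0.35) {
    return(structure(list(op = "id", id = sample(pool, 1)),
                     class = "gpr_expression"))
  }
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  structure(list(op = op,
                 args = replicate(k, random_gpr_tree(depth - 1, pool),
                                  simplify = FALSE)),
            class = "gpr_expression")
}

# Batch-means Monte-Carlo standard error of a chain's column means,
# honest about autocorrelation.
batch_se <- function(X, n_batches = 50) {
  n <- nrow(X)
  size <- floor(n / n_batches)
  bm <- sapply(seq_len(n_batches), function(b) {
    colMeans(X[((b - 1) * size + 1):(b * size), , drop = FALSE])
  })
  if (is.null(dim(bm))) bm <- matrix(bm, nrow = 1)
  apply(bm, 1, stats::sd) / sqrt(n_batches)
}

# Deterministic small instance of the random model family.
small_random_model <- function(seed) {
  random_cbm(synthetic_spec(
    n_metabolites = 10, n_reactions = 16, n_pathways = 3, n_exchanges = 3,
    reversible_fraction = 0.2, bound_width = 1, seed = seed))
}
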
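# Null-space kernel, reaction angles, modular decomposition.

test_that("the chain kernel is one-dimensional along (1,1,1)/sqrt(3)", {
  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE)
  kb <- kernel_basis(S)
  expect_equal(kb$rank, 2)
  expect_equal(kb$d, 1)
  dir <- kb$K[, 1] * sign(kb$K[1, 1])
  expect_equal(dir, rep(1, 3) / sqrt(3), tolerance = 1e-12)
})

test_that("a square full-rank system has no degrees of freedom", {
  S <- matrix(c(2, 1, 0, 3), 2, 2)
  kb <- kernel_basis(S)
  expect_equal(kb$d, 0)
  expect_error(reaction_angles(kb), "no degrees of freedom")
})

test_that("rank and kernel dimension always partition N", {
  for (seed in 1:8) {
    m <- small_random_model(seed)
    kb <- kernel_basis(m)
    expect_equal(kb$rank + kb$d, length(m$reaction_ids))
    expect_lte(max(abs(m$S %*% kb$K)), 1e-8)
    expect_equal(crossprod(kb$K), diag(kb$d), tolerance = 1e-10)
  }
})

test_that("angles follow the acute-angle convention", {
  # three coupled reactions: all angles 0
  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE)
  ang <- reaction_angles(kernel_basis(S))
  expect_equal(max(abs(ang)), 0, tolerance = 1e-6)

  # orthogonal kernel rows: 90 degrees; anti-coupled rows: 0 degrees
  K <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  rownames(K) <- c("a", "b", "c")
  ang2 <- reaction_angles(K)
  expect_equal(ang2["a", "b"], 90)
  expect_equal(ang2["a", "c"], 0)
  expect_true(all(ang2 >= 0 & ang2 <= 90))
  expect_equal(unname(diag(ang2)), rep(0, 3))
})

test_that("determined reactions are flagged and pushed to 90 degrees", {
  K <- rbind(c(1, 0), c(0, 0), c(0, 1))
  rownames(K) <- c("a", "fixed", "b")
  ang <- reaction_angles(K)
  expect_equal(attr(ang, "determined"), 2L)
  expect_equal(ang["fixed", "a"], 90)
  decomp <- cluster_reactions(ang, n_modules = 2)
  expect_true(is.na(decomp$labels["fixed"]))
  expect_equal(decomp$determined, "fixed")
})

test_that("angle matrix is invariant to rotation of the kernel basis", {
  m <- toys$toy_central_carbon
  kb <- kernel_basis(m)
  ang1 <- reaction_angles(kb)
  withr::with_seed(2, {
    Q <- qr.Q(qr(matrix(rnorm(kb$d^2), kb$d)))
  })
  kb_rot <- kb
  kb_rot$K <- kb$K %*% Q
  ang2 <- reaction_angles(kb_rot)
  expect_equal(ang1, ang2, tolerance = 1e-8)
})

test_that("two orthogonal coupled blocks split into two clean modules", {
  K <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)) / 1
  rownames(K) <- c("a1", "a2", "b1", "b2")
  ang <- reaction_angles(K)
  decomp <- cluster_reactions(ang, n_modules = 2)
  expect_equal(decomp$labels[["a1"]], decomp$labels[["a2"]])
  expect_equal(decomp$labels[["b1"]], decomp$labels[["b2"]])
  expect_false(decomp$labels[["a1"]] == decomp$labels[["b1"]])

  # n_modules = N gives singletons; n_modules > N errors
  singles <- cluster_reactions(ang, n_modules = 4)
  expect_equal(sort(unique(singles$labels)), 1:4)
  expect_error(cluster_reactions(ang, n_modules = 5), "exceeds")
})

test_that("strictly coupled reactions always share a module", {
  for (seed in 1:5) {
    m <- small_random_model(seed)
    kb <- kernel_basis(m)
    ang <- reaction_angles(kb)
    cls <- protoflux:::coupled_classes(kb$K)
    for (k in c(2, 3, 4)) {
      decomp <- cluster_reactions(ang, n_modules = k)
      for (grp in cls$classes) {
        if (length(grp) > 1) {
          labs <- decomp$labels[grp]
          expect_equal(length(unique(labs)), 1)
        }
      }
    }
  }
})

test_that("planted pathways are recovered from the angle clustering", {
  skip_if_not_installed("mclust")
  # pathway membership concerns internal conversions; exchange reactions
  # are boundary fluxes and are excluded from the decomposition
  agreement <- sapply(1:20, function(seed) {
    m <- random_cbm(synthetic_spec(
      n_metabolites = 12, n_reactions = 20, n_pathways = 3,
      n_exchanges = 4, reversible_fraction = 0.2, bound_width = 1,
      seed = seed))
    truth <- attr(m, "pathways")
    ang <- reaction_angles(kernel_basis(m))
    int <- which(!m$exchange)
    ang_int <- ang[int, int]
    attr(ang_int, "determined") <- integer(0)
    decomp <- cluster_reactions(ang_int, n_modules = 3)
    mclust::adjustedRandIndex(truth[int], decomp$labels)
  })
  expect_gte(median(agreement), 0.8)
})

test_that("coverage_report tabulates observation spread over modules", {
  K <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  rownames(K) <- c("a1", "a2", "b1", "b2")
  decomp <- cluster_reactions(reaction_angles(K), n_modules = 2)

  all_obs <- coverage_report(decomp, c("a1", "a2", "b1", "b2"))
  expect_true(all(all_obs$fraction == 1))
  expect_false(any(all_obs$flag_uncovered))

  none <- coverage_report(decomp, character(0))
  expect_true(all(none$fraction == 0))
  expect_true(all(none$flag_uncovered))

  half <- coverage_report(decomp, c("a1", "a2"))
  expect_equal(sort(half$fraction), c(0, 1))
  expect_equal(sum(half$flag_uncovered), 1)

  expect_error(coverage_report(decomp, "zz"), "unknown reaction")
})

test_that("module dendrograms export as parseable Newick", {
  K <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  rownames(K) <- c("a1", "a2", "b1", "b2")
  decomp <- cluster_reactions(reaction_angles(K), n_modules = 2)
  nwk <- modules_newick(decomp)
  expect_match(nwk, "^\\(.*\\);$")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("a1", "a2", "b1", "b2"))
})
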
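test_that("candidate network assembly filters, dedups and symmetrizes", {
  cand <- assemble_candidate_network(
    data.frame(a = c("a", "b"), b = c("b", "c")), c("a", "b"))
  expect_equal(cand$proteins, c("a", "b"))
  expect_equal(nrow(cand$pairs), 1L)
  expect_equal(cand$neighbors$a, "b")
  expect_equal(cand$neighbors$b, "a")

  # self pairs vanish
  empty <- assemble_candidate_network(data.frame(a = "a", b = "a"), "a")
  expect_length(empty$proteins, 0L)

  # duplicates (in either orientation) are stored once
  dup <- assemble_candidate_network(
    data.frame(a = c("a", "b", "a"), b = c("b", "a", "b")), c("a", "b"))
  expect_equal(nrow(dup$pairs), 1L)

  # explicit universe keeps isolated proteins
  iso <- assemble_candidate_network(data.frame(a = "a", b = "b"),
                                    c("a", "b", "z"),
                                    proteins = c("a", "b", "z"))
  expect_equal(iso$neighbors$z, character(0))
})

test_that("constrained least squares respects the basal-level constraint", {
  # intercept-only, positive mean: exact
  f1 <- fit_constrained_lsq(NULL, c(3, 3, 3))
  expect_equal(f1$beta, 3)
  expect_equal(f1$rss, 0)

  # intercept-only, negative mean: constraint active
  f2 <- fit_constrained_lsq(NULL, c(-1, -1, -1))
  expect_equal(f2$beta, 0)
  expect_equal(f2$rss, 3)

  # exact proportionality through one interactor
  f3 <- fit_constrained_lsq(cbind(x = c(1, 2, 3)), c(2, 4, 6))
  expect_equal(unname(f3$alpha), 2)
  expect_equal(f3$beta, 0)
  expect_equal(f3$rss, 0, tolerance = 1e-12)

  # rank-deficient design warns and still returns a solution
  X <- cbind(x1 = c(1, 2, 3, 4), x2 = c(2, 4, 6, 8))
  expect_warning(f4 <- fit_constrained_lsq(X, c(1, 2, 3, 4)), "rank")
  expect_equal(f4$rss, 0, tolerance = 1e-12)
})

test_that("the order-selection criterion matches its closed form", {
  expect_equal(aic(4, 4, 0), 0)               # log(1)
  expect_equal(aic(4, 4, 1), 0.5)             # 2 * 1 / 4
  expect_equal(aic(10, 5, 2), log(2) + 4 / 5)
  expect_identical(aic(0, 10, 3), -Inf)
  expect_error(aic(-1, 10, 0), "nonnegative")
  # at fixed rss the criterion penalizes order linearly
  expect_true(all(diff(vapply(0:5, function(L) aic(7, 9, L), 0)) > 0))
})

test_that("stepwise selection recovers planted supports and no more", {
  set.seed(61)
  S <- 50L
  x1 <- rnorm(S)
  x2 <- rnorm(S)
  X <- cbind(a = x1, b = x2)

  # pure signal through one candidate
  fit <- stepwise_select(X, 2 * x1)
  expect_equal(fit$selected, "a")
  expect_equal(unname(fit$alpha), 2, tolerance = 1e-9)
  expect_identical(fit$aic, -Inf)

  # no signal: the response ignores every candidate
  fit0 <- stepwise_select(X, rep(5, S))
  expect_length(fit0$selected, 0L)
  expect_equal(fit0$beta, 5)

  # empty candidate set falls back to the intercept-only model
  fitn <- stepwise_select(NULL, c(1, 2, 3))
  expect_length(fitn$selected, 0L)
  expect_equal(fitn$beta, 2)

  # the model order never exceeds S - 2
  S2 <- 6L
  X2 <- matrix(rnorm(S2 * 10), S2, 10,
               dimnames = list(NULL, sprintf("c%02d", 1:10)))
  y2 <- rnorm(S2)
  expect_lte(length(stepwise_select(X2, y2)$selected), S2 - 2L)
})

test_that("stepwise AIC never loses to the trivial or saturated model", {
  set.seed(62)
  for (r in 1:10) {
    S <- 40L
    K <- 6L
    X <- matrix(rnorm(S * K), S, K, dimnames = list(NULL, paste0("c", 1:K)))
    k <- sample(0:3, 1)
    coefs <- if (k > 0) runif(k, 1, 3) else numeric(0)
    y <- 1 + (if (k > 0) X[, seq_len(k), drop = FALSE] %*% coefs else 0) +
      rnorm(S, 0, 0.5)
    fit <- stepwise_select(X, y)
    a0 <- fit_protein_model(X, y, selected = character(0))$aic
    afull <- fit_protein_model(X, y)$aic
    expect_lte(fit$aic, a0)
    expect_lte(fit$aic, afull)
  }
})

test_that("t-test pruning keeps exact signals and drops noise", {
  set.seed(63)
  S <- 30L
  X <- cbind(a = rnorm(S), b = rnorm(S))
  y <- 3 * X[, "a"] + 1

  # noise-free exact signal: p ~ 0, retained
  fit <- prune_by_ttest(stepwise_select(X, y), X, y)
  expect_equal(fit$selected, "a")
  expect_equal(unname(fit$pvalues), 0)

  # a vacuous threshold deletes nothing
  yn <- y + rnorm(S, 0, 0.5)
  fit_raw <- stepwise_select(X, yn)
  fit_keep <- prune_by_ttest(fit_raw, X, yn, alpha_level = 1.0)
  expect_identical(fit_keep$selected, fit_raw$selected)

  # forced-in null coefficients are deleted at about the nominal rate
  set.seed(64)
  deleted <- vapply(1:200, function(r) {
    Xn <- matrix(rnorm(23 * 3), 23, 3, dimnames = list(NULL, c("u", "v", "w")))
    yn <- rnorm(23, 2)
    f <- prune_by_ttest(fit_protein_model(Xn, yn), Xn, yn)
    1 - length(f$selected) / 3
  }, 0)
  expect_gte(mean(deleted), 0.9)
})

test_that("stage network assembly obeys its structural invariants", {
  tr <- generate_truth(30, 2, 0.5, seed = 65, noise_sd = 0.1,
                       mode = "layered")
  expr <- simulate_expression(tr, 60, seed = 66)
  cand <- assemble_candidate_network(tr$candidate_edges, rownames(expr))
  net <- build_stage_network(expr, cand)

  # no self interactions; support within the candidate pairs
  expect_true(all(net$edges$target != net$edges$interactor))
  expect_true(all(pair_key(net$edges$target, net$edges$interactor) %in%
                    pair_key(cand$pairs$a, cand$pairs$b)))
  # every retained coefficient passed the pruning test
  expect_true(all(net$edges$p_value < 0.05))
  # basal levels obey the constraint
  expect_true(all(net$beta >= 0))
  expect_identical(net$stage, "C")

  # isolated proteins get an intercept-only fit and no adjacency row
  cand_iso <- assemble_candidate_network(
    tr$candidate_edges, rownames(expr),
    proteins = c(cand$proteins, setdiff(rownames(expr), cand$proteins)))
  iso_ids <- setdiff(cand_iso$proteins, unique(c(cand$pairs$a, cand$pairs$b)))
  if (length(iso_ids) > 0L) {
    net_iso <- build_stage_network(expr, cand_iso)
    expect_false(any(net_iso$edges$target %in% iso_ids))
    i <- iso_ids[1L]
    expect_equal(net_iso$beta[[i]], max(mean(expr[i, ]), 0))
  }

  # missing proteins in the expression matrix are an error
  expect_error(build_stage_network(expr[-1, ], cand), "lacks")
})
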
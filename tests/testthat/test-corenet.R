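make_net <- function(A, stage = "C") {
  ids <- sprintf("P%04d", seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  nz <- which(A != 0, arr.ind = TRUE)
  structure(list(proteins = ids,
                 edges = data.frame(target = ids[nz[, 1]],
                                    interactor = ids[nz[, 2]],
                                    alpha = A[nz], stringsAsFactors = FALSE),
                 beta = stats::setNames(seq_len(nrow(A)), ids),
                 fits = NULL, stage = stage),
            class = "stage_network")
}

test_that("eigen-decomposition energies and mode counts are exact", {
  # identity: flat spectrum, all three modes needed for 85%
  eid <- eigen_decompose(make_net(diag(3)))
  expect_equal(eid$singular_values, rep(1, 3))
  expect_equal(eid$energy_fractions, rep(100 / 3, 3))
  expect_equal(eid$n_principal, 3L)

  # diag(3, 1): energies 90% and 10%, one principal mode
  ed <- eigen_decompose(make_net(diag(c(3, 1))))
  expect_equal(ed$energy_fractions, c(90, 10))
  expect_equal(ed$n_principal, 1L)

  # rank-1 network: a single mode carries all energy
  er1 <- eigen_decompose(make_net(outer(c(1, 2), c(0, 1))))
  expect_equal(er1$energy_fractions[1], 100)
  expect_equal(er1$n_principal, 1L)

  expect_error(eigen_decompose(make_net(matrix(0, 3, 3))), "all zero")
})

test_that("the decomposition reconstructs the network and K is minimal", {
  net <- random_stage_network(50, 400, seed = 81)
  eig <- eigen_decompose(net)
  N <- stagenet:::network_matrix(net)

  recon <- eig$left %*% diag(eig$singular_values) %*%
    t(eig$eigen_interactions)
  expect_lt(max(abs(recon - N)), 1e-9)
  expect_lt(abs(sum(eig$energy_fractions) - 100), 1e-6)

  cum <- cumsum(eig$energy_fractions)
  K <- eig$n_principal
  expect_gte(cum[K], 85 - 1e-9)
  if (K > 1L) expect_lt(cum[K - 1L], 85)
})

test_that("similarity is the projection norm onto the principal modes", {
  net <- random_stage_network(8, 30, seed = 82)
  eig <- eigen_decompose(net)
  sim <- protein_similarity(net, eig)

  # independent dense oracle: explicit inner products with each mode
  N <- stagenet:::network_matrix(net)
  for (i in seq_len(8)) {
    coords <- vapply(seq_len(eig$n_principal), function(j) {
      sum(N[i, ] * eig$eigen_interactions[, j])
    }, 0)
    expect_equal(sim[[net$proteins[i]]], sqrt(sum(coords^2)),
                 tolerance = 1e-10)
  }

  # a protein with no outgoing interaction row has zero similarity
  net0 <- net
  net0$edges <- net0$edges[net0$edges$target != "P0001", ]
  eig0 <- eigen_decompose(net0)
  expect_equal(protein_similarity(net0, eig0)[["P0001"]], 0)

  # keeping all modes recovers the row norms exactly (orthonormality)
  eig_all <- eigen_decompose(net, energy_threshold = 100)
  expect_equal(eig_all$n_principal, 8L)
  sim_all <- protein_similarity(net, eig_all)
  expect_equal(unname(sim_all), unname(sqrt(rowSums(N^2))),
               tolerance = 1e-10)

  # scale covariance: scaling the network scales every similarity
  net3 <- net
  net3$edges$alpha <- 3 * net3$edges$alpha
  eig3 <- eigen_decompose(net3)
  expect_equal(unname(protein_similarity(net3, eig3)), unname(3 * sim),
               tolerance = 1e-9)

  # the max-inner-product variant is bounded by the 2-norm aggregate
  expect_true(all(protein_similarity(net, eig, method = "max") <= sim + 1e-12))
})

test_that("core selection is strict and nested under the threshold", {
  expect_identical(select_core(c(a = 6.0, b = 6.01), 6), "b")
  expect_length(select_core(c(a = 1, b = 2), 5), 0L)
  expect_identical(select_core(c(a = 1, b = 2), -1), c("a", "b"))

  net <- random_stage_network(40, 250, seed = 83)
  eig <- eigen_decompose(net)
  sim <- protein_similarity(net, eig)
  thresholds <- sort(unname(sim))
  cores <- lapply(thresholds, function(th) select_core(sim, th))
  for (j in seq_len(length(cores) - 1L)) {
    expect_true(all(cores[[j + 1L]] %in% cores[[j]]))
  }
})

test_that("core networks are induced subgraphs with carried attributes", {
  net <- random_stage_network(10, 40, seed = 84)

  full <- core_network(net, net$proteins)
  expect_equal(full$edges[order(full$edges$target, full$edges$interactor), ],
               net$edges[order(net$edges$target, net$edges$interactor), ],
               ignore_attr = TRUE)

  none <- core_network(net, character(0))
  expect_length(none$proteins, 0L)
  expect_equal(nrow(none$edges), 0L)

  # edges leaving the core are dropped, betas of core proteins retained
  two <- core_network(net, c("P0001", "P0002"))
  expect_true(all(two$edges$target %in% two$proteins &
                    two$edges$interactor %in% two$proteins))
  expect_equal(two$beta, net$beta[c("P0001", "P0002")])

  expect_error(core_network(net, "missing"), "belong")
})

test_that("regulation-candidate flagging partitions the large-shift set", {
  n1 <- random_stage_network(10, 30, seed = 85, stage = "C")
  n2 <- random_stage_network(10, 30, seed = 86, stage = "I")
  n2$beta <- n1$beta + c(2, -2, rep(0.1, 8))
  names(n2$beta) <- names(n1$beta)
  d <- differential_network(n2, n1)
  targets <- list(P0001 = c("miR-21", "miR-146a"))

  flags <- flag_regulation_candidates(d, targets, beta_change_min = 1)
  expect_equal(flags$mirna_candidates$protein, "P0001")
  expect_equal(flags$mirna_candidates$direction, "elevated")
  expect_equal(flags$mirna_candidates$mirnas, "miR-21,miR-146a")
  expect_equal(flags$methylation_candidates$protein, "P0002")
  expect_equal(flags$methylation_candidates$direction, "lowered")

  # partition property: disjoint, and together exactly the large-shift set
  big <- names(d$node_delta)[abs(d$node_delta) >= 1]
  expect_length(intersect(flags$mirna_candidates$protein,
                          flags$methylation_candidates$protein), 0L)
  expect_setequal(c(flags$mirna_candidates$protein,
                    flags$methylation_candidates$protein), big)

  # threshold beyond every shift: both sets empty
  none <- flag_regulation_candidates(d, targets, beta_change_min = 10)
  expect_equal(nrow(none$mirna_candidates), 0L)
  expect_equal(nrow(none$methylation_candidates), 0L)
})
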
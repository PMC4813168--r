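#' Generate a ground-truth interaction network for benchmarking
#'
#' Creates a sparse true interaction network (activities \eqn{\alpha_{ik}},
#' basal levels \eqn{\beta_i \ge 0}) embedded in a larger undirected candidate
#' network that additionally contains decoy pairs, emulating the false-positive
#' interactions that database-mined candidate sets carry.
#'
#' Two wiring modes are available:
#' \describe{
#'   \item{\code{"cyclic"}}{every protein receives about \code{true_degree}
#'     incoming interactions from uniformly chosen partners; the activity
#'     matrix is globally rescaled so its spectral radius is at most
#'     \code{max_radius}, keeping the simulated expression fixed point well
#'     defined. Sample-to-sample variation then comes from the per-protein
#'     stochastic term alone.}
#'   \item{\code{"layered"}}{proteins split into drivers (first half), whose
#'     levels vary exogenously across samples with standard deviation
#'     \code{signal_sd}, and responders, each receiving exactly
#'     \code{true_degree} incoming interactions from drivers. Responder
#'     equations carry noise with standard deviation \code{noise_sd}, so
#'     \code{noise_sd = 0} yields exactly identifiable noise-free interaction
#'     equations while the data still vary across samples. This is the mode
#'     used by the recovery benchmarks.}
#' }
#'
#' @param n_proteins number of proteins (>= 2).
#' @param true_degree incoming true interactions per (responder) protein.
#' @param candidate_excess decoy candidate pairs as a multiple of the number
#'   of true directed edges; decoys are drawn uniformly from non-candidate
#'   pairs.
#' @param seed integer seed; identical arguments give identical output.
#' @param noise_sd standard deviation of the per-protein stochastic term
#'   (responder equations in layered mode).
#' @param signal_sd standard deviation of driver-protein variation (layered
#'   mode only).
#' @param mode `"cyclic"` (default) or `"layered"`; see Details.
#' @param alpha_sd standard deviation of the raw activity draws.
#' @param beta_sd scale of the half-normal basal-level draws.
#' @param max_radius spectral-radius bound enforced on the activity matrix.
#' @return an object of class `synthetic_truth`: list with `protein_ids`,
#'   `candidate_edges` (two-column data frame of unordered pairs),
#'   `alpha` (data frame `target`, `interactor`, `alpha`), `beta` (named
#'   nonnegative vector), `noise_sd` (named per-protein vector), `mode`,
#'   `seed`.
#' @export
generate_truth <- function(n_proteins, true_degree, candidate_excess, seed,
                           noise_sd = 0.1, signal_sd = 1,
                           mode = c("cyclic", "layered"),
                           alpha_sd = 1, beta_sd = 1, max_radius = 0.8) {
  mode <- match.arg(mode)
  if (n_proteins < 2L) stop("n_proteins must be at least 2")
  if (true_degree < 0L || true_degree >= n_proteins)
    stop("true_degree must be in [0, n_proteins - 1]")
  if (candidate_excess < 0) stop("candidate_excess must be nonnegative")
  if (noise_sd < 0 || signal_sd < 0) stop("noise scales must be nonnegative")
  ids <- sprintf("P%04d", seq_len(n_proteins))

  with_seed(seed, {
    target <- character(0)
    interactor <- character(0)
    if (mode == "cyclic") {
      if (true_degree > 0L) {
        for (i in seq_len(n_proteins)) {
          ks <- sample(setdiff(seq_len(n_proteins), i), true_degree)
          target <- c(target, rep(ids[i], true_degree))
          interactor <- c(interactor, ids[ks])
        }
      }
      noise <- stats::setNames(rep(noise_sd, n_proteins), ids)
    } else {
      n_drivers <- ceiling(n_proteins / 2)
      if (true_degree > n_drivers)
        stop("layered mode requires true_degree <= number of drivers (",
             n_drivers, ")")
      if (true_degree > 0L && n_proteins > n_drivers) {
        for (i in seq(n_drivers + 1L, n_proteins)) {
          ks <- sample(seq_len(n_drivers), true_degree)
          target <- c(target, rep(ids[i], true_degree))
          interactor <- c(interactor, ids[ks])
        }
      }
      noise <- stats::setNames(
        c(rep(signal_sd, n_drivers), rep(noise_sd, n_proteins - n_drivers)),
        ids)
    }
    alpha <- data.frame(target = target, interactor = interactor,
                        alpha = stats::rnorm(length(target), 0, alpha_sd),
                        stringsAsFactors = FALSE)

    A <- interaction_matrix(ids, alpha)
    rho <- spectral_radius(A)
    if (rho > max_radius) alpha$alpha <- alpha$alpha * (max_radius / rho)

    beta <- stats::setNames(abs(stats::rnorm(n_proteins, 0, beta_sd)), ids)

    true_pairs <- if (nrow(alpha) > 0L) {
      canonical_pairs(alpha$target, alpha$interactor)
    } else {
      data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
    }
    n_decoy <- round(candidate_excess * nrow(alpha))
    all_possible <- choose(n_proteins, 2)
    if (nrow(true_pairs) + n_decoy > all_possible)
      stop("requested candidate network exceeds the number of distinct pairs")
    if (n_decoy > 0L) {
      combs <- utils::combn(n_proteins, 2)
      keys <- pair_key(ids[combs[1, ]], ids[combs[2, ]])
      free <- which(!(keys %in% pair_key(true_pairs$a, true_pairs$b)))
      pick <- sample(free, n_decoy)
      decoys <- data.frame(a = ids[combs[1, pick]], b = ids[combs[2, pick]],
                           stringsAsFactors = FALSE)
      candidate_edges <- rbind(true_pairs, decoys)
    } else {
      candidate_edges <- true_pairs
    }
    candidate_edges <-
      candidate_edges[order(candidate_edges$a, candidate_edges$b), ,
                      drop = FALSE]
    rownames(candidate_edges) <- NULL

    structure(list(protein_ids = ids,
                   candidate_edges = candidate_edges,
                   alpha = alpha,
                   beta = beta,
                   noise_sd = noise,
                   mode = mode,
                   seed = seed),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic interaction-network truth (", x$mode, " mode)\n", sep = "")
  cat("  proteins:        ", length(x$protein_ids), "\n", sep = "")
  cat("  true edges:      ", nrow(x$alpha), "\n", sep = "")
  cat("  candidate pairs: ", nrow(x$candidate_edges), "\n", sep = "")
  invisible(x)
}

#' Simulate an expression matrix from a ground-truth network
#'
#' Closes the interaction model into a generative law: per sample \eqn{m},
#' \deqn{y(m) = (I - A)^{-1} (\beta + \epsilon(m))}
#' with \eqn{\epsilon_i(m)} independent Gaussian with per-protein standard
#' deviation `truth$noise_sd`, so every sample satisfies
#' \eqn{y = A y + \beta + \epsilon} exactly.
#'
#' @param truth a `synthetic_truth` object.
#' @param n_samples number of samples (columns).
#' @param seed integer seed.
#' @param stage stage label attached to the result (attribute `"stage"`).
#' @return numeric matrix (proteins x samples) with an attached `"stage"`
#'   attribute.
#' @export
simulate_expression <- function(truth, n_samples, seed, stage = "C") {
  stopifnot(inherits(truth, "synthetic_truth"), n_samples >= 1L)
  ids <- truth$protein_ids
  P <- length(ids)
  A <- interaction_matrix(ids, truth$alpha)
  if (spectral_radius(A) >= 1)
    stop("spectral radius of the activity matrix is >= 1; ",
         "the expression fixed point is undefined")
  sd_vec <- rep_len(truth$noise_sd, P)
  Y <- with_seed(seed, {
    eps <- matrix(stats::rnorm(P * n_samples, 0, sd_vec), P, n_samples)
    solve(diag(P) - A, truth$beta + eps)
  })
  dimnames(Y) <- list(ids, sprintf("S%03d", seq_len(n_samples)))
  attr(Y, "stage") <- stage
  Y
}

#' Perturb a ground-truth network into a later-stage truth
#'
#' Removes a fixed fraction of the true edges and shifts a fixed fraction of
#' the basal levels, leaving the candidate pair set unchanged, so that
#' stage-to-stage differential networks have a known answer. Exactly
#' `floor(edge_change_frac * n_edges)` edges and
#' `floor(beta_change_frac * n_proteins)` basal levels differ from the input.
#'
#' @param truth a `synthetic_truth` object.
#' @param edge_change_frac fraction of true edges to remove, in \[0, 1\].
#' @param beta_change_frac fraction of basal levels to shift, in \[0, 1\].
#' @param seed integer seed.
#' @param max_radius spectral-radius bound re-enforced after perturbation.
#' @return a perturbed `synthetic_truth`.
#' @export
perturb_truth <- function(truth, edge_change_frac, beta_change_frac, seed,
                          max_radius = 0.8) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (edge_change_frac < 0 || edge_change_frac > 1 ||
      beta_change_frac < 0 || beta_change_frac > 1)
    stop("change fractions must lie in [0, 1]")
  out <- truth
  with_seed(seed, {
    n_drop <- floor(edge_change_frac * nrow(truth$alpha))
    if (n_drop > 0L) {
      drop <- sample(nrow(truth$alpha), n_drop)
      out$alpha <- truth$alpha[-drop, , drop = FALSE]
      rownames(out$alpha) <- NULL
    }
    n_shift <- floor(beta_change_frac * length(truth$beta))
    if (n_shift > 0L) {
      idx <- sample(length(truth$beta), n_shift)
      delta <- stats::runif(n_shift, 0.5, 1.5) *
        sample(c(-1, 1), n_shift, replace = TRUE)
      shifted <- truth$beta[idx] + delta
      # clamping at zero must still change the value
      bad <- shifted < 0 | shifted == truth$beta[idx]
      shifted[bad] <- truth$beta[idx][bad] + abs(delta[bad])
      out$beta[idx] <- shifted
    }
    A <- interaction_matrix(out$protein_ids, out$alpha)
    rho <- spectral_radius(A)
    # edge removal leaves the radius below the bound in practice; a global
    # rescale is the safety net for pathological sign patterns (with a small
    # tolerance so a radius already at the bound is left untouched)
    if (rho > max_radius * (1 + 1e-10))
      out$alpha$alpha <- out$alpha$alpha * (max_radius / rho)
  })
  out
}

#' Generate a synthetic function-annotation catalog
#'
#' Stands in for a pathway/function classification catalog: overlapping random
#' membership sets over the truth's proteins, each function tagged with one of
#' the four biological-significance groups used to colour functional networks
#' (immune, neuro/hormone, growth/death, general).
#'
#' Each protein joins each function independently with probability
#' `mean_size / n_proteins`, so the expected set size is `mean_size` and
#' `mean_size = n_proteins` yields full membership; empty sets are repaired
#' with one random member.
#'
#' @param truth a `synthetic_truth` object.
#' @param n_functions number of functions (>= 1).
#' @param mean_size expected members per function (<= number of proteins).
#' @param seed integer seed.
#' @return an object of class `function_catalog`: named list of protein-id
#'   character vectors with a `"groups"` attribute (named character vector).
#' @export
generate_function_catalog <- function(truth, n_functions, mean_size, seed) {
  stopifnot(inherits(truth, "synthetic_truth"), n_functions >= 1L)
  ids <- truth$protein_ids
  P <- length(ids)
  if (mean_size > P) stop("mean_size cannot exceed the number of proteins")
  if (mean_size < 1) stop("mean_size must be at least 1")
  groups_palette <- c("immune", "neuro/hormone", "growth/death", "general")
  with_seed(seed, {
    prob <- mean_size / P
    sets <- vector("list", n_functions)
    for (f in seq_len(n_functions)) {
      members <- ids[stats::runif(P) < prob]
      if (length(members) == 0L) members <- sample(ids, 1L)
      sets[[f]] <- members
    }
    names(sets) <- sprintf("F%03d", seq_len(n_functions))
    groups <- stats::setNames(
      sample(groups_palette, n_functions, replace = TRUE), names(sets))
    structure(sets, groups = groups, class = "function_catalog")
  })
}

#' @export
print.function_catalog <- function(x, ...) {
  cat("Function catalog: ", length(x), " functions, mean size ",
      round(mean(lengths(x)), 1), "\n", sep = "")
  invisible(x)
}

#' Serialize a ground truth to JSON (for test oracles and provenance)
#'
#' @param truth a `synthetic_truth` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(
    list(protein_ids = truth$protein_ids,
         candidate_edges = truth$candidate_edges,
         alpha = truth$alpha,
         beta = as.list(truth$beta),
         noise_sd = as.list(truth$noise_sd),
         mode = truth$mode,
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
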
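# Dense adjacency of a stage (or core) network: rows are target profiles
# (alpha_i1 ... alpha_iP), columns interactors.
network_matrix <- function(net) {
  interaction_matrix(net$proteins, net$edges)
}

#' Eigen-interactions of a stage network
#'
#' Singular value decomposition \eqn{N = U \Sigma V^\top} of the dense
#' adjacency matrix. The right singular vectors (columns of V) are the
#' eigen-interactions; the energy fraction of the i-th mode is
#' \eqn{r_i = \sigma_i^2 / \sum_j \sigma_j^2 \times 100\%}, and the number of
#' principal modes K is the smallest count whose cumulative energy reaches
#' `energy_threshold` (85% by default, the usual principal-component
#' convention).
#'
#' @param net a `stage_network` (or `core_network`) with at least one edge.
#' @param energy_threshold cumulative-energy cutoff in percent.
#' @return an object of class `eigen_decomposition`: list with
#'   `singular_values` (descending), `eigen_interactions` (columns of V),
#'   `left` (U), `energy_fractions` (percent, summing to 100),
#'   `n_principal` (K) and `proteins`.
#' @export
eigen_decompose <- function(net, energy_threshold = 85.0) {
  N <- network_matrix(net)
  if (all(N == 0)) stop("the network adjacency is all zero; no structure")
  sv <- svd(N)
  r <- 100 * sv$d^2 / sum(sv$d^2)
  cum <- cumsum(r)
  K <- which(cum >= energy_threshold - 1e-9)[1L]
  if (is.na(K)) K <- length(r)
  structure(list(singular_values = sv$d,
                 eigen_interactions = sv$v,
                 left = sv$u,
                 energy_fractions = r,
                 n_principal = K,
                 energy_threshold = energy_threshold,
                 proteins = net$proteins),
            class = "eigen_decomposition")
}

#' @export
print.eigen_decomposition <- function(x, ...) {
  cat("Eigen-decomposition: ", length(x$singular_values), " modes, K = ",
      x$n_principal, " principal (>= ", x$energy_threshold, "% energy)\n",
      sep = "")
  invisible(x)
}

#' Similarity of protein interaction profiles to the principal modes
#'
#' Projects each protein's interaction row \eqn{(\alpha_{i1} \cdots
#' \alpha_{iP})} onto the K principal eigen-interactions. The default
#' similarity is the 2-norm of the K projection coefficients, which by
#' orthonormality equals the full row norm when K = P; `method = "max"`
#' scores the largest absolute single-mode inner product instead.
#'
#' Similarities scale linearly with the network weights, so a fixed
#' similarity threshold is meaningful only relative to the data scale.
#'
#' @param net the network the decomposition was computed from.
#' @param eig an `eigen_decomposition` of `net`.
#' @param method `"l2"` (default) or `"max"`.
#' @return named nonnegative numeric vector over the network's proteins.
#' @export
protein_similarity <- function(net, eig, method = c("l2", "max")) {
  method <- match.arg(method)
  stopifnot(inherits(eig, "eigen_decomposition"))
  if (!identical(eig$proteins, net$proteins))
    stop("the decomposition was not computed from this network")
  N <- network_matrix(net)
  V <- eig$eigen_interactions[, seq_len(eig$n_principal), drop = FALSE]
  proj <- N %*% V
  sim <- switch(method,
                l2 = sqrt(rowSums(proj^2)),
                max = apply(abs(proj), 1L, max))
  stats::setNames(as.numeric(sim), net$proteins)
}

#' Select core proteins by similarity threshold
#'
#' Keeps proteins whose similarity strictly exceeds the threshold (default 6,
#' a data-scale-dependent choice tuned to the size of the resulting core
#' networks).
#'
#' @param similarity named similarity vector from [protein_similarity()].
#' @param threshold strict lower cutoff.
#' @return character vector of core protein ids.
#' @export
select_core <- function(similarity, threshold = 6.0) {
  names(similarity)[similarity > threshold]
}

#' Induced core network
#'
#' Restricts a stage network to the core proteins: the adjacency keeps the
#' interactions with both endpoints in the core, and basal levels (and
#' similarities, when given) are carried over for the core proteins.
#'
#' @param net a `stage_network`.
#' @param core character vector of core proteins (subset of `net$proteins`).
#' @param similarity optional named similarity vector to attach.
#' @return an object of class `core_network`: list with `proteins`, `edges`,
#'   `beta`, `similarity` and `stage`.
#' @export
core_network <- function(net, core, similarity = NULL) {
  stopifnot(inherits(net, "stage_network"))
  core <- sort(unique(as.character(core)))
  if (!all(core %in% net$proteins))
    stop("core proteins must belong to the network")
  keep <- net$edges$target %in% core & net$edges$interactor %in% core
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(proteins = core,
                 edges = edges,
                 beta = net$beta[core],
                 similarity = if (!is.null(similarity)) similarity[core],
                 stage = net$stage),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  cat("Core network", if (!is.na(x$stage)) paste0(" [", x$stage, "]"),
      ": ", length(x$proteins), " core proteins, ", nrow(x$edges),
      " interactions\n", sep = "")
  invisible(x)
}

#' Flag candidate miRNA- versus methylation-regulated proteins
#'
#' Among the proteins whose basal level changed by at least `beta_change_min`
#' between the two stages of a differential (core) network, those with a
#' known miRNA targeting them are flagged as candidate miRNA regulations and
#' the remainder as candidate methylation regulations, each with the
#' direction of the basal-level change.
#'
#' @param diff a `differential_network` carrying `node_delta`.
#' @param mirna_targets protein-to-miRNA map: either a named list of miRNA id
#'   vectors or a two-column data frame (protein, miRNA).
#' @param beta_change_min minimum absolute basal-level change.
#' @return list with data frames `mirna_candidates` (protein, delta_beta,
#'   direction, mirnas) and `methylation_candidates` (protein, delta_beta,
#'   direction); the two sets partition the large-change proteins.
#' @export
flag_regulation_candidates <- function(diff, mirna_targets, beta_change_min) {
  stopifnot(inherits(diff, "differential_network"))
  if (is.null(diff$node_delta))
    stop("the differential network carries no basal-level changes")
  if (is.data.frame(mirna_targets)) {
    mirna_targets <- split(as.character(mirna_targets[[2L]]),
                           as.character(mirna_targets[[1L]]))
  }
  nd <- diff$node_delta
  big <- names(nd)[abs(nd) >= beta_change_min]
  direction <- ifelse(nd[big] > 0, "elevated", "lowered")
  is_mirna <- big %in% names(mirna_targets)
  mirna <- data.frame(
    protein = big[is_mirna],
    delta_beta = unname(nd[big[is_mirna]]),
    direction = unname(direction[is_mirna]),
    mirnas = vapply(big[is_mirna],
                    function(p) paste(mirna_targets[[p]], collapse = ","),
                    character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  methyl <- data.frame(
    protein = big[!is_mirna],
    delta_beta = unname(nd[big[!is_mirna]]),
    direction = unname(direction[!is_mirna]),
    stringsAsFactors = FALSE)
  list(mirna_candidates = mirna, methylation_candidates = methyl)
}
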
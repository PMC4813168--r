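#' Over-representation test for catalog functions in a network
#'
#' One-sided hypergeometric test per catalog function: are its members
#' over-represented among the network proteins relative to the measured
#' background? P-values are corrected by Benjamini-Hochberg and functions
#' passing the FDR threshold are returned. A user-supplied enriched-function
#' list can bypass this test entirely in downstream calls, since the choice
#' of enrichment statistic is a convention rather than part of the network
#' model.
#'
#' @param network_proteins character vector of proteins in the constructed
#'   network (the foreground).
#' @param catalog a `function_catalog` (named list of member id vectors).
#' @param background character vector of all measured proteins; must contain
#'   the foreground.
#' @param fdr Benjamini-Hochberg threshold (default 0.05).
#' @return character vector of enriched function names, with a `"stats"`
#'   attribute: data frame of per-function overlap counts and (adjusted)
#'   p-values.
#' @export
enrich_functions <- function(network_proteins, catalog, background,
                             fdr = 0.05) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("background set is empty")
  network_proteins <- unique(as.character(network_proteins))
  if (!all(network_proteins %in% background))
    stop("background must contain every network protein")
  n <- length(network_proteins)
  N <- length(background)
  stats_df <- do.call(rbind, lapply(names(catalog), function(f) {
    members <- intersect(catalog[[f]], background)
    K <- length(members)
    k <- length(intersect(members, network_proteins))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(fun = f, members = K, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  }))
  stats_df$p_adjusted <- stats::p.adjust(stats_df$p_value, method = "BH")
  enriched <- stats_df$fun[stats_df$p_adjusted <= fdr & stats_df$members > 0L]
  attr(enriched, "stats") <- stats_df
  enriched
}

#' Aggregate a stage network into a functional network
#'
#' The interaction activity between two enriched functions is the sum of the
#' interaction activities between their member proteins: for functions f and
#' g, every directed edge (i, k) with i in f and k in g contributes its
#' \eqn{\alpha_{ik}} to the pair, as does every edge with i in g and k in f;
#' within-function activity sums the edges with both endpoints in the
#' function. Activities are summed as signed reals, preserving the up/down
#' direction of interaction changes. A protein belonging to both functions
#' contributes once per ordered containment.
#'
#' @param net a `stage_network`.
#' @param enriched character vector of enriched function names (subset of the
#'   catalog).
#' @param catalog a `function_catalog`.
#' @return an object of class `functional_network`: list with `functions`,
#'   `edges` (data frame `f`, `g`, `activity`, with `f <= g`) and `stage`.
#' @export
functional_network <- function(net, enriched, catalog) {
  stopifnot(inherits(net, "stage_network"))
  enriched <- as.character(enriched)
  if (!all(enriched %in% names(catalog)))
    stop("every enriched function must be present in the catalog")
  # protein -> enriched functions containing it
  membership <- new.env(parent = emptyenv())
  for (f in enriched) {
    for (p in catalog[[f]]) {
      assign(p, c(get0(p, envir = membership, ifnotfound = character(0)), f),
             envir = membership)
    }
  }
  acc <- new.env(parent = emptyenv())
  if (nrow(net$edges) > 0L) {
    for (e in seq_len(nrow(net$edges))) {
      fi <- get0(net$edges$target[e], envir = membership,
                 ifnotfound = character(0))
      fk <- get0(net$edges$interactor[e], envir = membership,
                 ifnotfound = character(0))
      if (length(fi) == 0L || length(fk) == 0L) next
      for (f in fi) {
        for (g in fk) {
          key <- pair_key(f, g)
          assign(key, get0(key, envir = acc, ifnotfound = 0) +
                   net$edges$alpha[e], envir = acc)
        }
      }
    }
  }
  keys <- ls(acc)
  edges <- if (length(keys) > 0L) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(f = vapply(parts, `[`, "", 1L),
               g = vapply(parts, `[`, "", 2L),
               activity = vapply(keys, get, 0, envir = acc,
                                 USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(f = character(0), g = character(0), activity = numeric(0),
               stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$f, edges$g), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(functions = sort(enriched), edges = edges,
                 stage = net$stage),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat("Functional network", if (!is.na(x$stage)) paste0(" [", x$stage, "]"),
      ": ", length(x$functions), " enriched functions, ", nrow(x$edges),
      " function-pair activities\n", sep = "")
  invisible(x)
}

#' Differential network between two stages
#'
#' Edgewise difference (later minus earlier) over the union of edges, with
#' absent edges treated as zero. For core (or stage) networks, the node-level
#' difference of basal levels \eqn{\Delta\beta} is included; basal-level
#' changes between stages are the readout used to flag candidate miRNA or
#' methylation regulation.
#'
#' @param later,earlier two networks of the same kind: `functional_network`,
#'   `core_network` or `stage_network`.
#' @return an object of class `differential_network`: list with `edge_delta`
#'   (data frame with the two node columns and `delta`), `node_delta` (named
#'   vector of basal-level differences, or `NULL` for functional networks),
#'   `from_stage` (earlier) and `to_stage` (later).
#' @export
differential_network <- function(later, earlier) {
  functional <- inherits(later, "functional_network")
  if (functional != inherits(earlier, "functional_network"))
    stop("'later' and 'earlier' must be networks of the same kind")
  if (functional) {
    key_cols <- c("f", "g")
    le <- later$edges
    ee <- earlier$edges
    lw <- stats::setNames(le$activity, pair_key(le$f, le$g))
    ew <- stats::setNames(ee$activity, pair_key(ee$f, ee$g))
  } else {
    key_cols <- c("target", "interactor")
    le <- later$edges
    ee <- earlier$edges
    lw <- stats::setNames(le$alpha, paste(le$target, le$interactor,
                                          sep = "\r"))
    ew <- stats::setNames(ee$alpha, paste(ee$target, ee$interactor,
                                          sep = "\r"))
  }
  keys <- union(names(lw), names(ew))
  delta <- vapply(keys, function(k) {
    (if (k %in% names(lw)) lw[[k]] else 0) -
      (if (k %in% names(ew)) ew[[k]] else 0)
  }, numeric(1), USE.NAMES = FALSE)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edge_delta <- data.frame(a = vapply(parts, `[`, "", 1L),
                           b = vapply(parts, `[`, "", 2L),
                           delta = delta, stringsAsFactors = FALSE)
  names(edge_delta)[1:2] <- key_cols
  edge_delta <- edge_delta[order(edge_delta[[1L]], edge_delta[[2L]]), ,
                           drop = FALSE]
  rownames(edge_delta) <- NULL

  node_delta <- NULL
  if (!functional && (!is.null(later$beta) || !is.null(earlier$beta))) {
    nodes <- union(names(later$beta), names(earlier$beta))
    lb <- stats::setNames(rep(0, length(nodes)), nodes)
    eb <- lb
    lb[names(later$beta)] <- later$beta
    eb[names(earlier$beta)] <- earlier$beta
    node_delta <- (lb - eb)[sort(nodes)]
  }
  structure(list(edge_delta = edge_delta,
                 node_delta = node_delta,
                 from_stage = earlier$stage %||% NA_character_,
                 to_stage = later$stage %||% NA_character_),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat("Differential network ", x$from_stage, " -> ", x$to_stage, ": ",
      nrow(x$edge_delta), " edge deltas",
      if (!is.null(x$node_delta))
        paste0(", ", length(x$node_delta), " node deltas"),
      "\n", sep = "")
  invisible(x)
}
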
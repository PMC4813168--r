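#' Assemble the candidate interaction network
#'
#' Intersects a candidate protein-pair list with the measured genes: pairs
#' with an unmeasured endpoint, self pairs and duplicates are dropped, and the
#' survivors are stored with their symmetric neighborhood structure (candidate
#' pairs are undirected; each direction becomes a candidate regressor in the
#' respective target model).
#'
#' @param edges two-column data frame (or matrix) of candidate protein pairs.
#' @param measured_genes character vector of measured gene/protein ids.
#' @param proteins optional explicit protein universe (must contain every
#'   surviving endpoint); proteins without any candidate pair are kept as
#'   isolated nodes and receive intercept-only model fits.
#' @return an object of class `candidate_network`: list with `proteins`,
#'   `pairs` (canonical two-column data frame) and `neighbors` (named list of
#'   character vectors).
#' @export
assemble_candidate_network <- function(edges, measured_genes,
                                       proteins = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L && ncol(edges) < 2L)
    stop("edges must have two columns")
  a <- as.character(edges[[1L]] %||% character(0))
  b <- as.character(edges[[2L]] %||% character(0))
  keep <- a %in% measured_genes & b %in% measured_genes
  pairs <- canonical_pairs(a[keep], b[keep])
  endpoints <- sort(unique(c(pairs$a, pairs$b)))
  if (is.null(proteins)) {
    proteins <- endpoints
  } else {
    proteins <- sort(unique(as.character(proteins)))
    if (!all(endpoints %in% proteins))
      stop("'proteins' must contain every surviving pair endpoint")
  }
  neighbors <- stats::setNames(
    rep(list(character(0)), length(proteins)), proteins)
  if (nrow(pairs) > 0L) {
    nb <- split(c(pairs$b, pairs$a), c(pairs$a, pairs$b))
    neighbors[names(nb)] <- lapply(nb, function(v) sort(unique(v)))
  }
  structure(list(proteins = proteins, pairs = pairs, neighbors = neighbors),
            class = "candidate_network")
}

#' @export
print.candidate_network <- function(x, ...) {
  cat("Candidate network: ", length(x$proteins), " proteins, ",
      nrow(x$pairs), " candidate pairs\n", sep = "")
  invisible(x)
}

#' Least squares with a nonnegative basal level
#'
#' Minimises \eqn{\|Z\alpha + \beta 1 - y\|_2^2} subject to \eqn{\beta \ge 0},
#' with the interaction activities \eqn{\alpha} unconstrained. With a single
#' inequality constraint the active-set method reduces to two phases: the
#' unconstrained least-squares solution is optimal whenever its intercept is
#' nonnegative; otherwise the constraint is active and the model is refitted
#' with \eqn{\beta = 0}.
#'
#' @param x numeric matrix of interactor profiles (samples x L); may have
#'   zero columns for an intercept-only fit.
#' @param y numeric response vector (length = number of samples).
#' @return list with `alpha` (named by the columns of `x`), `beta` (>= 0) and
#'   `rss`. Rank-deficient designs yield the minimum-norm solution with a
#'   warning.
#' @export
fit_constrained_lsq <- function(x, y) {
  y <- as.numeric(y)
  S <- length(y)
  if (is.null(x)) x <- matrix(numeric(0), S, 0L)
  x <- as.matrix(x)
  if (nrow(x) != S) stop("nrow(x) must equal length(y)")
  L <- ncol(x)

  solve_ls <- function(X) {
    qd <- qr(X)
    if (qd$rank < ncol(X)) {
      warning("rank-deficient design; returning the minimum-norm solution")
      sv <- svd(X)
      pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L]
      drop(sv$v[, pos, drop = FALSE] %*%
             ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
    } else {
      qr.coef(qd, y)
    }
  }

  X <- cbind(x, 1)
  theta <- solve_ls(X)
  if (theta[L + 1L] < 0) {
    # basal constraint active at the optimum
    if (L == 0L) {
      alpha <- numeric(0)
    } else {
      alpha <- solve_ls(x)
    }
    beta <- 0
    fitted <- if (L == 0L) rep(0, S) else drop(x %*% alpha)
  } else {
    alpha <- theta[seq_len(L)]
    beta <- theta[L + 1L]
    fitted <- drop(X %*% theta)
  }
  names(alpha) <- colnames(x)
  list(alpha = alpha, beta = unname(beta), rss = sum((y - fitted)^2))
}

#' Akaike information criterion for the interaction model order
#'
#' \eqn{AIC(L) = \log(RSS/M) + 2L/M} (natural log), the criterion minimised
#' during model-order detection. A perfect fit (`rss = 0`) returns `-Inf`;
#' ties at `-Inf` are broken toward the smaller order by the selection
#' routines.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n_samples number of samples M (>= 1).
#' @param order model order L (number of interactors, >= 0).
#' @return the AIC value.
#' @export
aic <- function(rss, n_samples, order) {
  if (rss < 0) stop("rss must be nonnegative")
  if (n_samples < 1L) stop("n_samples must be positive")
  if (order < 0L) stop("order must be nonnegative")
  if (rss == 0) return(-Inf)
  log(rss / n_samples) + 2 * order / n_samples
}

# Fit a selected interactor subset and evaluate its AIC; residual sums below
# rss_tol are treated as exact fits.
.fit_subset <- function(candidates, selected, y, rss_tol) {
  x <- if (length(selected) == 0L) {
    matrix(numeric(0), length(y), 0L)
  } else {
    candidates[, selected, drop = FALSE]
  }
  fit <- fit_constrained_lsq(x, y)
  if (fit$rss < rss_tol) fit$rss <- 0
  fit$aic <- aic(fit$rss, length(y), length(selected))
  fit
}

#' Fit a protein interaction model on a given interactor set
#'
#' Fits the constrained least-squares model for one target protein on a fixed
#' set of interactors (no order selection), e.g. to refit a known support or
#' to evaluate a candidate subset. [stepwise_select()] automates the choice
#' of the set.
#'
#' @param candidates numeric matrix (samples x candidates) with interactor
#'   ids as column names.
#' @param y numeric response profile of the target protein.
#' @param selected interactor ids to include (default: all candidates).
#' @param target optional target id recorded in the result.
#' @param rss_tol exact-fit tolerance as in [stepwise_select()].
#' @return a `protein_fit` for the given interactor set.
#' @export
fit_protein_model <- function(candidates, y, selected = colnames(candidates),
                              target = NA_character_, rss_tol = NULL) {
  y <- as.numeric(y)
  candidates <- as.matrix(candidates)
  selected <- sort(as.character(selected %||% character(0)))
  if (!all(selected %in% colnames(candidates)))
    stop("'selected' must name columns of 'candidates'")
  if (is.null(rss_tol)) rss_tol <- 1e-9 * max(sum(y^2), 1)
  fit <- .fit_subset(candidates, selected, y, rss_tol)
  structure(list(target = target,
                 selected = selected,
                 alpha = fit$alpha[selected],
                 beta = fit$beta,
                 rss = fit$rss,
                 aic = fit$aic,
                 pvalues = NULL,
                 n_samples = length(y)),
            class = "protein_fit")
}

#' Stepwise model-order detection for one target protein
#'
#' Greedy forward selection over the candidate interactors: at each step the
#' candidate whose inclusion (refitting by [fit_constrained_lsq()]) most
#' decreases the AIC is added, stopping when no addition decreases it. After
#' each addition beyond the first, backward elimination removes any selected
#' interactor whose removal decreases the AIC (or, at a tied perfect fit,
#' leaves it at `-Inf`, so the smallest perfect order wins). Ties in the AIC
#' decrease are broken toward the lexicographically smallest interactor id.
#'
#' @param candidates numeric matrix (samples x candidates) with interactor
#'   ids as column names; zero columns yield the intercept-only fit.
#' @param y numeric response profile of the target protein.
#' @param target optional target id recorded in the result.
#' @param max_order cap on the model order; defaults to
#'   `min(ncol(candidates), length(y) - 2)` so the pruning t-test keeps at
#'   least one residual degree of freedom.
#' @param rss_tol absolute tolerance below which a residual sum of squares is
#'   treated as an exact fit; defaults to `1e-9 * max(sum(y^2), 1)`.
#' @return an object of class `protein_fit`: list with `target`, `selected`
#'   (sorted interactor ids), `alpha`, `beta`, `rss`, `aic`, `pvalues`
#'   (filled by [prune_by_ttest()]) and `n_samples`.
#' @export
stepwise_select <- function(candidates, y, target = NA_character_,
                            max_order = NULL, rss_tol = NULL) {
  y <- as.numeric(y)
  S <- length(y)
  if (S < 2L) stop("at least two samples are required")
  if (is.null(candidates)) candidates <- matrix(numeric(0), S, 0L)
  candidates <- as.matrix(candidates)
  if (nrow(candidates) != S) stop("candidate profiles must have length(y) rows")
  if (ncol(candidates) > 0L && is.null(colnames(candidates)))
    stop("candidate columns must be named by interactor id")
  # deterministic lexicographic tie-breaking
  if (ncol(candidates) > 0L)
    candidates <- candidates[, order(colnames(candidates)), drop = FALSE]
  pool <- colnames(candidates)
  if (is.null(max_order)) max_order <- min(length(pool), S - 2L)
  max_order <- max(0L, min(max_order, length(pool)))
  if (is.null(rss_tol)) rss_tol <- 1e-9 * max(sum(y^2), 1)

  selected <- character(0)
  current <- .fit_subset(candidates, selected, y, rss_tol)

  backward_pass <- function() {
    repeat {
      if (length(selected) == 0L) return(invisible())
      best <- NULL
      for (s in selected) {
        trial_sel <- setdiff(selected, s)
        trial <- .fit_subset(candidates, trial_sel, y, rss_tol)
        drop_ok <- trial$aic < current$aic ||
          (is.infinite(trial$aic) && is.infinite(current$aic))
        if (drop_ok && (is.null(best) || trial$aic < best$fit$aic)) {
          best <- list(sel = trial_sel, fit = trial)
        }
      }
      if (is.null(best)) return(invisible())
      selected <<- best$sel
      current <<- best$fit
    }
  }

  repeat {
    if (length(selected) >= max_order) break
    remaining <- setdiff(pool, selected)
    if (length(remaining) == 0L) break
    best <- NULL
    for (cnd in remaining) {
      trial_sel <- c(selected, cnd)
      trial <- .fit_subset(candidates, trial_sel, y, rss_tol)
      if (trial$aic < current$aic &&
          (is.null(best) || trial$aic < best$fit$aic)) {
        best <- list(sel = trial_sel, fit = trial)
      }
    }
    if (is.null(best)) break
    selected <- best$sel
    current <- best$fit
    if (length(selected) >= 2L) backward_pass()
  }

  ord <- order(selected)
  structure(list(target = target,
                 selected = selected[ord],
                 alpha = current$alpha[selected[ord]],
                 beta = current$beta,
                 rss = current$rss,
                 aic = current$aic,
                 pvalues = NULL,
                 n_samples = S),
            class = "protein_fit")
}

#' @export
print.protein_fit <- function(x, ...) {
  cat("Protein interaction model fit",
      if (!is.na(x$target)) paste0(" for ", x$target), "\n", sep = "")
  cat("  order L = ", length(x$selected), ", rss = ",
      signif(x$rss, 4), ", AIC = ", signif(x$aic, 4), "\n", sep = "")
  invisible(x)
}

#' Prune a fitted model by per-coefficient t-tests
#'
#' Tests each interaction activity against the null \eqn{\alpha_{ij} = 0}
#' using the unconstrained ordinary-least-squares covariance (the basal-level
#' constraint binds on \eqn{\beta} alone, which is not tested), with
#' `S - L - 1` degrees of freedom. Coefficients with two-sided p-value at or
#' above `alpha_level` are deleted and the model is refitted once on the
#' survivors.
#'
#' @param fit a `protein_fit` from [stepwise_select()].
#' @param candidates the candidate profile matrix used for the fit.
#' @param y the target profile used for the fit.
#' @param alpha_level deletion threshold (default 0.05); coefficients with
#'   p >= `alpha_level` are removed.
#' @param rss_tol exact-fit tolerance as in [stepwise_select()].
#' @return the pruned and refitted `protein_fit`, with `pvalues` for the
#'   retained coefficients. If the residual degrees of freedom are
#'   nonpositive, pruning is skipped with a warning.
#' @export
prune_by_ttest <- function(fit, candidates, y, alpha_level = 0.05,
                           rss_tol = NULL) {
  stopifnot(inherits(fit, "protein_fit"))
  y <- as.numeric(y)
  S <- length(y)
  L <- length(fit$selected)
  if (is.null(rss_tol)) rss_tol <- 1e-9 * max(sum(y^2), 1)
  if (L == 0L) {
    fit$pvalues <- stats::setNames(numeric(0), character(0))
    return(fit)
  }
  df <- S - L - 1L
  if (df <= 0L) {
    warning("no residual degrees of freedom; skipping the t-test pruning")
    return(fit)
  }
  X <- cbind(candidates[, fit$selected, drop = FALSE], 1)
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    warning("rank-deficient design; skipping the t-test pruning")
    return(fit)
  }
  coef <- qr.coef(qd, y)
  rss_u <- sum(qr.resid(qd, y)^2)
  if (rss_u < rss_tol) {
    # exact fit: |t| is unbounded, every coefficient is retained
    p <- rep(0, L)
  } else {
    sigma2 <- rss_u / df
    covm <- sigma2 * solve(crossprod(X))
    se <- sqrt(diag(covm))[seq_len(L)]
    p <- 2 * stats::pt(-abs(coef[seq_len(L)] / se), df)
  }
  names(p) <- fit$selected
  keep <- fit$selected[p < alpha_level]
  refit <- .fit_subset(candidates, keep, y, rss_tol)
  structure(list(target = fit$target,
                 selected = keep,
                 alpha = refit$alpha[keep],
                 beta = refit$beta,
                 rss = refit$rss,
                 aic = refit$aic,
                 pvalues = p[keep],
                 n_samples = S),
            class = "protein_fit")
}

#' Identify the stage-specific interaction network
#'
#' Runs [stepwise_select()] followed by [prune_by_ttest()] for every protein
#' of the candidate network against its candidate neighbors' expression
#' profiles, and assembles the retained interaction activities into the
#' directed sparse adjacency `N[target, interactor] = alpha` together with the
#' per-protein basal levels. Per-target fits are independent, so the result
#' does not depend on evaluation order.
#'
#' @param expr expression matrix (genes x samples) covering every candidate
#'   protein; its `"stage"` attribute labels the result.
#' @param cand a `candidate_network`.
#' @param alpha_level t-test pruning threshold (default 0.05).
#' @param max_order optional cap on the per-target model order.
#' @return an object of class `stage_network`: list with `proteins`, `edges`
#'   (data frame `target`, `interactor`, `alpha`, `p_value`), `beta` (named
#'   vector), `fits` (per-protein summary data frame) and `stage`.
#' @export
build_stage_network <- function(expr, cand, alpha_level = 0.05,
                                max_order = NULL) {
  stopifnot(inherits(cand, "candidate_network"))
  expr <- as.matrix(expr)
  missing <- setdiff(cand$proteins, rownames(expr))
  if (length(missing) > 0L)
    stop("expression matrix lacks candidate proteins: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  edges <- vector("list", length(cand$proteins))
  beta <- stats::setNames(numeric(length(cand$proteins)), cand$proteins)
  fits <- vector("list", length(cand$proteins))
  for (j in seq_along(cand$proteins)) {
    i <- cand$proteins[j]
    nb <- cand$neighbors[[i]]
    y <- expr[i, ]
    profiles <- t(expr[nb, , drop = FALSE])
    colnames(profiles) <- nb
    fit <- stepwise_select(profiles, y, target = i, max_order = max_order)
    fit <- prune_by_ttest(fit, profiles, y, alpha_level = alpha_level)
    beta[i] <- fit$beta
    if (length(fit$selected) > 0L) {
      edges[[j]] <- data.frame(target = i,
                               interactor = fit$selected,
                               alpha = unname(fit$alpha),
                               p_value = unname(fit$pvalues),
                               stringsAsFactors = FALSE)
    }
    fits[[j]] <- data.frame(protein = i, order = length(fit$selected),
                            rss = fit$rss, aic = fit$aic,
                            stringsAsFactors = FALSE)
  }
  edges <- if (any(!vapply(edges, is.null, logical(1)))) {
    do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  } else {
    data.frame(target = character(0), interactor = character(0),
               alpha = numeric(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(proteins = cand$proteins,
                 edges = edges,
                 beta = beta,
                 fits = do.call(rbind, fits),
                 stage = attr(expr, "stage") %||% NA_character_),
            class = "stage_network")
}

#' @export
print.stage_network <- function(x, ...) {
  cat("Stage network", if (!is.na(x$stage)) paste0(" [", x$stage, "]"),
      ": ", length(x$proteins), " proteins, ", nrow(x$edges),
      " directed interactions\n", sep = "")
  invisible(x)
}
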
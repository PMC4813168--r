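#' Read and validate a pipeline configuration
#'
#' Configuration is YAML or JSON with fields:
#' \describe{
#'   \item{stages}{named map of stage label to expression TSV path, in stage
#'     order (e.g. C, I, II, III); at least one stage, at least two for
#'     differential outputs.}
#'   \item{candidate_edges}{two-column TSV of candidate protein pairs.}
#'   \item{catalog}{GMT catalog of functions.}
#'   \item{mirna_targets}{optional two-column TSV (protein, miRNA).}
#'   \item{normalize}{logical; quantile-normalize each stage matrix.}
#'   \item{thresholds}{optional map: `t_alpha` (0.05), `enrich_fdr` (0.05),
#'     `energy` (85), `similarity` (6), `beta_change_min` (0.5).}
#'   \item{seed}{integer, echoed into the manifest.}
#'   \item{out_dir}{output directory, created if missing.}
#' }
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a configuration list (already parsed).
#' @export
as_pipeline_config <- function(cfg) {
  if (is.null(cfg$stages) || length(cfg$stages) < 1L)
    stop("config needs at least one entry under 'stages'")
  if (is.null(names(cfg$stages)) || any(!nzchar(names(cfg$stages))))
    stop("'stages' must be a named map of label -> expression TSV")
  for (f in c(unlist(cfg$stages), cfg$candidate_edges, cfg$catalog,
              cfg$mirna_targets)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  if (is.null(cfg$candidate_edges)) stop("config needs 'candidate_edges'")
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    t_alpha = th$t_alpha %||% 0.05,
    enrich_fdr = th$enrich_fdr %||% 0.05,
    energy = th$energy %||% 85,
    similarity = th$similarity %||% 6,
    beta_change_min = th$beta_change_min %||% 0.5)
  cfg$normalize <- isTRUE(cfg$normalize)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "stagenet-out"
  structure(cfg, class = "pipeline_config")
}

#' Run the full stagewise network pipeline
#'
#' Preprocessing, per-stage network identification, functional aggregation,
#' principal network projection and consecutive-stage differential analysis,
#' from a single configuration. All outputs are written under
#' `config$out_dir` and summarised in a JSON run manifest (per-stage node and
#' edge counts, thresholds, seed).
#'
#' The pipeline is deterministic given the configuration; the seed is set at
#' entry and echoed in the manifest so reruns are reproducible byte for byte.
#'
#' @param config a `pipeline_config`, or a path to one.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  labels <- names(config$stages)

  message("reading ", length(labels), " stage matrices")
  mats <- lapply(labels, function(s) {
    m <- read_expression_tsv(config$stages[[s]], stage = s)
    if (config$normalize) m <- quantile_normalize(m)
    m
  })
  names(mats) <- labels
  measured <- Reduce(intersect, lapply(mats, rownames))
  if (length(measured) == 0L) stop("the stage matrices share no genes")

  cand <- assemble_candidate_network(read_edge_list(config$candidate_edges),
                                     measured)
  catalog <- if (!is.null(config$catalog)) read_gmt(config$catalog)

  stage_nets <- list()
  func_nets <- list()
  core_nets <- list()
  manifest_stages <- list()
  for (s in labels) {
    message("stage ", s, ": identifying interaction network")
    net <- build_stage_network(mats[[s]], cand, alpha_level = th$t_alpha)
    stage_nets[[s]] <- net
    write_stage_network(net, file.path(config$out_dir,
                                       paste0("stage_", s, "_network")))
    connected <- unique(c(net$edges$target, net$edges$interactor))

    fn <- NULL
    if (!is.null(catalog)) {
      enriched <- enrich_functions(connected, catalog, measured,
                                   fdr = th$enrich_fdr)
      fn <- functional_network(net, enriched, catalog)
      func_nets[[s]] <- fn
      write_edge_list(fn$edges,
                      file.path(config$out_dir,
                                paste0("stage_", s, "_functional.tsv")))
    }

    cn <- NULL
    if (nrow(net$edges) > 0L) {
      eig <- eigen_decompose(net, energy_threshold = th$energy)
      sim <- protein_similarity(net, eig)
      cn <- core_network(net, select_core(sim, th$similarity),
                         similarity = sim)
      core_nets[[s]] <- cn
      write_edge_list(cn$edges,
                      file.path(config$out_dir,
                                paste0("stage_", s, "_core.tsv")))
      if (length(cn$proteins) > 0L) {
        write_graphml(cn$edges[, c("target", "interactor", "alpha")],
                      data.frame(name = cn$proteins,
                                 beta = unname(cn$beta),
                                 similarity = unname(cn$similarity)),
                      file.path(config$out_dir,
                                paste0("stage_", s, "_core.graphml")))
      }
    } else {
      warning("stage ", s, ": no interactions retained; core network skipped")
    }

    manifest_stages[[s]] <- list(
      proteins = length(connected),
      interactions = nrow(net$edges),
      functional_nodes = if (!is.null(fn)) length(fn$functions) else 0L,
      core_proteins = if (!is.null(cn)) length(cn$proteins) else 0L,
      core_interactions = if (!is.null(cn)) nrow(cn$edges) else 0L)
  }

  differentials <- list()
  if (length(labels) >= 2L) {
    for (j in seq_len(length(labels) - 1L)) {
      from <- labels[j]
      to <- labels[j + 1L]
      tag <- paste0(from, "_to_", to)
      if (!is.null(func_nets[[from]]) && !is.null(func_nets[[to]])) {
        df <- differential_network(func_nets[[to]], func_nets[[from]])
        write_edge_list(df$edge_delta,
                        file.path(config$out_dir,
                                  paste0("diff_", tag, "_functional.tsv")))
      }
      ds <- differential_network(stage_nets[[to]], stage_nets[[from]])
      write_edge_list(ds$edge_delta,
                      file.path(config$out_dir,
                                paste0("diff_", tag, "_network.tsv")))
      dc <- if (!is.null(core_nets[[from]]) && !is.null(core_nets[[to]])) {
        differential_network(core_nets[[to]], core_nets[[from]])
      } else {
        ds
      }
      write_edge_list(dc$edge_delta,
                      file.path(config$out_dir,
                                paste0("diff_", tag, "_core.tsv")))
      flags <- NULL
      if (!is.null(config$mirna_targets)) {
        flags <- flag_regulation_candidates(
          dc, read_mirna_targets(config$mirna_targets),
          beta_change_min = th$beta_change_min)
        utils::write.table(flags$mirna_candidates,
                           file.path(config$out_dir,
                                     paste0("diff_", tag, "_mirna.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(flags$methylation_candidates,
                           file.path(config$out_dir,
                                     paste0("diff_", tag,
                                            "_methylation.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      differentials[[tag]] <- list(
        from = from, to = to,
        edge_deltas = nrow(dc$edge_delta),
        mirna_candidates = if (!is.null(flags))
          nrow(flags$mirna_candidates) else NA_integer_,
        methylation_candidates = if (!is.null(flags))
          nrow(flags$methylation_candidates) else NA_integer_)
    }
  } else {
    warning("only one stage configured; no differential outputs")
  }

  manifest <- list(
    stages = manifest_stages,
    differentials = differentials,
    candidate = list(proteins = length(cand$proteins),
                     pairs = nrow(cand$pairs)),
    thresholds = th,
    normalize = config$normalize,
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
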
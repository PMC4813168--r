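#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path TSV file path.
#' @param stage optional stage label to attach.
#' @return numeric matrix (genes x samples) with a `"stage"` attribute.
#' @export
read_expression_tsv <- function(path, stage = NULL) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  attr(m, "stage") <- stage
  m
}

#' Write an expression matrix to TSV
#'
#' @param x numeric matrix (genes x samples).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix-style expression table
#'
#' Skips metadata lines (prefix `!`) and reads the remaining block as a TSV
#' expression matrix.
#'
#' @param path file path.
#' @param stage optional stage label.
#' @return numeric matrix with a `"stage"` attribute.
#' @export
read_geo_series_matrix <- function(path, stage = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  attr(m, "stage") <- stage
  m
}

#' Read a probe-to-gene map from a two-column TSV
#'
#' @param path TSV with columns probe and gene (header optional, detected by
#'   the literal column names).
#' @return data frame with columns `probe` and `gene`.
#' @export
read_probe_map <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("probe", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = header,
                          colClasses = "character")[, 1:2]
  names(df) <- c("probe", "gene")
  df
}

#' Read a candidate edge list from a two-column TSV
#'
#' @param path TSV of protein pairs, one pair per line; lines starting with
#'   `#` are skipped.
#' @return two-column character data frame.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("edge list must have two columns: ", path)
  names(df)[1:2] <- c("a", "b")
  df[, 1:2]
}

#' Write a weighted directed edge list to TSV
#'
#' @param edges data frame of edges (e.g. `target`, `interactor`, `alpha`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set catalog
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`. The
#' description field is kept as the function's group label when nonempty.
#'
#' @param path GMT file path.
#' @return a `function_catalog`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1L], " in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  groups <- stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  structure(sets, groups = groups, class = "function_catalog")
}

#' Write a function catalog to GMT
#'
#' @param catalog a `function_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  groups <- attr(catalog, "groups")
  lines <- vapply(names(catalog), function(f) {
    desc <- if (!is.null(groups) && f %in% names(groups)) groups[[f]] else "na"
    paste(c(f, desc, catalog[[f]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-to-miRNA target table
#'
#' @param path two-column TSV (protein, miRNA), one pair per line.
#' @return named list mapping protein id to a character vector of miRNAs.
#' @export
read_mirna_targets <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("miRNA target table must have two columns")
  split(df[[2L]], df[[1L]])
}

#' Export a network to GraphML
#'
#' Writes nodes with optional numeric attributes (basal level, similarity,
#' basal-level change) and weighted edges, matching the attribute semantics
#' used to render differential networks (signed weights encode up/down
#' regulation).
#'
#' @param edges data frame whose first two columns are the endpoint ids,
#'   remaining numeric columns become edge attributes.
#' @param nodes optional data frame whose first column is the node id,
#'   remaining columns become node attributes.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, nodes = NULL, path) {
  if (is.null(nodes)) {
    ids <- unique(c(as.character(edges[[1L]]), as.character(edges[[2L]])))
    nodes <- data.frame(name = ids, stringsAsFactors = FALSE)
  }
  names(nodes)[1L] <- "name"
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a stage network to TSV files
#'
#' Produces `<prefix>_edges.tsv` (target, interactor, alpha, p_value) and
#' `<prefix>_proteins.tsv` (protein, beta, order, rss, aic).
#'
#' @param net a `stage_network`.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_stage_network <- function(net, prefix) {
  stopifnot(inherits(net, "stage_network"))
  edge_path <- paste0(prefix, "_edges.tsv")
  prot_path <- paste0(prefix, "_proteins.tsv")
  write_edge_list(net$edges, edge_path)
  prot <- merge(data.frame(protein = net$proteins,
                           beta = unname(net$beta[net$proteins]),
                           stringsAsFactors = FALSE),
                net$fits, by = "protein", sort = TRUE)
  utils::write.table(prot, prot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, prot_path))
}
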
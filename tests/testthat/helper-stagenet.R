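# Shared fixture builders; everything is generated in code under fixed seeds.

pair_key <- stagenet:::pair_key

# A random weighted directed network in stage_network form.
random_stage_network <- function(n_proteins, n_edges, seed, stage = "C") {
  ids <- sprintf("P%04d", seq_len(n_proteins))
  withr::with_seed(seed, {
    pool <- expand.grid(target = ids, interactor = ids,
                        stringsAsFactors = FALSE)
    pool <- pool[pool$target != pool$interactor, ]
    pick <- pool[sample(nrow(pool), min(n_edges, nrow(pool))), ]
    edges <- data.frame(target = pick$target, interactor = pick$interactor,
                        alpha = rnorm(nrow(pick)), stringsAsFactors = FALSE)
    structure(list(proteins = ids, edges = edges,
                   beta = stats::setNames(abs(rnorm(n_proteins)), ids),
                   fits = NULL, stage = stage),
              class = "stage_network")
  })
}

# Independent brute-force oracle for functional aggregation: explicit double
# loop over member protein pairs of each function pair.
brute_functional_activity <- function(net, enriched, catalog) {
  amap <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(net$edges))) {
    assign(paste(net$edges$target[e], net$edges$interactor[e]),
           net$edges$alpha[e], envir = amap)
  }
  a_of <- function(i, k) get0(paste(i, k), envir = amap, ifnotfound = 0)
  out <- list()
  for (f in enriched) {
    for (g in enriched) {
      if (f > g) next
      total <- 0
      if (f == g) {
        for (i in catalog[[f]]) for (k in catalog[[f]]) {
          total <- total + a_of(i, k)
        }
      } else {
        for (i in catalog[[f]]) for (k in catalog[[g]]) {
          total <- total + a_of(i, k) + a_of(k, i)
        }
      }
      if (total != 0) out[[paste(f, g, sep = "\r")]] <- total
    }
  }
  out
}

# Undirected support of a truth / recovered network as canonical pair keys.
true_pair_keys <- function(truth) {
  unique(pair_key(truth$alpha$target, truth$alpha$interactor))
}
recovered_pair_keys <- function(net) {
  unique(pair_key(net$edges$target, net$edges$interactor))
}
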
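# Small in-code fixtures shared across test files.

two_marker_map <- function(span_cM = 20) {
  marker_map(c("A", "B"), c("I", "I"), c(0, span_cM))
}

# Build a dataset from two-marker spore genotypes: each tetrad is a character
# vector of four genotypes like "11" (P1 at A, P1 at B). "x" codes a dead
# spore.
two_marker_dataset <- function(tetrads, map = two_marker_map(),
                               strain = "hand-built") {
  rows <- do.call(rbind, lapply(seq_along(tetrads), function(i) {
    g <- tetrads[[i]]
    stopifnot(length(g) == 4L)
    dead <- g == "x"
    data.frame(
      tetrad_id = paste0("T", i),
      spore_id = c("a", "b", "c", "d"),
      viable = !dead,
      A = ifelse(dead, "NONE", paste0("P", substr(g, 1, 1))),
      B = ifelse(dead, "NONE", paste0("P", substr(g, 2, 2))),
      stringsAsFactors = FALSE
    )
  }))
  tetrad_dataset(strain, map, rows)
}

# Fast null-model simulation settings for one chromosome.
null_params <- function(map, length_cM, n, seed, conversion = 0, ndj = 0,
                        m = 0, noninterfering = 0) {
  chr <- unique(map$chromosome)
  len <- stats::setNames(length_cM, chr)
  sim_params(map, chrom_length_cM = len, m = m,
             noninterfering_fraction = noninterfering,
             conversion_prob = conversion, ndj_prob_e0 = ndj,
             disome_viable = stats::setNames(FALSE, chr),
             n_tetrads = n, seed = seed)
}
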
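#' Spore-viability profile of a dataset
#'
#' Tallies tetrads by their number of viable spores (0 through 4) and
#' computes the overall percent spore viability over all dissected spores,
#' including tetrads with no viable spore. Meiosis I nondisjunction shows up
#' in this profile as an excess of 0- and 2-spore-viable tetrads over the 1-
#' and 3-spore classes.
#'
#' @param dataset A [tetrad_dataset()].
#' @return A list of class `viability_profile`: `counts` (named "0".."4"),
#'   `percent_viable`, `n_tetrads`.
#' @export
viability_profile <- function(dataset) {
  viable <- .spore_matrix(dataset, "viable")
  n_viable <- colSums(viable)
  counts <- vapply(0:4, function(k) sum(n_viable == k), integer(1))
  names(counts) <- as.character(0:4)
  structure(
    list(counts = counts,
         percent_viable = 100 * sum(n_viable) / (4 * ncol(viable)),
         n_tetrads = ncol(viable)),
    class = "viability_profile"
  )
}

#' @export
print.viability_profile <- function(x, ...) {
  cat(sprintf("<viability_profile> n=%d SV=%.1f%% | 4:%d 3:%d 2:%d 1:%d 0:%d\n",
              x$n_tetrads, x$percent_viable,
              x$counts[["4"]], x$counts[["3"]], x$counts[["2"]],
              x$counts[["1"]], x$counts[["0"]]))
  invisible(x)
}

#' Nondisjunction signature of two-spore-viable tetrads
#'
#' Among tetrads with exactly two viable spores, computes the fraction that
#' are *non-maters* (both viable spores carry `BOTH` at the mating-type
#' marker: the chromosome-III disome carries MATa and MATalpha and cannot
#' mate) and the fraction whose two viable spores are *sisters*, inferred
#' from identical calls at every centromere-linked marker (sister spores
#' share centromeres, so they agree at tightly centromere-linked loci).
#'
#' @param dataset A [tetrad_dataset()] whose map flags a mating-type marker.
#' @return A list of class `ndj_signature`: `two_spore_tetrads`,
#'   `nonmater_fraction` and `sister_fraction` (percent of two-spore-viable
#'   tetrads, `NA` when there are none).
#' @export
ndj_signature <- function(dataset) {
  map <- dataset$marker_map
  mat <- map$marker[map$is_mating_type]
  if (length(mat) != 1L) stop("map must flag exactly one mating-type marker")
  cen <- map$marker[map$is_centromere_linked]
  viable <- .spore_matrix(dataset, "viable")
  two_spore <- colSums(viable) == 2L
  n2 <- sum(two_spore)
  if (n2 == 0L) {
    return(structure(list(two_spore_tetrads = 0L,
                          nonmater_fraction = NA_real_,
                          sister_fraction = NA_real_),
                     class = "ndj_signature"))
  }
  mat_calls <- .spore_matrix(dataset, mat)
  nonmater <- colSums(viable & mat_calls == "BOTH") == 2L
  sister <- rep(TRUE, ncol(viable))
  for (m in cen) {
    calls <- .spore_matrix(dataset, m)
    agree <- vapply(seq_len(ncol(calls)), function(j) {
      v <- calls[viable[, j], j]
      length(v) == 2L && v[1] == v[2]
    }, logical(1))
    sister <- sister & agree
  }
  structure(
    list(two_spore_tetrads = n2,
         nonmater_fraction = 100 * sum(nonmater & two_spore) / n2,
         sister_fraction = 100 * sum(sister & two_spore) / n2),
    class = "ndj_signature"
  )
}

#' @export
print.ndj_signature <- function(x, ...) {
  cat(sprintf("<ndj_signature> two-spore tetrads=%d non-mater=%.1f%% sisters=%.1f%%\n",
              x$two_spore_tetrads, x$nonmater_fraction, x$sister_fraction))
  invisible(x)
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact p-value by summation of hypergeometric probabilities: over all
#' tables with the observed margins, probabilities no larger than that of
#' the observed table (up to a relative tolerance of 1e-7 for ties) are
#' summed. Degenerate tables with a zero margin return p = 1.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return Two-tailed p-value.
#' @export
#' @examples
#' fisher_exact_2x2(9, 19, 2, 27) # 0.02: msh5 vs msh4 low-viability alleles
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("cell counts must be non-negative integers")
  }
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Viability-versus-crossover threshold table
#'
#' Orders strains by total map distance and tags those below a spore
#' viability cutoff, for threshold analyses of how far crossing over can
#' drop before viability suffers.
#'
#' @param strains `data.frame` with columns `label`, `total_cM`,
#'   `percent_viable` (one row per strain).
#' @param viability_cutoff Strains with `percent_viable` below this are
#'   tagged (`below_cutoff`); default 0 tags none.
#' @return The input rows sorted by `total_cM` with a logical
#'   `below_cutoff` column.
#' @export
threshold_surface <- function(strains, viability_cutoff = 0) {
  stopifnot(is.data.frame(strains), nrow(strains) >= 1L,
            all(c("label", "total_cM", "percent_viable") %in% names(strains)))
  out <- strains[order(strains$total_cM), , drop = FALSE]
  out$below_cutoff <- out$percent_viable < viability_cutoff
  rownames(out) <- NULL
  out
}
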
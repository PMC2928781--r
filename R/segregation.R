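SEG_CLASSES <- c("2:2", "3:1", "1:3", "4:0", "0:4", "unscorable")

# 4 x T matrices of calls / viability, columns in tetrad input order
.spore_matrix <- function(dataset, column) {
  sp <- dataset$spores
  ids <- tetrad_ids(dataset)
  ord <- order(match(sp$tetrad_id, ids), match(sp$spore_id, SPORE_IDS))
  matrix(sp[[column]][ord], nrow = 4L, dimnames = list(NULL, ids))
}

#' Classify per-marker segregation in each tetrad
#'
#' Counts `P1` versus `P2` calls among the four spores of each tetrad. A
#' (2,2) split is normal Mendelian segregation; (3,1)/(1,3) are
#' gene-conversion classes and (4,0)/(0,4) full conversions. A tetrad is
#' unscorable at a marker if it has fewer than four viable spores or any
#' `BOTH`/`NONE` call among viable spores (e.g. a disome).
#'
#' @param dataset A [tetrad_dataset()].
#' @param marker Marker name present in the dataset's map.
#' @return A factor (one element per tetrad, in input order) with levels
#'   `2:2`, `3:1`, `1:3`, `4:0`, `0:4`, `unscorable`.
#' @export
classify_marker_segregation <- function(dataset, marker) {
  if (!marker %in% dataset$marker_map$marker) {
    stop("marker not in map: ", marker)
  }
  calls <- .spore_matrix(dataset, marker)
  viable <- .spore_matrix(dataset, "viable")
  all_viable <- colSums(viable) == 4L
  n1 <- colSums(calls == "P1")
  n2 <- colSums(calls == "P2")
  cls <- rep("unscorable", ncol(calls))
  scorable <- all_viable & (n1 + n2 == 4L)
  cls[scorable & n1 == 2L] <- "2:2"
  cls[scorable & n1 == 3L] <- "3:1"
  cls[scorable & n1 == 1L] <- "1:3"
  cls[scorable & n1 == 4L] <- "4:0"
  cls[scorable & n1 == 0L] <- "0:4"
  factor(cls, levels = SEG_CLASSES)
}

#' Which tetrads have four viable spores?
#'
#' @param dataset A [tetrad_dataset()].
#' @return Logical vector, one element per tetrad in input order.
#' @export
four_spore_viable <- function(dataset) {
  colSums(.spore_matrix(dataset, "viable")) == 4L
}

#' Aberrant (non-2:2) segregation rate at a marker
#'
#' The percentage of four-spore-viable tetrads whose segregation at `marker`
#' is not 2:2 (gene conversions and full-conversion 4:0/0:4 events both
#' count as aberrant). The denominator is the number of four-spore-viable
#' tetrads, matching how dissection studies tabulate conversion frequencies.
#'
#' @param dataset A [tetrad_dataset()].
#' @param marker Marker name.
#' @return Percentage in `[0, 100]`.
#' @export
aberrant_rate <- function(dataset, marker) {
  cls <- classify_marker_segregation(dataset, marker)
  complete <- four_spore_viable(dataset)
  n <- sum(complete)
  if (n == 0L) stop("no four-spore-viable tetrads: aberrant rate undefined")
  aberrant <- complete & cls %in% c("3:1", "1:3", "4:0", "0:4")
  100 * sum(aberrant) / n
}

#' Tetrads scorable for linkage on a chromosome
#'
#' A tetrad enters interval tallies for a chromosome only if it has four
#' viable spores and segregates 2:2 at every marker of that chromosome;
#' tetrads aberrant at any marker are excluded from all intervals of the
#' chromosome, which keeps the per-interval totals of a chromosome equal.
#'
#' @param dataset A [tetrad_dataset()].
#' @param chromosome Chromosome label.
#' @return Logical vector, one element per tetrad in input order.
#' @export
chromosome_scorable <- function(dataset, chromosome) {
  markers <- dataset$marker_map$marker[dataset$marker_map$chromosome == chromosome]
  if (length(markers) == 0L) stop("no markers on chromosome ", chromosome)
  ok <- four_spore_viable(dataset)
  for (m in markers) {
    ok <- ok & classify_marker_segregation(dataset, m) == "2:2"
  }
  ok
}
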
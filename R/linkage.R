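#' Construct an interval tally
#'
#' Parental ditype (PD), tetratype (TT), and nonparental ditype (NPD) counts
#' for one two-marker interval, after exclusion of aberrant tetrads. Counts
#' may be non-negative reals so that published fractional tallies can be
#' carried through the estimators.
#'
#' @param PD,TT,NPD Non-negative counts.
#' @param interval Optional length-2 character vector naming the flanking
#'   markers.
#' @return A list of class `interval_tally` with fields `PD`, `TT`, `NPD`,
#'   `n` and `interval`.
#' @export
#' @examples
#' interval_tally(413, 141, 2)
interval_tally <- function(PD, TT, NPD, interval = c(NA_character_, NA_character_)) {
  if (any(c(PD, TT, NPD) < 0)) stop("tally counts must be non-negative")
  structure(
    list(PD = as.numeric(PD), TT = as.numeric(TT), NPD = as.numeric(NPD),
         n = as.numeric(PD + TT + NPD), interval = as.character(interval)),
    class = "interval_tally"
  )
}

#' @export
print.interval_tally <- function(x, ...) {
  iv <- if (all(is.na(x$interval))) "" else paste0(" ", x$interval[1], "-", x$interval[2])
  cat(sprintf("<interval_tally>%s PD=%g TT=%g NPD=%g (n=%g)\n",
              iv, x$PD, x$TT, x$NPD, x$n))
  invisible(x)
}

#' Classify tetrads for a two-marker interval
#'
#' For each tetrad that is scorable on the interval's chromosome (four viable
#' spores, 2:2 at every marker of the chromosome), the four two-marker spore
#' genotypes are compared against the parental configurations: all four
#' parental gives PD, all four recombinant gives NPD, and a 2:2 split gives
#' TT. Unscorable or aberrant tetrads are `excluded`.
#'
#' @param dataset A [tetrad_dataset()].
#' @param markerA,markerB Marker names on the same chromosome.
#' @return A factor (one element per tetrad, in input order) with levels
#'   `PD`, `TT`, `NPD`, `excluded`.
#' @export
classify_interval <- function(dataset, markerA, markerB) {
  map <- dataset$marker_map
  for (m in c(markerA, markerB)) {
    if (!m %in% map$marker) stop("marker not in map: ", m)
  }
  chrA <- map$chromosome[map$marker == markerA]
  chrB <- map$chromosome[map$marker == markerB]
  if (!identical(chrA, chrB)) {
    stop("markers ", markerA, " and ", markerB, " are on different chromosomes")
  }
  scorable <- chromosome_scorable(dataset, chrA)
  a <- .spore_matrix(dataset, markerA)
  b <- .spore_matrix(dataset, markerB)
  n_parental <- colSums(a == b)
  cls <- rep("excluded", ncol(a))
  cls[scorable & n_parental == 4L] <- "PD"
  cls[scorable & n_parental == 2L] <- "TT"
  cls[scorable & n_parental == 0L] <- "NPD"
  factor(cls, levels = c("PD", "TT", "NPD", "excluded"))
}

#' Tally PD/TT/NPD counts for an interval
#'
#' @inheritParams classify_interval
#' @return An [interval_tally()].
#' @export
tally_interval <- function(dataset, markerA, markerB) {
  cls <- classify_interval(dataset, markerA, markerB)
  counts <- table(cls)
  if (sum(counts[c("PD", "TT", "NPD")]) == 0) {
    stop("empty tally: no scorable tetrads for ", markerA, "-", markerB)
  }
  interval_tally(counts[["PD"]], counts[["TT"]], counts[["NPD"]],
                 interval = c(markerA, markerB))
}

#' Perkins tetrad map distance
#'
#' The classical tetrad estimator of genetic distance,
#' \deqn{cM = 100 (TT/2 + 3\,NPD) / n,}
#' which corrects for double crossovers through the NPD class. No mapping
#' function is applied.
#'
#' @param tally An [interval_tally()].
#' @return Map distance in centimorgans.
#' @export
#' @examples
#' perkins_distance(interval_tally(413, 141, 2)) # 13.8 cM
perkins_distance <- function(tally) {
  stopifnot(inherits(tally, "interval_tally"))
  if (tally$n <= 0) stop("empty tally: map distance undefined")
  100 * (tally$TT / 2 + 3 * tally$NPD) / tally$n
}

#' Delta-method standard error of the Perkins distance
#'
#' Treats (TT, NPD) as multinomial out of n tetrads; with \eqn{t = TT/n} and
#' \eqn{v = NPD/n},
#' \deqn{SE(cM) = 100 \sqrt{ (t(1-t)/4 + 9 v (1-v) - 3 t v) / n }.}
#' This reconstruction reproduces the standard errors printed by the
#' Stahl-laboratory tetrad tools to one decimal.
#'
#' @param tally An [interval_tally()].
#' @return Standard error in centimorgans.
#' @export
perkins_se <- function(tally) {
  stopifnot(inherits(tally, "interval_tally"))
  if (tally$n <= 0) stop("empty tally: standard error undefined")
  t <- tally$TT / tally$n
  v <- tally$NPD / tally$n
  100 * sqrt((t * (1 - t) / 4 + 9 * v * (1 - v) - 3 * t * v) / tally$n)
}

#' Single-spore recombination frequency as map distance
#'
#' Recombinant spores over total viable spores, times 100. Spores are counted
#' from all viable spores regardless of whether their tetrad was complete.
#'
#' @param parental,recombinant Spore counts (non-negative; fractional values
#'   from published tallies are accepted).
#' @return Map distance in centimorgans.
#' @export
#' @examples
#' spore_rf(2360, 351) # 12.9 cM
spore_rf <- function(parental, recombinant) {
  total <- parental + recombinant
  if (total <= 0) stop("no spores: recombination frequency undefined")
  100 * recombinant / total
}

#' Wilson score confidence interval for a spore map distance
#'
#' The Wilson interval (no continuity correction) on the recombinant
#' proportion, scaled to centimorgans. This is the interval the VassarStats
#' calculators report.
#'
#' @param recombinant,total Counts with `0 <= recombinant <= total`.
#' @param confidence Coverage level in (0, 1); default 0.95.
#' @return Length-2 numeric `c(low, high)` in cM.
#' @export
#' @examples
#' wilson_ci(351, 2711) # 11.7-14.3 cM
wilson_ci <- function(recombinant, total, confidence = 0.95) {
  if (total <= 0) stop("no spores: confidence interval undefined")
  if (recombinant < 0 || recombinant > total) {
    stop("recombinant count must be between 0 and total")
  }
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- recombinant / total
  denom <- 1 + z^2 / total
  centre <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  100 * c(centre - half, centre + half)
}

#' Sum of interval map distances for a dataset
#'
#' Sums per-interval estimates over the given interval list, by either the
#' tetrad (Perkins) or single-spore route. Grouping the interval list by
#' chromosome gives per-chromosome totals for chromosome-size analyses.
#'
#' @param dataset A [tetrad_dataset()].
#' @param intervals `data.frame` with columns `markerA`, `markerB` (e.g. from
#'   [marker_intervals()]).
#' @param route `"tetrad"` (Perkins on PD/TT/NPD tallies) or `"spore"`
#'   (recombination frequency over all viable spores).
#' @return Total map distance in cM.
#' @export
chromosome_map_sum <- function(dataset, intervals, route = c("tetrad", "spore")) {
  route <- match.arg(route)
  if (is.null(intervals) || nrow(intervals) == 0L) {
    stop("empty interval list")
  }
  per_interval <- vapply(seq_len(nrow(intervals)), function(i) {
    a <- intervals$markerA[i]
    b <- intervals$markerB[i]
    if (route == "tetrad") {
      perkins_distance(tally_interval(dataset, a, b))
    } else {
      tal <- spore_tally_interval(dataset, a, b)
      spore_rf(tal$parental, tal$recombinant)
    }
  }, numeric(1))
  sum(per_interval)
}

#' Parental/recombinant spore tally for an interval
#'
#' Counts viable spores with definite (`P1`/`P2`) calls at both markers;
#' spores from incomplete tetrads are included, matching the single-spore
#' columns of dissection reports.
#'
#' @inheritParams classify_interval
#' @return List with `parental`, `recombinant`, `total`.
#' @export
spore_tally_interval <- function(dataset, markerA, markerB) {
  sp <- dataset$spores
  a <- sp[[markerA]]
  b <- sp[[markerB]]
  usable <- sp$viable & a %in% c("P1", "P2") & b %in% c("P1", "P2")
  parental <- sum(usable & a == b)
  recombinant <- sum(usable & a != b)
  list(parental = parental, recombinant = recombinant,
       total = parental + recombinant)
}
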
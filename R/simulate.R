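#' Simulation parameters for the meiosis generator
#'
#' Bundles the biological dials of the simulator. Crossovers form on each
#' bivalent at 2 per Morgan of genetic length (each crossover involves two of
#' the four chromatids, so map length in cM is recovered directly as percent
#' recombinant spores). Interference follows the counting (chi-square) model:
#' precursor events are Poisson and every (m+1)-th matures into a crossover;
#' `m = 0` is the no-interference Poisson null. A fraction of crossover
#' activity can be routed through an interference-free Poisson pathway
#' (the Mms4-Mus81-like component). Bivalents that receive no crossover fail
#' the obligate crossover and nondisjoin at Meiosis I with probability
#' `ndj_prob_e0`, producing two disomic and two nullisomic spores; nullisomy
#' is always lethal, disomy is lethal except on chromosomes flagged viable
#' (chromosome III by default, whose disome is the classical non-mater).
#'
#' @param marker_map A [marker_map()]; defaults to [nhy_marker_map()].
#' @param chrom_length_cM Named numeric of full genetic lengths per
#'   chromosome (cM). Defaults to 115/350/180 for III/VII/VIII with the
#'   default map, otherwise to each chromosome's marker span.
#' @param m Interference order of the counting model (integer >= 0).
#' @param noninterfering_fraction Fraction of crossover activity through the
#'   non-interfering pathway, in `[0, 1]`.
#' @param conversion_prob Per-marker, per-meiosis gene conversion
#'   probability (one chromatid's allele overwritten, giving 3:1 or 1:3).
#' @param ndj_prob_e0 Probability that a zero-crossover bivalent nondisjoins
#'   at Meiosis I.
#' @param disome_viable Named logical: chromosomes whose disomic spores
#'   survive. Unnamed chromosomes default to lethal disomy.
#' @param n_tetrads Number of tetrads to simulate.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(marker_map = nhy_marker_map(),
                       chrom_length_cM = NULL,
                       m = 3L,
                       noninterfering_fraction = 0.2,
                       conversion_prob = 0.02,
                       ndj_prob_e0 = 0.5,
                       disome_viable = c(III = TRUE),
                       n_tetrads = 500L,
                       seed = 1L) {
  validate_marker_map(marker_map)
  chroms <- unique(marker_map$chromosome)
  if (is.null(chrom_length_cM)) {
    if (identical(sort(chroms), sort(c("III", "VII", "VIII")))) {
      chrom_length_cM <- c(III = 115, VII = 350, VIII = 180)
    } else {
      chrom_length_cM <- vapply(chroms, function(chr) {
        max(marker_map$position_cM[marker_map$chromosome == chr])
      }, numeric(1))
    }
  }
  if (is.null(names(chrom_length_cM)) || !all(chroms %in% names(chrom_length_cM))) {
    stop("chrom_length_cM must be named for every chromosome in the map")
  }
  for (chr in chroms) {
    span <- max(marker_map$position_cM[marker_map$chromosome == chr])
    if (chrom_length_cM[[chr]] < span) {
      stop("chromosome ", chr, " length (", chrom_length_cM[[chr]],
           " cM) is shorter than its marker span (", span, " cM)")
    }
  }
  stopifnot(m >= 0, m == floor(m),
            noninterfering_fraction >= 0, noninterfering_fraction <= 1,
            conversion_prob >= 0, conversion_prob <= 1,
            ndj_prob_e0 >= 0, ndj_prob_e0 <= 1,
            n_tetrads >= 1)
  dv <- stats::setNames(rep(FALSE, length(chroms)), chroms)
  dv[names(disome_viable)[names(disome_viable) %in% chroms]] <-
    disome_viable[names(disome_viable) %in% chroms]
  structure(
    list(marker_map = marker_map,
         chrom_length_cM = chrom_length_cM[chroms],
         m = as.integer(m),
         noninterfering_fraction = noninterfering_fraction,
         conversion_prob = conversion_prob,
         ndj_prob_e0 = ndj_prob_e0,
         disome_viable = dv,
         n_tetrads = as.integer(n_tetrads),
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

# Crossover positions for a batch of bivalents.
# Interfering pathway: stationary renewal -- precursors Poisson at
# 2(m+1)(1-f) per Morgan, every (m+1)-th matures, with a uniform phase so
# the crossover process is stationary at rate 2(1-f)/Morgan. Non-interfering
# pathway: Poisson at 2f/Morgan. Returns events sorted by (tetrad, position).
.crossover_batch <- function(n, length_M, m, noninterfering_fraction) {
  f <- noninterfering_fraction
  tid <- integer(0)
  pos <- numeric(0)
  if (f < 1 && length_M > 0) {
    lambda <- 2 * (m + 1) * (1 - f)
    npre <- stats::rpois(n, lambda * length_M)
    total <- sum(npre)
    if (total > 0) {
      tid_pre <- rep.int(seq_len(n), npre)
      u <- stats::runif(total, 0, length_M)
      ord <- order(tid_pre, u)
      tid_pre <- tid_pre[ord]
      u <- u[ord]
      # rank of each precursor within its tetrad
      first <- c(TRUE, tid_pre[-1L] != tid_pre[-total])
      idx <- seq_len(total)
      rk <- idx - rep.int(idx[first], diff(c(which(first), total + 1L))) + 1L
      off <- if (m == 0L) rep.int(0L, n) else sample(0:m, n, replace = TRUE)
      keep <- rk > off[tid_pre] & (rk - off[tid_pre] - 1L) %% (m + 1L) == 0L
      tid <- tid_pre[keep]
      pos <- u[keep]
    }
  }
  if (f > 0 && length_M > 0) {
    nni <- stats::rpois(n, 2 * f * length_M)
    total_ni <- sum(nni)
    if (total_ni > 0) {
      tid <- c(tid, rep.int(seq_len(n), nni))
      pos <- c(pos, stats::runif(total_ni, 0, length_M))
    }
  }
  ord <- order(tid, pos)
  list(tid = tid[ord], pos = pos[ord],
       n_co = tabulate(tid, nbins = n))
}

#' Simulate crossover positions on one bivalent
#'
#' Draws the crossover positions of a single meiosis for a bivalent of the
#' given genetic length, combining the interfering counting-model pathway
#' and the interference-free Poisson pathway. The expected number of
#' crossovers is `2 * length_M` regardless of `m` and the pathway split;
#' interference (`m > 0`) makes the count underdispersed.
#'
#' @param length_M Genetic length in Morgans (>= 0).
#' @param m Counting-model interference order.
#' @param noninterfering_fraction Fraction of crossovers through the
#'   Poisson pathway.
#' @return Sorted numeric vector of crossover positions in `[0, length_M]`.
#' @export
simulate_bivalent <- function(length_M, m = 0L, noninterfering_fraction = 0) {
  if (length_M < 0) stop("length must be non-negative")
  if (length_M == 0) return(numeric(0))
  ev <- .crossover_batch(1L, length_M, as.integer(m), noninterfering_fraction)
  sort(ev$pos)
}

# Apply crossover events to a batch of bivalents and read out marker alleles.
# state: n x 4 parent matrix evolving left-to-right (slots = spores). Each
# crossover exchanges the distal segments of one chromatid of each local
# parental identity, chosen uniformly and independently per event (no
# chromatid interference): two slots carry P1 and two carry P2 at any
# position, and the event picks one of each at random. This is the classical
# model under which successive exchanges are independent, so disjoint
# intervals show no spurious coincidence. Returns an n x 4 x K integer array.
.apply_crossovers <- function(n, events, marker_pos_M) {
  K <- length(marker_pos_M)
  state <- matrix(rep(c(1L, 1L, 2L, 2L), each = n), nrow = n)
  alleles <- array(NA_integer_, dim = c(n, 4L, K))
  ne <- length(events$tid)
  if (ne > 0L) {
    pick_a <- stats::runif(ne) < 0.5
    pick_b <- stats::runif(ne) < 0.5
    gap <- findInterval(events$pos, marker_pos_M) + 1L  # events in gap k precede marker k
    # sequential rank within (tetrad, gap); events are sorted by (tid, pos)
    first <- if (ne == 1L) TRUE else
      c(TRUE, events$tid[-1L] != events$tid[-ne] | gap[-1L] != gap[-ne])
    idx <- seq_len(ne)
    rk <- idx - rep.int(idx[first], diff(c(which(first), ne + 1L))) + 1L
    for (k in seq_len(K)) {
      in_gap <- which(gap == k)
      if (length(in_gap) > 0L) {
        max_rk <- max(rk[in_gap])
        for (r in seq_len(max_rk)) {
          sel <- in_gap[rk[in_gap] == r]
          tid_s <- events$tid[sel]
          S <- state[tid_s, , drop = FALSE]
          is_p1 <- S == 1L
          # exactly two slots of each identity per row; pick one of each
          a <- ifelse(pick_a[sel], max.col(is_p1, ties.method = "first"),
                      max.col(is_p1, ties.method = "last"))
          b <- ifelse(pick_b[sel], max.col(!is_p1, ties.method = "first"),
                      max.col(!is_p1, ties.method = "last"))
          ia <- cbind(tid_s, a)
          ib <- cbind(tid_s, b)
          tmp <- state[ia]
          state[ia] <- state[ib]
          state[ib] <- tmp
        }
      }
      alleles[, , k] <- state
    }
  } else {
    for (k in seq_len(K)) alleles[, , k] <- state
  }
  alleles
}

#' Simulate a tetrad dissection dataset
#'
#' Runs `n_tetrads` meioses under the given [sim_params()]: crossovers are
#' placed per chromosome (counting-model interference plus a Poisson
#' pathway), assigned to chromatids uniformly without chromatid
#' interference, marker alleles are read off the four chromatids, gene
#' conversions overwrite single chromatid alleles, zero-crossover bivalents
#' may nondisjoin at Meiosis I (two disomic sister spores, two nullisomic),
#' and spore viability follows the resulting aneuploidies. The output is a
#' [tetrad_dataset()] in the canonical dissection format, with the
#' ground-truth per-chromosome crossover counts and nondisjunction events
#' attached as `attr(x, "truth")`.
#'
#' @param params A [sim_params()].
#' @param path Optional path: write the dissection TSV.
#' @param truth_path Optional path: write the truth sidecar TSV (tetrad,
#'   chromosome, crossover count, nondisjunction flag, conversion count).
#' @return A [tetrad_dataset()] with a `truth` attribute.
#' @export
simulate_dataset <- function(params, path = NULL, truth_path = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  map <- params$marker_map
  n <- params$n_tetrads
  chroms <- unique(map$chromosome)
  markers <- map$marker

  allele_calls <- matrix("", nrow = n * 4L, ncol = length(markers),
                         dimnames = list(NULL, markers))
  ploidy <- array(1L, dim = c(n, 4L, length(chroms)),
                  dimnames = list(NULL, NULL, chroms))
  truth <- vector("list", length(chroms))
  names(truth) <- chroms

  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    mk <- map$marker[map$chromosome == chr]
    pos_M <- map$position_cM[map$chromosome == chr] / 100
    L <- params$chrom_length_cM[[chr]] / 100
    ev <- .crossover_batch(n, L, params$m, params$noninterfering_fraction)
    alleles <- .apply_crossovers(n, ev, pos_M)

    # per-chromosome Meiosis I orientation: which homolog goes to which pole
    flip <- stats::runif(n) < 0.5
    if (any(flip)) alleles[flip, , ] <- alleles[flip, c(3L, 4L, 1L, 2L), , drop = FALSE]

    # gene conversion: single-chromatid, single-marker overwrites
    n_conv <- integer(n)
    if (params$conversion_prob > 0) {
      for (k in seq_along(mk)) {
        hit <- which(stats::runif(n) < params$conversion_prob)
        if (length(hit) > 0L) {
          ch <- sample(1:4, length(hit), replace = TRUE)
          ij <- cbind(hit, ch, rep(k, length(hit)))
          alleles[ij] <- 3L - alleles[ij]
          n_conv[hit] <- n_conv[hit] + 1L
        }
      }
    }

    # obligate-crossover failure: zero-crossover bivalents may nondisjoin
    ndj <- ev$n_co == 0L & stats::runif(n) < params$ndj_prob_e0
    if (any(ndj)) {
      pole <- sample(1:2, sum(ndj), replace = TRUE)
      w <- which(ndj)
      dis1 <- w[pole == 1L]  # spores a,b disomic; c,d nullisomic
      dis2 <- w[pole == 2L]
      ploidy[dis1, 1:2, ci] <- 2L
      ploidy[dis1, 3:4, ci] <- 0L
      ploidy[dis2, 3:4, ci] <- 2L
      ploidy[dis2, 1:2, ci] <- 0L
    }

    for (k in seq_along(mk)) {
      calls <- c("P1", "P2")[alleles[, , k]]
      calls[ploidy[, , ci] == 2L] <- "BOTH"
      calls[ploidy[, , ci] == 0L] <- "NONE"
      # spores in row-major tetrad order: (tetrad 1: a..d, tetrad 2: a..d, ...)
      allele_calls[, mk[k]] <- as.vector(t(matrix(calls, nrow = n)))
    }
    truth[[chr]] <- data.frame(tetrad_id = paste0("T", seq_len(n)),
                               chromosome = chr, n_crossovers = ev$n_co,
                               ndj = ndj, n_conversions = n_conv,
                               stringsAsFactors = FALSE)
  }

  # viability: nullisomy lethal; disomy lethal unless flagged viable
  viable_mat <- matrix(TRUE, nrow = n, ncol = 4L)
  for (ci in seq_along(chroms)) {
    pl <- ploidy[, , ci]
    viable_mat <- viable_mat & pl != 0L &
      (pl != 2L | params$disome_viable[[chroms[ci]]])
  }
  viable <- as.vector(t(viable_mat))
  allele_calls[!viable, ] <- "NONE"

  spores <- data.frame(
    tetrad_id = rep(paste0("T", seq_len(n)), each = 4L),
    spore_id = rep(SPORE_IDS, times = n),
    viable = viable,
    stringsAsFactors = FALSE
  )
  for (mname in markers) spores[[mname]] <- allele_calls[, mname]

  dataset <- tetrad_dataset(paste0("sim-seed", params$seed), map, spores)
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  attr(dataset, "truth") <- truth_df
  if (!is.null(path)) write_tetrad_table(dataset, path)
  if (!is.null(truth_path)) {
    utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  dataset
}

#' Simulate a single tetrad
#'
#' Convenience wrapper around [simulate_dataset()] with `n_tetrads = 1`.
#'
#' @param params A [sim_params()].
#' @return A [tetrad_dataset()] with one tetrad and a `truth` attribute.
#' @export
simulate_tetrad <- function(params) {
  params$n_tetrads <- 1L
  simulate_dataset(params)
}
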
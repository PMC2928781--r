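#' Build an analysis configuration
#'
#' @param dataset A [tetrad_dataset()], or a path to a dissection TSV (in
#'   which case `map` must be given).
#' @param map Optional [marker_map()] or path to a marker-map TSV, used when
#'   `dataset` is a path.
#' @param intervals Interval list (`data.frame` with `markerA`, `markerB`);
#'   defaults to all consecutive marker pairs.
#' @param interval_pairs `data.frame` with columns `markerA`, `markerB`,
#'   `markerC` naming adjacent interval pairs for COC analysis; defaults to
#'   all consecutive marker triples; an empty data.frame omits the COC
#'   section.
#' @param npd_method `"mle"` or `"papazian"`.
#' @param confidence Confidence level for spore-route intervals.
#' @param viability_cutoff Viability tag threshold (percent).
#' @param out_dir Optional directory for TSV report files.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(dataset, map = NULL, intervals = NULL,
                            interval_pairs = NULL, npd_method = "mle",
                            confidence = 0.95, viability_cutoff = 0,
                            out_dir = NULL) {
  if (is.character(dataset)) {
    dataset <- read_tetrad_table(dataset, map)
  }
  validate_tetrad_dataset(dataset)
  if (is.null(intervals)) intervals <- marker_intervals(dataset$marker_map)
  if (is.null(interval_pairs)) {
    iv <- intervals
    keep <- iv$markerB[-nrow(iv)] == iv$markerA[-1L] &
      iv$chromosome[-nrow(iv)] == iv$chromosome[-1L]
    interval_pairs <- data.frame(markerA = iv$markerA[-nrow(iv)][keep],
                                 markerB = iv$markerB[-nrow(iv)][keep],
                                 markerC = iv$markerB[-1L][keep],
                                 stringsAsFactors = FALSE)
  }
  structure(
    list(dataset = dataset, intervals = intervals,
         interval_pairs = interval_pairs, npd_method = npd_method,
         confidence = confidence, viability_cutoff = viability_cutoff,
         out_dir = out_dir),
    class = "analysis_config"
  )
}

#' Run the full tetrad analysis pipeline
#'
#' Produces the standard report bundle for one dissection dataset: interval
#' map distances by both routes (spore recombination frequency with Wilson
#' intervals; Perkins tetrad distance with delta-method SE), per-marker
#' aberrant-segregation rates, coefficient-of-coincidence interference
#' tests for adjacent interval pairs, NPD-ratio tests per interval, and the
#' spore-viability profile with the nondisjunction signature when the map
#' carries a mating-type marker. Counts excluded at each filter are logged
#' via [message()].
#'
#' @param config An [analysis_config()].
#' @return A list of class `analysis_report` with data.frame components
#'   `map_table`, `aberrant_table`, `coc_table` (NULL when no pairs),
#'   `npd_table`, `viability`, `ndj` (NULL without a mating-type marker).
#'   If `config$out_dir` is set, each table is also written as TSV.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  ds <- config$dataset
  iv <- config$intervals
  n_total <- n_tetrads(ds)
  complete <- four_spore_viable(ds)
  message("run_analysis: ", n_total, " tetrads, ",
          sum(!complete), " excluded as incomplete (<4 viable spores)")

  map_table <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
    a <- iv$markerA[i]; b <- iv$markerB[i]
    st <- spore_tally_interval(ds, a, b)
    ci <- wilson_ci(st$recombinant, st$total, config$confidence)
    tal <- tally_interval(ds, a, b)
    data.frame(chromosome = iv$chromosome[i], interval = paste0(a, "-", b),
               spores_n = st$total, parental = st$parental,
               recombinant = st$recombinant,
               cM_spore = spore_rf(st$parental, st$recombinant),
               ci_low = ci[1], ci_high = ci[2],
               tetrads_n = tal$n, PD = tal$PD, TT = tal$TT, NPD = tal$NPD,
               cM_tetrad = perkins_distance(tal),
               se_tetrad = perkins_se(tal),
               stringsAsFactors = FALSE)
  }))
  for (chr in unique(iv$chromosome)) {
    message("run_analysis: chromosome ", chr, ": ",
            sum(complete) - sum(chromosome_scorable(ds, chr)),
            " complete tetrads excluded as aberrant")
  }

  aberrant_table <- do.call(rbind, lapply(ds$marker_map$marker, function(m) {
    data.frame(marker = m, aberrant_percent = aberrant_rate(ds, m),
               stringsAsFactors = FALSE)
  }))

  coc_table <- NULL
  if (!is.null(config$interval_pairs) && nrow(config$interval_pairs) > 0L) {
    ip <- config$interval_pairs
    coc_table <- do.call(rbind, lapply(seq_len(nrow(ip)), function(i) {
      i1 <- c(ip$markerA[i], ip$markerB[i])
      i2 <- c(ip$markerB[i], ip$markerC[i])
      t1 <- tally_interval(ds, i1[1], i1[2])
      t2 <- tally_interval(ds, i2[1], i2[2])
      obs <- count_dco(ds, i1, i2)
      res <- coc_test(obs, expected_dco(t1, t2), t1$n)
      data.frame(pair = paste(ip$markerA[i], ip$markerB[i], ip$markerC[i],
                              sep = "-"),
                 dco_obs = res$dco_obs, dco_exp = res$dco_exp, coc = res$coc,
                 p = res$p_two_tailed,
                 interference = res$interference_called,
                 stringsAsFactors = FALSE)
    }))
  }

  npd_table <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
    tal <- tally_interval(ds, iv$markerA[i], iv$markerB[i])
    res <- tryCatch(npd_ratio_test(tal, config$npd_method),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(interval = paste0(iv$markerA[i], "-", iv$markerB[i]),
               npd_obs = res$npd_obs, npd_exp = res$npd_exp,
               ratio = res$ratio, x_hat = res$x_hat, p = res$p,
               method = res$method, interference = res$interference_called,
               stringsAsFactors = FALSE)
  }))

  vp <- viability_profile(ds)
  viability <- data.frame(n_tetrads = vp$n_tetrads,
                          percent_viable = vp$percent_viable,
                          viable4 = vp$counts[["4"]], viable3 = vp$counts[["3"]],
                          viable2 = vp$counts[["2"]], viable1 = vp$counts[["1"]],
                          viable0 = vp$counts[["0"]])

  ndj <- NULL
  if (sum(ds$marker_map$is_mating_type) == 1L) {
    sig <- ndj_signature(ds)
    ndj <- data.frame(two_spore_tetrads = sig$two_spore_tetrads,
                      nonmater_percent = sig$nonmater_fraction,
                      sister_percent = sig$sister_fraction)
  }

  report <- structure(
    list(strain = ds$strain, map_table = map_table,
         aberrant_table = aberrant_table, coc_table = coc_table,
         npd_table = npd_table, viability = viability, ndj = ndj),
    class = "analysis_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("map_table", "aberrant_table", "coc_table", "npd_table",
                 "viability", "ndj")) {
      tab <- report[[nm]]
      if (is.null(tab)) next
      out <- tab
      num <- vapply(out, is.numeric, logical(1))
      out[num] <- lapply(out[num], round_half_up, digits = 4)
      utils::write.table(out, file.path(config$out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> strain:", x$strain, "\n")
  cat("  intervals:", nrow(x$map_table),
      "| total tetrad cM:", round_half_up(sum(x$map_table$cM_tetrad), 1), "\n")
  invisible(x)
}
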
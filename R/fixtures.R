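#' Load a bundled published-count fixture
#'
#' The package ships the printed count tables of the NHY/EAY *msh4*/*msh5*
#' dissection study as plain TSV fixtures: per-interval spore and tetrad
#' tallies for eight strains (`table2_nhy`), the 57-allele spore-viability /
#' chromosome-XV map-distance survey (`table1_eay`), observed
#' double-crossover counts with the published COC calls (`table4`), and the
#' published NPD-ratio rows (`table5`). These are tallies, not per-tetrad
#' data: the study published marginal counts, so fixture-driven analyses
#' feed [interval_tally()] objects straight into the estimators.
#'
#' @param name One of `"table2_nhy"`, `"table1_eay"`, `"table4"`, `"table5"`.
#' @return For `table2_nhy`, a list with the raw `data` plus nested
#'   `tallies[[strain]][[interval]]` ([interval_tally()]) and
#'   `spore_tallies[[strain]][[interval]]` (parental/recombinant lists);
#'   for the others, a `data.frame`.
#' @export
#' @examples
#' fx <- load_fixture("table2_nhy")
#' perkins_distance(fx$tallies[["wild-type"]][["HIS4-LEU2"]]) # 13.8 cM
load_fixture <- function(name) {
  files <- c(table2_nhy = "nhy_table2.tsv", table1_eay = "eay_table1.tsv",
             table4 = "table4_coc.tsv", table5 = "table5_npd.tsv")
  if (!name %in% names(files)) {
    stop("unknown fixture: ", name, " (expected one of ",
         paste(names(files), collapse = ", "), ")")
  }
  path <- system.file("extdata", files[[name]], package = "tetramap",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (name != "table2_nhy") return(df)
  tallies <- list()
  spore_tallies <- list()
  for (i in seq_len(nrow(df))) {
    s <- df$strain[i]
    iv <- df$interval[i]
    tallies[[s]][[iv]] <- interval_tally(df$PD[i], df$TT[i], df$NPD[i],
                                         interval = strsplit(iv, "-")[[1]])
    spore_tallies[[s]][[iv]] <- list(parental = df$parental[i],
                                     recombinant = df$recombinant[i],
                                     total = df$parental[i] + df$recombinant[i])
  }
  list(data = df, tallies = tallies, spore_tallies = spore_tallies)
}

#' Per-strain chromosome map sums from the table2 fixture
#'
#' Sums the Perkins distances (or spore recombination frequencies) over the
#' fixture's eight intervals for one strain, optionally per chromosome.
#'
#' @param fixture Result of `load_fixture("table2_nhy")`.
#' @param strain Strain name in the fixture.
#' @param route `"tetrad"` or `"spore"`.
#' @param by_chromosome If `TRUE`, return a named per-chromosome vector.
#' @return Total cM (or named vector).
#' @export
fixture_map_sum <- function(fixture, strain, route = c("tetrad", "spore"),
                            by_chromosome = FALSE) {
  route <- match.arg(route)
  df <- fixture$data[fixture$data$strain == strain, , drop = FALSE]
  if (nrow(df) == 0L) stop("strain not in fixture: ", strain)
  per <- vapply(seq_len(nrow(df)), function(i) {
    if (route == "tetrad") {
      perkins_distance(interval_tally(df$PD[i], df$TT[i], df$NPD[i]))
    } else {
      spore_rf(df$parental[i], df$recombinant[i])
    }
  }, numeric(1))
  if (by_chromosome) {
    tapply(per, df$chromosome, sum)
  } else {
    sum(per)
  }
}
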
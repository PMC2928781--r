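test_that("viability profiles tally tetrads by viable-spore class", {
  ds <- two_marker_dataset(list(
    c("11", "11", "22", "22"),
    c("11", "12", "21", "22"),
    c("11", "11", "x", "x"),
    c("x", "x", "x", "x")
  ))
  vp <- viability_profile(ds)
  expect_equal(unname(vp$counts), c(1, 0, 1, 0, 2))
  expect_equal(vp$percent_viable, 100 * (4 + 4 + 2 + 0) / 16)
  expect_equal(sum(vp$counts), n_tetrads(ds))

  all_live <- two_marker_dataset(list(c("11", "11", "22", "22")))
  expect_equal(viability_profile(all_live)$percent_viable, 100)
})

test_that("nondisjunction signature identifies non-mater sister pairs", {
  map <- marker_map(c("CEN3", "MAT"), c("III", "III"), c(10, 25),
                    is_centromere_linked = c(TRUE, FALSE),
                    is_mating_type = c(FALSE, TRUE))
  rows <- rbind(
    # III-NDJ tetrad: two viable disomic sisters, both non-maters
    data.frame(tetrad_id = "T1", spore_id = c("a", "b", "c", "d"),
               viable = c(TRUE, TRUE, FALSE, FALSE),
               CEN3 = c("BOTH", "BOTH", "NONE", "NONE"),
               MAT = c("BOTH", "BOTH", "NONE", "NONE")),
    # two-spore tetrad from random death: non-sisters, maters
    data.frame(tetrad_id = "T2", spore_id = c("a", "b", "c", "d"),
               viable = c(TRUE, FALSE, TRUE, FALSE),
               CEN3 = c("P1", "NONE", "P2", "NONE"),
               MAT = c("P1", "NONE", "P2", "NONE"))
  )
  ds <- tetrad_dataset("t", map, rows)
  sig <- ndj_signature(ds)
  expect_equal(sig$two_spore_tetrads, 2L)
  expect_equal(sig$nonmater_fraction, 50)
  expect_equal(sig$sister_fraction, 50)

  no_mat <- marker_map(c("CEN3"), c("III"), c(10), TRUE, FALSE)
  ds2 <- tetrad_dataset("t", no_mat, rows[, names(rows) != "MAT"])
  expect_error(ndj_signature(ds2), "mating-type")
})

test_that("Fisher exact test matches published comparison and R's reference", {
  # msh5 vs msh4 alleles at or below 50% spore viability
  expect_equal(round_half_up(fisher_exact_2x2(9, 19, 2, 27), 2), 0.02)
  # independent cross-check against stats::fisher.test
  for (tab in list(c(9, 19, 2, 27), c(5, 12, 5, 3), c(0, 10, 4, 6))) {
    expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
  # independence-balanced table
  expect_equal(fisher_exact_2x2(4, 8, 2, 4), 1)
  # degenerate margins
  expect_equal(fisher_exact_2x2(0, 0, 3, 5), 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher exact equals the enumeration oracle on random small tables", {
  set.seed(7)
  for (i in 1:200) {
    tab <- stats::rpois(4, 5)
    expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 fisher_enum_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
})

test_that("threshold surface orders strains and tags low viability", {
  t1 <- load_fixture("table1_eay")
  strains <- data.frame(label = t1$allele, total_cM = t1$total_cM,
                        percent_viable = t1$sv_percent)
  surf <- threshold_surface(strains, viability_cutoff = 50)
  expect_equal(nrow(surf), 60)
  expect_true(!is.unsorted(surf$total_cM))
  # published anchor rows
  expect_equal(surf[surf$label == "wild-type", c("total_cM", "percent_viable")],
               data.frame(total_cM = 96.1, percent_viable = 97.0,
                          row.names = which(surf$label == "wild-type")))
  expect_equal(surf$total_cM[surf$label == "msh5-D532A"], 38.7)
  expect_equal(surf$percent_viable[surf$label == "msh5-D532A"], 64.5)
  # nothing is tagged at cutoff 0
  expect_false(any(threshold_surface(strains, 0)$below_cutoff))
  # the low-viability class is tagged at 50%
  expect_true(surf$below_cutoff[surf$label == "msh5-W298A"])
  expect_false(surf$below_cutoff[surf$label == "msh4-R676W"])
})

test_that("NDJ excess of 0- and 2-viable classes grows with the NDJ rate", {
  # null-mutant-like 2.5-fold crossover loss compresses the whole genetic map
  map <- nhy_marker_map()
  map$position_cM <- map$position_cM * 0.4
  short <- c(III = 46, VII = 140, VIII = 72)
  excess <- vapply(c(0, 0.25, 0.5), function(ndj) {
    p <- sim_params(map, chrom_length_cM = short, m = 0,
                    noninterfering_fraction = 1, conversion_prob = 0,
                    ndj_prob_e0 = ndj, n_tetrads = 800, seed = 31)
    vp <- viability_profile(simulate_dataset(p))
    (vp$counts[["0"]] + vp$counts[["2"]]) -
      (vp$counts[["1"]] + vp$counts[["3"]])
  }, numeric(1))
  expect_true(all(diff(excess) > 0))
})
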
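test_that("interval classification distinguishes PD, TT, NPD and exclusions", {
  ds <- two_marker_dataset(list(
    c("11", "11", "22", "22"),  # PD
    c("11", "12", "21", "22"),  # TT
    c("12", "12", "21", "21"),  # NPD
    c("11", "11", "12", "22"),  # aberrant at A -> excluded
    c("11", "11", "22", "x")    # incomplete -> excluded
  ))
  expect_equal(as.character(classify_interval(ds, "A", "B")),
               c("PD", "TT", "NPD", "excluded", "excluded"))
  tal <- tally_interval(ds, "A", "B")
  expect_equal(c(tal$PD, tal$TT, tal$NPD, tal$n), c(1, 1, 1, 3))

  map2 <- marker_map(c("A", "B"), c("I", "II"), c(0, 0))
  ds2 <- two_marker_dataset(list(c("11", "11", "22", "22")), map = map2)
  expect_error(classify_interval(ds2, "A", "B"), "different chromosomes")
})

test_that("aberrant tetrads are excluded from all intervals of the chromosome", {
  map3 <- marker_map(c("A", "B", "C"), c("I", "I", "I"), c(0, 10, 20))
  rows <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(tetrad_id = paste0("T", i), spore_id = c("a", "b", "c", "d"),
               viable = TRUE,
               A = if (i == 1) c("P1", "P1", "P1", "P2") else c("P1", "P1", "P2", "P2"),
               B = c("P1", "P1", "P2", "P2"), C = c("P1", "P1", "P2", "P2"),
               stringsAsFactors = FALSE)
  }))
  ds <- tetrad_dataset("t", map3, rows)
  # tetrad 1 is aberrant at A only, but drops out of the B-C interval too
  expect_equal(tally_interval(ds, "A", "B")$n, 9)
  expect_equal(tally_interval(ds, "B", "C")$n, 9)
})

test_that("Perkins distance and SE reproduce published wild-type values", {
  wt <- interval_tally(413, 141, 2)
  expect_equal(round_half_up(perkins_distance(wt), 1), 13.8)
  expect_equal(round_half_up(perkins_se(wt), 1), 1.2)
  expect_equal(round_half_up(perkins_se(interval_tally(317, 219, 2)), 1), 1.3)
  expect_equal(round_half_up(perkins_distance(interval_tally(378, 282, 3)), 1),
               22.6)
  # degenerate all-PD tally
  expect_equal(perkins_distance(interval_tally(100, 0, 0)), 0)
  expect_equal(perkins_se(interval_tally(100, 0, 0)), 0)
  expect_error(perkins_distance(interval_tally(0, 0, 0)), "empty")
})

test_that("single-spore map distances and Wilson intervals match published rows", {
  expect_equal(round_half_up(spore_rf(2360, 351), 1), 12.9)
  expect_equal(round_half_up(spore_rf(2379, 662), 1), 21.8)
  expect_equal(spore_rf(100, 0), 0)
  expect_error(spore_rf(0, 0), "undefined")

  expect_equal(round_half_up(wilson_ci(351, 2711), 1), c(11.7, 14.3))
  expect_equal(round_half_up(wilson_ci(92, 933), 1), c(8.1, 11.9))
  expect_equal(wilson_ci(0, 500)[1], 0)
  expect_error(wilson_ci(1, 0), "undefined")
})

test_that("published tallies regenerate the printed map-distance columns", {
  fx <- load_fixture("table2_nhy")
  df <- fx$data
  for (i in seq_len(nrow(df))) {
    tal <- interval_tally(df$PD[i], df$TT[i], df$NPD[i])
    expect_equal(round_half_up(perkins_distance(tal), 1), df$cM_tetrad[i],
                 info = paste(df$strain[i], df$interval[i]))
    expect_equal(round_half_up(spore_rf(df$parental[i], df$recombinant[i]), 1),
                 df$cM_spore[i], info = paste(df$strain[i], df$interval[i]))
    # printed SEs/CIs came from external web tools whose exact algorithms are
    # unpublished; the reconstructions agree within 0.1 cM on every row
    expect_lt(abs(perkins_se(tal) - df$se_tetrad[i]), 0.1)
    ci <- wilson_ci(df$recombinant[i], df$parental[i] + df$recombinant[i])
    expect_lt(max(abs(ci - c(df$ci_low[i], df$ci_high[i]))), 0.1)
  }
  # interval totals are equal within each chromosome after aberrant exclusion
  totals <- with(df, tapply(PD + TT + NPD, paste(strain, chromosome),
                            function(x) length(unique(x))))
  expect_true(all(totals == 1))
})

test_that("chromosome map sums reproduce the published strain totals", {
  fx <- load_fixture("table2_nhy")
  expect_equal(round_half_up(fixture_map_sum(fx, "wild-type"), 0), 147)
  expect_equal(round_half_up(fixture_map_sum(fx, "msh4-R676W"), 0), 109)
  expect_equal(round_half_up(fixture_map_sum(fx, "msh4d"), 0), 68)
  expect_equal(round_half_up(fixture_map_sum(fx, "msh5d"), 0), 56)
  # spore-route totals for the nulls, as published
  expect_equal(round_half_up(fixture_map_sum(fx, "msh4d", "spore"), 0), 87)
  expect_equal(round_half_up(fixture_map_sum(fx, "msh5d", "spore"), 0), 75)
})

test_that("chromosome_map_sum over a dataset equals the per-interval estimates", {
  d <- simulate_dataset(null_params(two_marker_map(), 20, 400, seed = 3))
  iv <- marker_intervals(d$marker_map)
  expect_equal(chromosome_map_sum(d, iv, "tetrad"),
               perkins_distance(tally_interval(d, "A", "B")))
  st <- spore_tally_interval(d, "A", "B")
  expect_equal(chromosome_map_sum(d, iv, "spore"),
               spore_rf(st$parental, st$recombinant))
  expect_error(chromosome_map_sum(d, iv[0, ], "tetrad"), "empty")
})

test_that("tetratype frequency matches the no-interference closed form", {
  # 20 cM interval: x = 0.4 exchanges/meiosis, pTT = (2/3)(1 - exp(-3x/2))
  d <- simulate_dataset(null_params(two_marker_map(), 20, 2000, seed = 21))
  tal <- tally_interval(d, "A", "B")
  p_tt <- (2 / 3) * (1 - exp(-0.6))
  expect_lt(abs(tal$TT / tal$n - p_tt), 3 * sqrt(p_tt * (1 - p_tt) / 2000))
})

test_that("Perkins and spore estimators agree on short no-interference intervals", {
  d <- simulate_dataset(null_params(two_marker_map(10), 10, 2000, seed = 8))
  tal <- tally_interval(d, "A", "B")
  st <- spore_tally_interval(d, "A", "B")
  diff <- perkins_distance(tal) - spore_rf(st$parental, st$recombinant)
  se_comb <- sqrt(perkins_se(tal)^2 +
                    (100^2) * 0.1 * 0.9 / st$total)
  expect_lt(abs(diff), 3 * se_comb + 1)  # +1 cM for the small double-crossover bias
})

test_that("delta-method SE tracks the replicate spread of the Perkins estimate", {
  n_rep <- 500
  per_rep <- 300
  d <- simulate_dataset(null_params(two_marker_map(), 20, n_rep * per_rep,
                                    seed = 13))
  cls <- classify_interval(d, "A", "B")
  grp <- rep(seq_len(n_rep), each = per_rep)
  ests <- vapply(split(cls, grp), function(x) {
    perkins_distance(interval_tally(sum(x == "PD"), sum(x == "TT"),
                                    sum(x == "NPD")))
  }, numeric(1))
  pooled <- tally_interval(d, "A", "B")
  se_pred <- perkins_se(interval_tally(pooled$PD / n_rep, pooled$TT / n_rep,
                                       pooled$NPD / n_rep))
  expect_lt(abs(stats::sd(ests) - se_pred) / se_pred, 0.15)
})

test_that("Wilson interval coverage is near nominal", {
  set.seed(99)
  n <- 500
  p <- 0.1
  hits <- replicate(1000, {
    k <- stats::rbinom(1, n, p)
    ci <- wilson_ci(k, n) / 100
    ci[1] <= p && p <= ci[2]
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("fractional published tallies are accepted by the estimators", {
  # some published spore tallies carry half counts (ambiguous spores)
  expect_equal(round_half_up(spore_rf(2222.5, 468.5), 1), 17.4)
  tal <- interval_tally(100.5, 50.5, 1)
  expect_gt(perkins_distance(tal), 0)
})
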
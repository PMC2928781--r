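test_that("DCO counting requires adjacency and counts TT/NPD-in-both tetrads", {
  map3 <- marker_map(c("A", "B", "C"), c("I", "I", "I"), c(0, 10, 20))
  mk <- function(gA, gB, gC) c(A = gA, B = gB, C = gC)
  rows <- do.call(rbind, lapply(seq_len(5), function(i) {
    g <- switch(i,
      list(c("P1","P1","P2","P2"), c("P1","P2","P1","P2"), c("P1","P2","P2","P1")), # TT both
      list(c("P1","P1","P2","P2"), c("P1","P2","P1","P2"), c("P2","P1","P1","P2")), # TT both
      list(c("P1","P1","P2","P2"), c("P1","P1","P2","P2"), c("P1","P2","P1","P2")), # PD then TT
      list(c("P1","P1","P2","P2"), c("P1","P1","P2","P2"), c("P1","P1","P2","P2")), # PD both
      list(c("P1","P1","P2","P2"), c("P1","P1","P2","P2"), c("P1","P1","P2","P2")))
    data.frame(tetrad_id = paste0("T", i), spore_id = c("a","b","c","d"),
               viable = TRUE, A = g[[1]], B = g[[2]], C = g[[3]],
               stringsAsFactors = FALSE)
  }))
  ds <- tetrad_dataset("t", map3, rows)
  expect_equal(count_dco(ds, c("A", "B"), c("B", "C")), 2)
  expect_error(count_dco(ds, c("A", "B"), c("A", "C")), "adjacent")

  expect_equal(count_dco(
    tetrad_dataset("t", map3, within(rows, {B <- A; C <- A})),
    c("A", "B"), c("B", "C")), 0)
})

test_that("expected DCO counts reproduce the published chance expectations", {
  # wild-type chromosome III and VIII interval pairs
  expect_equal(round_half_up(expected_dco(interval_tally(413, 141, 2),
                                          interval_tally(488, 68, 0)), 1), 17.5)
  expect_equal(round_half_up(expected_dco(interval_tally(317, 219, 2),
                                          interval_tally(277, 260, 1)), 1), 107.2)
  expect_equal(expected_dco(interval_tally(100, 0, 0),
                            interval_tally(50, 50, 0)), 0)
  expect_error(expected_dco(interval_tally(10, 5, 0), interval_tally(9, 5, 0)),
               "equal n")
})

test_that("the COC binomial test reproduces the published p-values and calls", {
  strong <- coc_test(67, 107.2138, 538)
  expect_equal(round_half_up(strong$coc, 3), 0.625)
  expect_lt(strong$p_two_tailed, 0.0001)
  expect_true(strong$interference_called)

  wt3 <- coc_test(5, 17.48921, 556)
  expect_equal(round_half_up(wt3$p_two_tailed, 3), 0.004)
  expect_true(wt3$interference_called)

  weak <- coc_test(14, 16.19735, 679)
  expect_equal(round_half_up(weak$coc, 3), 0.864)
  expect_lt(abs(weak$p_two_tailed - 0.667), 0.01)
  expect_false(weak$interference_called)

  null_case <- coc_test(20, 20, 500)
  expect_equal(null_case$coc, 1)
  expect_gt(null_case$p_two_tailed, 0.9)
  expect_false(null_case$interference_called)
  expect_error(coc_test(3, 0, 500), "zero expected")
})

test_that("no-interference class probabilities have the right structure", {
  expect_equal(no_interference_probs(0), c(PD = 1, TT = 0, NPD = 0))
  far <- no_interference_probs(50)
  expect_equal(unname(far), c(1 / 6, 2 / 3, 1 / 6), tolerance = 1e-10)
  for (x in seq(0, 5, by = 0.25)) {
    p <- no_interference_probs(x)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p[["PD"]] - p[["NPD"]], exp(-x), tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_error(no_interference_probs(-1), "non-negative")
})

test_that("class probabilities match the brute-force chromatid Monte-Carlo", {
  set.seed(42)
  for (x in c(0.5, 1.5)) {
    mc <- mc_tetrad_class_probs(x, 2e5)
    analytic <- no_interference_probs(x)
    for (cls in c("PD", "TT", "NPD")) {
      se <- sqrt(analytic[[cls]] * (1 - analytic[[cls]]) / 2e5)
      expect_lt(abs(mc[[cls]] - analytic[[cls]]), 3 * se + 1e-9)
    }
  }
})

test_that("Papazian expected NPDs agree with the moment-matched model", {
  expect_equal(papazian_expected_npd(interval_tally(100, 0, 0)), 0)
  expect_equal(round_half_up(papazian_expected_npd(interval_tally(197, 337, 9)), 1),
               57.3)
  # identity: n * pNPD(x) at the x that matches the tetratype frequency
  for (T in seq(0.05, 0.6, by = 0.05)) {
    n <- 1000
    tal <- interval_tally(n * (1 - T), n * T, 0)
    x <- -2 / 3 * log(1 - 3 * T / 2)
    expect_equal(papazian_expected_npd(tal),
                 n * no_interference_probs(x)[["NPD"]], tolerance = 1e-9)
  }
  expect_error(papazian_expected_npd(interval_tally(10, 90, 0)), "infeasible")
})

test_that("NPD-ratio test flags the published interference deficit", {
  wt_trp5 <- interval_tally(197, 337, 9)
  mle <- npd_ratio_test(wt_trp5, "mle")
  expect_lt(mle$ratio, 1)
  expect_lt(mle$p, 0.05)
  expect_true(mle$interference_called)
  pap <- npd_ratio_test(wt_trp5, "papazian")
  expect_lt(pap$ratio, 1)
  expect_lt(pap$p, 0.05)

  # MLE likelihood dominates the moment fit
  ll <- function(x, tal) {
    p <- no_interference_probs(x)
    tal$PD * log(p["PD"]) + tal$TT * log(p["TT"]) + tal$NPD * log(p["NPD"])
  }
  for (tal in list(interval_tally(197, 337, 9), interval_tally(413, 141, 2),
                   interval_tally(277, 260, 1))) {
    mle_fit <- npd_ratio_test(tal, "mle")
    x_pap <- -2 / 3 * log(1 - 3 * tal$TT / tal$n / 2)
    expect_gte(ll(mle_fit$x_hat, tal) + 1e-9, ll(x_pap, tal))
  }

  # exact agreement: observed == expected gives ratio 1
  n <- 600
  x <- 0.5
  p <- no_interference_probs(x)
  bal <- interval_tally(n * p[["PD"]], n * p[["TT"]], n * p[["NPD"]])
  res <- npd_ratio_test(bal, "mle")
  expect_equal(res$ratio, 1, tolerance = 1e-4)
  expect_equal(res$x_hat, x, tolerance = 1e-4)
  expect_gt(res$p, 0.99)
})

test_that("null simulations give NPD ratios near 1 and non-small p-values", {
  map <- two_marker_map(35)
  ratios <- numeric(8)
  ps <- numeric(8)
  for (i in seq_len(8)) {
    d <- simulate_dataset(null_params(map, 35, 1500, seed = 100 + i))
    res <- npd_ratio_test(tally_interval(d, "A", "B"), "mle")
    ratios[i] <- res$ratio
    ps[i] <- res$p
  }
  expect_lt(abs(mean(ratios) - 1), 0.25)
  expect_gt(mean(ps > 0.05), 0.5)
})
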
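#' Count double-crossover tetrads across two adjacent intervals
#'
#' A tetrad counts as a double crossover if it bears at least one detected
#' exchange (TT or NPD) in *both* intervals; a tetrad NPD in one interval and
#' TT in the other is a single DCO tetrad. Tetrads excluded in either
#' interval are dropped.
#'
#' @param dataset A [tetrad_dataset()].
#' @param interval1,interval2 Length-2 character vectors of marker names; the
#'   intervals must be adjacent (share the middle marker) on one chromosome.
#' @return Integer count of DCO tetrads.
#' @export
count_dco <- function(dataset, interval1, interval2) {
  if (!identical(interval1[2], interval2[1])) {
    stop("intervals must be adjacent (share the middle marker)")
  }
  cls1 <- classify_interval(dataset, interval1[1], interval1[2])
  cls2 <- classify_interval(dataset, interval2[1], interval2[2])
  keep <- cls1 != "excluded" & cls2 != "excluded"
  sum(keep & cls1 %in% c("TT", "NPD") & cls2 %in% c("TT", "NPD"))
}

#' Expected double-crossover tetrads under independence
#'
#' With \eqn{R_i = TT_i + NPD_i} crossover-containing tetrads in interval
#' \eqn{i} and a shared total of \eqn{n} tetrads, the chance expectation is
#' \eqn{R_1 R_2 / n}.
#'
#' @param tally1,tally2 [interval_tally()] objects over the same tetrad set
#'   (equal `n`).
#' @return Expected DCO count (real).
#' @export
#' @examples
#' expected_dco(interval_tally(413, 141, 2), interval_tally(488, 68, 0)) # 17.5
expected_dco <- function(tally1, tally2) {
  stopifnot(inherits(tally1, "interval_tally"), inherits(tally2, "interval_tally"))
  if (!isTRUE(all.equal(tally1$n, tally2$n))) {
    stop("tallies must come from the same tetrad set (equal n): ",
         tally1$n, " vs ", tally2$n)
  }
  R1 <- tally1$TT + tally1$NPD
  R2 <- tally2$TT + tally2$NPD
  R1 * R2 / tally1$n
}

#' Coefficient-of-coincidence test for crossover interference
#'
#' COC = observed / expected double crossovers; values below 1 indicate
#' interference. The two-tailed p-value uses the continuity-corrected normal
#' approximation to Binomial(n, expected/n):
#' \deqn{z = (|obs - exp| - 0.5) / \sqrt{n p_0 (1 - p_0)}, \quad
#'       p = 2 (1 - \Phi(z)),}
#' clamped to `[0, 1]`. Interference is called when p < 0.05 and COC < 1.
#'
#' @param dco_obs Observed DCO count.
#' @param dco_exp Expected DCO count (from [expected_dco()]).
#' @param n Number of tetrads shared by the two intervals.
#' @return A list of class `coc_result`: `dco_obs`, `dco_exp`, `coc`,
#'   `p_two_tailed`, `interference_called`.
#' @export
coc_test <- function(dco_obs, dco_exp, n) {
  if (n <= 0) stop("n must be positive")
  if (dco_exp < 0) stop("expected DCO count must be non-negative")
  if (dco_exp == 0) {
    if (dco_obs > 0) stop("COC undefined: zero expected but nonzero observed DCOs")
    coc <- NA_real_
    p <- 1
  } else {
    coc <- dco_obs / dco_exp
    p0 <- dco_exp / n
    z <- (abs(dco_obs - dco_exp) - 0.5) / sqrt(n * p0 * (1 - p0))
    p <- min(1, max(0, 2 * (1 - stats::pnorm(z))))
  }
  structure(
    list(dco_obs = dco_obs, dco_exp = dco_exp, coc = coc, p_two_tailed = p,
         interference_called = is.finite(coc) && p < 0.05 && coc < 1),
    class = "coc_result"
  )
}

#' @export
print.coc_result <- function(x, ...) {
  cat(sprintf("<coc_result> obs=%g exp=%.1f COC=%.3f p=%.4g %s\n",
              x$dco_obs, x$dco_exp, x$coc, x$p_two_tailed,
              if (x$interference_called) "(interference)" else ""))
  invisible(x)
}

#' Tetrad-class probabilities under no interference
#'
#' Under a Poisson number of exchanges per bivalent with mean `x` and no
#' chromatid interference (each exchange picks one chromatid of each homolog
#' uniformly), the tetrad classes for a marker pair have probabilities
#' \deqn{p_{TT} = \tfrac{2}{3}(1 - e^{-3x/2}), \quad
#'       p_{NPD} = \tfrac{1}{6} + \tfrac{1}{3} e^{-3x/2} - \tfrac{1}{2} e^{-x},}
#' with \eqn{p_{PD} = 1 - p_{TT} - p_{NPD}} (so \eqn{p_{PD} - p_{NPD} = e^{-x}}).
#' As \eqn{x \to \infty} the classes approach 1/6 : 2/3 : 1/6.
#'
#' @param x Mean exchanges per meiosis in the interval (`x >= 0`).
#' @return Named numeric `c(PD=, TT=, NPD=)` summing to 1.
#' @export
no_interference_probs <- function(x) {
  if (any(x < 0)) stop("x must be non-negative")
  tt <- (2 / 3) * (1 - exp(-3 * x / 2))
  npd <- 1 / 6 + exp(-3 * x / 2) / 3 - exp(-x) / 2
  c(PD = 1 - tt - npd, TT = tt, NPD = npd)
}

#' Papazian expected NPD count
#'
#' Papazian's classical moment formula: matching the observed tetratype
#' frequency \eqn{T = TT/n} to the no-interference model gives
#' \deqn{E[NPD] = \tfrac{n}{2}\left[(1 - T) - (1 - 3T/2)^{2/3}\right].}
#' Requires `T < 2/3` (the model's maximum tetratype frequency).
#'
#' @param tally An [interval_tally()].
#' @return Expected NPD count under no interference.
#' @export
papazian_expected_npd <- function(tally) {
  stopifnot(inherits(tally, "interval_tally"))
  if (tally$n <= 0) stop("empty tally")
  T <- tally$TT / tally$n
  if (T >= 2 / 3) {
    stop("tetratype frequency >= 2/3: no-interference model infeasible")
  }
  tally$n * 0.5 * ((1 - T) - (1 - 3 * T / 2)^(2 / 3))
}

# mean exchanges implied by the tetratype frequency alone (Papazian moment fit)
.x_from_tt <- function(T) {
  if (T >= 2 / 3) stop("tetratype frequency >= 2/3: x undefined")
  -2 / 3 * log(1 - 3 * T / 2)
}

# multinomial log-likelihood of (PD, TT, NPD) at exchange mean x
.npd_loglik <- function(x, tally) {
  p <- no_interference_probs(x)
  p <- pmax(p, 1e-300)
  tally$PD * log(p["PD"]) + tally$TT * log(p["TT"]) + tally$NPD * log(p["NPD"])
}

#' NPD-ratio test for crossover interference
#'
#' Compares the observed NPD count with the count expected under random
#' (no-interference) crossing over. `method = "papazian"` takes the expected
#' count from [papazian_expected_npd()] (tetratype-frequency moment fit);
#' `method = "mle"` fits the mean exchange number \eqn{\hat x} by maximizing
#' the multinomial likelihood of all three tetrad classes, then takes
#' \eqn{E[NPD] = n\,p_{NPD}(\hat x)}. Both methods report a 1-df chi-square
#' goodness-of-fit of (PD, TT, NPD) against the fitted class expectations; a
#' low p with a ratio below 1 flags interference (an NPD deficit).
#'
#' @param tally An [interval_tally()].
#' @param method `"papazian"` or `"mle"`.
#' @return A list of class `npd_ratio_result`: `npd_obs`, `npd_exp`, `ratio`,
#'   `x_hat`, `chi2`, `p`, `method`, `interference_called`.
#' @export
npd_ratio_test <- function(tally, method = c("mle", "papazian")) {
  method <- match.arg(method)
  stopifnot(inherits(tally, "interval_tally"))
  if (tally$n <= 0) stop("empty tally")
  if (method == "papazian") {
    x_hat <- .x_from_tt(tally$TT / tally$n)
    npd_exp <- papazian_expected_npd(tally)
  } else {
    # unlike the moment fit, the likelihood is well-defined even at TT/n >= 2/3
    opt <- stats::optimize(function(x) .npd_loglik(x, tally),
                           interval = c(1e-6, 20), maximum = TRUE,
                           tol = 1e-8)
    x_hat <- opt$maximum
    npd_exp <- tally$n * no_interference_probs(x_hat)[["NPD"]]
  }
  if (npd_exp <= 0 && tally$NPD > 0) {
    stop("zero expected NPDs with nonzero observed: ratio undefined")
  }
  ratio <- if (npd_exp > 0) tally$NPD / npd_exp else NA_real_
  expected <- tally$n * no_interference_probs(x_hat)
  obs <- c(tally$PD, tally$TT, tally$NPD)
  chi2 <- sum((obs - expected)^2 / pmax(expected, 1e-12))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(
    list(npd_obs = tally$NPD, npd_exp = npd_exp, ratio = ratio, x_hat = x_hat,
         chi2 = chi2, p = p, method = method,
         interference_called = is.finite(ratio) && p < 0.05 && ratio < 1),
    class = "npd_ratio_result"
  )
}

#' @export
print.npd_ratio_result <- function(x, ...) {
  cat(sprintf("<npd_ratio_result method=%s> obs=%g exp=%.2f ratio=%.3f x_hat=%.3f p=%.4g %s\n",
              x$method, x$npd_obs, x$npd_exp, x$ratio, x$x_hat, x$p,
              if (x$interference_called) "(interference)" else ""))
  invisible(x)
}
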
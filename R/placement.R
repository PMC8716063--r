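#' Shift an exclusivity rate on the logit scale
#'
#' The clonal exclusivity score `delta` acts as a shift in logit space,
#' `r' = logistic(logit(r) - delta)`, so that shifted rates stay inside
#' `[0, 1]`. Negative `delta` raises the rate (exclusivity enrichment),
#' positive `delta` lowers it (co-occurrence enrichment). Rates of exactly 0
#' or 1 (linear and star topologies) are fixed points for any finite shift,
#' which is why such patients carry no placement signal.
#'
#' @param r Rate(s) in `[0, 1]`.
#' @param delta Shift(s) on the logit scale.
#' @return Shifted rate(s).
#' @export
#' @examples
#' shift_rate(0.40, -4) # ~0.97
#' shift_rate(0.40, -3) # ~0.93
shift_rate <- function(r, delta) {
  if (any(r < 0 | r > 1, na.rm = TRUE)) abort("rates must lie in [0, 1].")
  out <- plogis(qlogis(r) - delta)
  fixed <- !is.na(r) & (r == 0 | r == 1)
  out[fixed] <- r[fixed]
  out
}

#' Null log-likelihood of observed exclusivity patterns
#'
#' Under random placement the pair is exclusive in patient `i` with
#' probability equal to the background rate `r_i`, giving log-likelihood
#' `sum_i O_i log(r_i) + (1 - O_i) log(1 - r_i)`. Outcomes may be fractional
#' when a patient contributes several posterior trees.
#'
#' @param rates Background rates, all strictly inside `(0, 1)`.
#' @param outcomes Exclusivity outcomes `O_i` in `[0, 1]`.
#' @return The log-likelihood (0 for empty data).
#' @export
loglik_placement_null <- function(rates, outcomes) {
  if (length(rates) != length(outcomes)) abort("rates and outcomes differ in length.")
  if (length(rates) == 0L) return(0)
  if (any(rates <= 0 | rates >= 1)) {
    abort("rates of 0 or 1 are uninformative; filter them before computing the likelihood.")
  }
  sum(outcomes * log(rates) + (1 - outcomes) * log1p(-rates))
}

# Vectorised golden-section maximisation of
#   f_j(d) = sum_i log sigma(d - eta[i, j]) - d * k[j]
# over d in [-bound, bound], one column at a time. This is the
# delta-dependent part of the shifted Bernoulli log-likelihood: writing
# O log s(eta - d) + (1 - O) log s(d - eta) = O eta + log s(d - eta) - d O
# shows the outcome enters only through its sum k = sum(O) (one-parameter
# exponential-family structure). The objective is concave in d (log-sigmoid
# is concave), so golden section converges to the global maximum, including
# boundary optima. Returns per-column argmax and maximum.
.max_gshift <- function(eta, kvec, bound = 10, iters = 62L) {
  n <- nrow(eta)
  B <- ncol(eta)
  f <- function(d) {
    .colSums(plogis(rep(d, each = n) - eta, log.p = TRUE), n, B) - d * kvec
  }
  gr <- (sqrt(5) - 1) / 2
  lo <- rep(-bound, B)
  hi <- rep(bound, B)
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1)
  f2 <- f(x2)
  for (it in seq_len(iters)) {
    left <- f1 > f2
    hi[left] <- x2[left]
    x2[left] <- x1[left]
    f2[left] <- f1[left]
    x1[left] <- hi[left] - gr * (hi[left] - lo[left])
    lo[!left] <- x1[!left]
    x1[!left] <- x2[!left]
    f1[!left] <- f2[!left]
    x2[!left] <- lo[!left] + gr * (hi[!left] - lo[!left])
    xnew <- ifelse(left, x1, x2)
    fnew <- f(xnew)
    f1[left] <- fnew[left]
    f2[!left] <- fnew[!left]
  }
  best1 <- f1 >= f2
  list(delta = ifelse(best1, x1, x2), value = pmax(f1, f2))
}

# maximised full log-likelihood per column: eta n x B logit rates, om n x B
# outcomes (fractional allowed); see .max_gshift for the decomposition
.max_loglik_shift <- function(eta, om, bound = 10, iters = 62L) {
  n <- nrow(eta)
  B <- ncol(eta)
  opt <- .max_gshift(eta, .colSums(om, n, B), bound = bound, iters = iters)
  opt$value <- opt$value + .colSums(om * eta, n, B)
  opt
}

# Because the LLR statistic depends on a binary outcome vector only through
# its exclusive count k (the b-specific term cancels between alternative and
# null), enumerating the 2^n outcome patterns collapses exactly onto
# k = 0..n: the LLR per k needs n + 1 optimisations, and the pattern
# probabilities aggregate to the Poisson-binomial distribution of k.
.placement_llr_by_k <- function(rates, bound = 10) {
  n <- length(rates)
  eta <- matrix(qlogis(rates), nrow = n, ncol = n + 1)
  opt <- .max_gshift(eta, 0:n, bound = bound)
  g0 <- sum(plogis(-qlogis(rates), log.p = TRUE)) # G(0) = sum log(1 - r)
  list(llr = pmax(0, 2 * (opt$value - g0)), delta = opt$delta)
}

# Poisson-binomial distribution of the exclusive count under the null:
# P(K = k) for k = 0..n given independent Bernoulli(r_i)
.pb_dist <- function(rates) {
  p <- 1
  for (r in rates) p <- c(p * (1 - r), 0) + c(0, p * r)
  p
}

# report optima that touch the optimisation bounds as +/-Inf
.report_delta <- function(delta, bound, inf_tol = 1e-6) {
  delta[delta >= bound - inf_tol] <- Inf
  delta[delta <= -(bound - inf_tol)] <- -Inf
  delta
}

#' Placement likelihood-ratio statistic for one gene pair
#'
#' Maximises the alternative log-likelihood over the shared logit shift
#' `delta` restricted to `[-bound, bound]` and returns the likelihood-ratio
#' statistic `LLR = 2 (l1 - l0)`. An optimum within `inf_tol` of a bound is
#' reported as `-Inf` (exclusivity) or `+Inf` (co-occurrence): beyond the
#' bound the saturating logit transform no longer changes the likelihood
#' appreciably.
#'
#' @inheritParams loglik_placement_null
#' @param bound Optimisation bound on `delta` (default 10).
#' @param inf_tol Distance to a bound at which `delta` is reported infinite.
#' @return List with `delta` (the maximising shift, possibly `+/-Inf`) and
#'   `llr` (non-negative statistic).
#' @export
placement_llr <- function(rates, outcomes, bound = 10, inf_tol = 1e-6) {
  if (length(rates) < 1L) abort("placement LLR needs at least one informative patient.")
  l0 <- loglik_placement_null(rates, outcomes)
  opt <- .max_loglik_shift(cbind(qlogis(rates)), cbind(outcomes), bound = bound)
  list(
    delta = .report_delta(opt$delta, bound, inf_tol),
    llr = max(0, 2 * (opt$value - l0))
  )
}

#' Asymptotic placement p-value
#'
#' Upper tail of the chi-squared distribution with one degree of freedom,
#' appropriate when the pair is observed in enough patients (the package
#' switches to this approximation above `exact_max_n`, by default 12).
#'
#' @param llr Non-negative likelihood-ratio statistic.
#' @param tol Negative values beyond `-tol` raise an error.
#' @return p-value.
#' @export
p_placement_chisq <- function(llr, tol = 1e-8) {
  if (any(llr < -tol)) abort("negative LLR statistic.")
  pchisq(pmax(llr, 0), df = 1, lower.tail = FALSE)
}

.tie_band <- function(llr, obs, tie_tol = 1e-9) {
  abs(llr - obs) <= tie_tol * max(1, abs(obs))
}

#' Exact placement p-value by enumeration
#'
#' Enumerates the `2^n` binary exclusivity patterns with null probabilities
#' `P(b) = prod_i r_i^{b_i} (1-r_i)^{1-b_i}`, and returns the total
#' probability of patterns with a larger LLR statistic than observed plus
#' half the probability of patterns with an equal LLR (the mid-p / half-tie
#' rule, which makes the p-value calibrated on average under the null).
#' Because the LLR depends on a pattern only through its exclusive count
#' (the shift parameter is the natural parameter of a one-parameter
#' exponential family with sufficient statistic `sum(b)`), the enumeration
#' is carried out over the `n + 1` counts with Poisson-binomial
#' probabilities — the result is identical to brute-force pattern
#' enumeration, vector ties included.
#'
#' @inheritParams placement_llr
#' @param outcomes Binary outcomes (patients with posterior tree samples must
#'   be binarised first; see [test_placement()]).
#' @param exact_max_n Maximum `n` for enumeration (default 12); larger inputs
#'   raise an error directing to the chi-squared or Monte-Carlo variants.
#' @param tie_tol Relative tolerance for detecting tied LLR statistics.
#' @return p-value.
#' @export
p_placement_exact <- function(rates, outcomes, bound = 10, exact_max_n = 12,
                              tie_tol = 1e-9) {
  n <- length(rates)
  if (n < 1L) abort("exact test needs at least one informative patient.")
  if (n > exact_max_n) {
    abort(sprintf(
      "n = %d exceeds the enumeration limit (%d); use the chi-squared or Monte-Carlo variant.",
      n, exact_max_n
    ))
  }
  if (!all(outcomes %in% c(0, 1))) {
    abort("the exact test is defined on binary outcomes; binarise fractional O first.")
  }
  if (any(rates <= 0 | rates >= 1)) abort("rates must lie strictly in (0, 1).")
  llr_k <- .placement_llr_by_k(rates, bound = bound)$llr
  prob_k <- .pb_dist(rates)
  obs <- llr_k[sum(outcomes) + 1]
  tie <- .tie_band(llr_k, obs, tie_tol)
  sum(prob_k[llr_k > obs & !tie]) + 0.5 * sum(prob_k[tie])
}

#' Monte-Carlo placement p-value with beta smoothing
#'
#' Instead of enumerating outcomes, samples `M` outcome vectors from the null.
#' Each sample first perturbs every rate with a `Beta(nu * r, nu * (1 - r))`
#' draw (overdispersion `nu`; `nu -> Inf` is noiseless and recovers the exact
#' test) and then draws Bernoulli outcomes at the perturbed rates; the
#' sample's LLR is computed at those perturbed rates. The p-value is the
#' fraction of samples with an LLR strictly larger than the observed
#' statistic; with noise, exact ties have probability zero, which smooths the
#' discreteness of the exact null.
#'
#' @inheritParams placement_llr
#' @param nu Overdispersion of the beta noise (default 10).
#' @param M Number of Monte-Carlo samples.
#' @param seed Optional seed for reproducibility.
#' @return p-value.
#' @export
p_placement_mc <- function(rates, outcomes, nu = 10, M = 1000, bound = 10,
                           seed = NULL) {
  n <- length(rates)
  if (n < 1L) abort("Monte-Carlo test needs at least one informative patient.")
  obs <- placement_llr(rates, outcomes, bound = bound)$llr
  draw <- function() {
    rt <- rbeta(n * M, rep(nu * rates, M), rep(nu * (1 - rates), M))
    rt <- pmin(pmax(rt, 1e-12), 1 - 1e-12)
    rt <- matrix(rt, nrow = n)
    bm <- matrix(rbinom(n * M, 1L, rt), nrow = n)
    l0 <- .colSums(bm * log(rt) + (1 - bm) * log1p(-rt), n, M)
    opt <- .max_loglik_shift(qlogis(rt), bm, bound = bound)
    llr <- pmax(0, 2 * (opt$value - l0))
    mean(llr > obs)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Minimum achievable exact p-value for a patient set
#'
#' The smallest exact placement p-value over all `2^n` possible outcome
#' vectors, given the background rates of the patients carrying the pair.
#' Pairs whose minimum exceeds the significance level can never be called
#' significant and are removed before testing so that they do not dilute the
#' multiple-testing correction (alpha budgeting).
#'
#' @inheritParams p_placement_exact
#' @param rates Background rates of the patients possessing both genes.
#' @return The minimum achievable p-value.
#' @export
min_possible_p <- function(rates, bound = 10, exact_max_n = 12, tie_tol = 1e-9) {
  n <- length(rates)
  if (n < 1L) abort("needs at least one informative patient.")
  if (n > exact_max_n) {
    abort(sprintf("n = %d exceeds the enumeration limit (%d).", n, exact_max_n))
  }
  llr_k <- .placement_llr_by_k(rates, bound = bound)$llr
  prob_k <- .pb_dist(rates)
  top <- max(llr_k)
  tie <- .tie_band(llr_k, top, tie_tol)
  # p is decreasing in the observed LLR, so the minimum is attained by the
  # top tie cluster, whose p is half its own probability mass
  0.5 * sum(prob_k[tie])
}

#' Run the placement test on a collected gene pair
#'
#' Filters to informative patients (background rate strictly between 0 and
#' 1), computes the LLR and the p-value: exact enumeration when `n <=
#' exact_max_n` (fractional posterior outcomes are binarised at `O >= 0.5`),
#' otherwise the chi-squared approximation on the possibly fractional
#' outcomes.
#'
#' @param obs A `clonex_pair_obs` from [collect_pair()].
#' @param exact_max_n Switch point between exact and asymptotic p-values.
#' @inheritParams placement_llr
#' @return A `clonex_test` object (see [tidy.clonex_test()]).
#' @export
test_placement <- function(obs, exact_max_n = 12, bound = 10, inf_tol = 1e-6) {
  pts <- obs$patients[obs$patients$informative, ]
  if (nrow(pts) == 0L) {
    abort(sprintf("pair %s_%s has no informative patients.", obs$gene_j, obs$gene_k))
  }
  exact <- nrow(pts) <= exact_max_n
  out_used <- if (exact) as.numeric(pts$excl) else pts$o
  st <- placement_llr(pts$r, out_used, bound = bound, inf_tol = inf_tol)
  p <- if (exact) {
    p_placement_exact(pts$r, out_used, bound = bound, exact_max_n = exact_max_n)
  } else {
    p_placement_chisq(st$llr)
  }
  .new_test(obs, method = "placement", delta = st$delta, llr = st$llr, p = p,
            exact_used = exact, bound = bound)
}

.new_test <- function(obs, method, delta, llr, p, exact_used, bound,
                      extra = list()) {
  structure(
    c(list(
      gene_j = obs$gene_j, gene_k = obs$gene_k, method = method,
      n_t = obs$n_t, n = obs$n, n_cx = obs$n_cx, n_l = obs$n_l, n_s = obs$n_s,
      m = obs$m, delta = delta, llr = llr, p = p,
      exact_used = exact_used, bound_hit = is.infinite(delta)
    ), extra),
    class = "clonex_test"
  )
}

#' @export
print.clonex_test <- function(x, ...) {
  cat(sprintf(
    "<%s test> %s_%s: delta = %s, LLR = %.3f, p = %.3g%s\n",
    x$method, x$gene_j, x$gene_k,
    formatC(x$delta, digits = 3, format = "g"), x$llr, x$p,
    if (x$exact_used) " (exact)" else " (chi-squared)"
  ))
  invisible(x)
}
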
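#' Combined occurrence-plus-placement likelihood-ratio statistic
#'
#' Joint test of which patients carry the gene pair and how it is placed in
#' their trees, with a single shared shift `delta` for both signals. When the
#' two shifts are equated, the per-patient placement factors and the weights
#' of the selected patients cancel in the joint likelihood ratio, which then
#' depends on the data only through `m`, the number of selected trees in
#' which the pair is clonally exclusive (counting star trees as exclusive and
#' linear trees as co-occurring). The reduced objective maximised here is
#'
#' `g(delta) = n_t log 2 + m log(1 - rho) + (n_t - m) log(rho) + log e_{n_t}(w) - log e_{n_t}(w'(rho))`
#'
#' with `rho = logistic(delta)` and tilted weights `w'` as in
#' [occurrence_alt_weights()]; `g(0) = 0`, so `LLR = 2 max_delta g(delta)`.
#'
#' @param m Number of exclusive trees among the selected patients, including
#'   star trees (`0 <= m <= n_t`).
#' @param n_t Number of selected patients.
#' @param w,r Weights and background rates of the eligible cohort.
#' @param bound,inf_tol As in [placement_llr()].
#' @return List with `delta` and `llr`.
#' @export
combined_llr <- function(m, n_t, w, r, bound = 10, inf_tol = 1e-6) {
  if (m < 0 || m > n_t) abort("m must lie between 0 and n_t.")
  if (n_t > length(w)) abort("n_t exceeds the cohort size.")
  if (n_t == length(w) && diff(range(r)) == 0) {
    return(list(delta = 0, llr = 0)) # only one possible set, no tilt signal
  }
  log_z <- .log_esp(w, n_t)
  g <- function(d) {
    n_t * log(2) + m * plogis(-d, log.p = TRUE) + (n_t - m) * plogis(d, log.p = TRUE) +
      log_z - .log_esp(occurrence_alt_weights(w, r, d), n_t)
  }
  opt <- optimize(g, c(-bound, bound), maximum = TRUE, tol = 1e-8)
  cand_x <- c(opt$maximum, -bound, bound, 0)
  cand_f <- c(opt$objective, g(-bound), g(bound), 0)
  best <- which.max(cand_f)
  llr <- max(0, 2 * cand_f[best])
  delta <- if (llr == 0) 0 else .report_delta(cand_x[best], bound, inf_tol)
  list(delta = delta, llr = llr)
}

#' Null distribution of the exclusive-tree count
#'
#' Under the null, the selected patient set of size `n_t` follows the
#' weighted-sampling distribution and, independently per selected patient,
#' the pair is exclusive with probability `r_i`. The distribution of the
#' exclusive count `m` is computed exactly by a bivariate dynamic programme
#' over patients tracking (selected count, exclusive count) with per-patient
#' factors 1 (not selected), `w_i (1 - r_i)` (selected, co-occurring) and
#' `w_i r_i` (selected, exclusive), normalised by `e_{n_t}(w)`.
#'
#' @inheritParams combined_llr
#' @return Numeric vector of probabilities `P(m)` for `m = 0, ..., n_t`.
#' @export
combined_null_m <- function(n_t, w, r) {
  N <- length(w)
  if (n_t > N) abort("n_t exceeds the cohort size.")
  s <- max(w, 1)
  ws <- w / s
  # T[s+1, m+1]: sum of products over ways to select s patients, m exclusive
  tab <- matrix(0, nrow = n_t + 1, ncol = n_t + 1)
  tab[1, 1] <- 1
  down <- function(mat) rbind(0, mat[-nrow(mat), , drop = FALSE])   # s -> s+1
  right <- function(mat) cbind(0, mat[, -ncol(mat), drop = FALSE])  # m -> m+1
  for (i in seq_len(N)) {
    tab <- tab + ws[i] * (1 - r[i]) * down(tab) + ws[i] * r[i] * down(right(tab))
  }
  p <- tab[n_t + 1, ]
  p / sum(p)
}

# LLR, maximiser and null probability for every m = 0..n_t at once; the
# building block shared by the p-value, the observed statistic and the
# alpha-budget filter
.combined_all <- function(n_t, w, r, bound = 10) {
  st <- lapply(0:n_t, function(m) combined_llr(m, n_t, w, r, bound = bound))
  list(
    llr = vapply(st, `[[`, numeric(1), "llr"),
    delta = vapply(st, `[[`, numeric(1), "delta"),
    p_m = combined_null_m(n_t, w, r)
  )
}

.combined_p_from_all <- function(all, m_obs, tie_tol = 1e-9) {
  obs <- all$llr[m_obs + 1]
  tie <- .tie_band(all$llr, obs, tie_tol)
  sum(all$p_m[all$llr > obs & !tie]) + 0.5 * sum(all$p_m[tie])
}

#' Exact p-value of the combined test
#'
#' Enumerates the `n_t + 1` possible exclusive-tree counts, computes each
#' count's LLR via [combined_llr()] and its null probability via
#' [combined_null_m()], and applies the same half-tie (mid-p) rule as the
#' exact placement test.
#'
#' @inheritParams combined_llr
#' @param m_obs Observed exclusive-tree count.
#' @param tie_tol Relative tolerance for tied LLR statistics.
#' @return p-value.
#' @export
p_combined_exact <- function(m_obs, n_t, w, r, bound = 10, tie_tol = 1e-9) {
  if (m_obs < 0 || m_obs > n_t) abort("m_obs must lie between 0 and n_t.")
  .combined_p_from_all(.combined_all(n_t, w, r, bound = bound), m_obs, tie_tol)
}

# smallest achievable combined p over the n_t + 1 outcomes (alpha budgeting)
.combined_min_p <- function(n_t, w, r, bound = 10, tie_tol = 1e-9) {
  all <- .combined_all(n_t, w, r, bound = bound)
  top <- max(all$llr)
  tie <- .tie_band(all$llr, top, tie_tol)
  0.5 * sum(all$p_m[tie])
}

#' Fisher's-method combination of placement and occurrence p-values
#'
#' The placement and occurrence tests are independent under the null, so
#' their p-values can be merged with Fisher's method. Provided as a secondary
#' comparison to the joint combined test, which shares a single shift
#' parameter instead.
#'
#' @param p_placement,p_occurrence Marginal p-values.
#' @return Combined p-value (chi-squared with 4 degrees of freedom).
#' @export
fisher_combine <- function(p_placement, p_occurrence) {
  pchisq(-2 * (log(p_placement) + log(p_occurrence)), df = 4, lower.tail = FALSE)
}

#' Run the combined test on a collected gene pair
#'
#' Uses the exclusive-tree count `m = n_cx + n_s` over all `n_t` patients
#' carrying the pair (fractional posterior outcomes binarised at
#' `O >= 0.5`), with the exact null over `m`. Fisher's-method combination of
#' the two marginal tests is reported alongside as `p_fisher` when both
#' marginals are computable.
#'
#' @inheritParams test_occurrence
#' @param exact_max_n Enumeration limit passed to the marginal placement test
#'   used only for `p_fisher`.
#' @return A `clonex_test` object with extra field `p_fisher`.
#' @export
test_combined <- function(obs, cohort, eligible_only = TRUE, bound = 10,
                          exact_max_n = 12, inf_tol = 1e-6) {
  if (obs$n_t == 0L) abort("pair occurs in no patient.")
  el <- .eligible_cohort(cohort, eligible_only)
  all <- .combined_all(obs$n_t, el$w, el$r, bound = bound)
  st <- list(delta = all$delta[obs$m + 1], llr = all$llr[obs$m + 1])
  p <- .combined_p_from_all(all, obs$m)
  p_fisher <- tryCatch({
    pp <- test_placement(obs, exact_max_n = exact_max_n, bound = bound)$p
    po <- test_occurrence(obs, cohort, eligible_only = eligible_only, bound = bound)$p
    fisher_combine(pp, po)
  }, error = function(e) NA_real_)
  .new_test(obs, method = "combined", delta = st$delta, llr = st$llr, p = p,
            exact_used = TRUE, bound = bound, extra = list(p_fisher = p_fisher))
}
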
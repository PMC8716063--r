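#' Elementary symmetric polynomial by dynamic programming
#'
#' `esp(w, k)` is the sum over all k-subsets of the products of the selected
#' weights, i.e. the normalising constant of the weighted-sampling
#' (Fisher non-central hypergeometric) null for patient sets of size `k`.
#' Computed by the standard DP in `O(N k)` time rather than enumerating the
#' `choose(N, k)` subsets.
#'
#' @param w Non-negative weights.
#' @param k Subset size, `0 <= k <= length(w)`.
#' @return `e_k(w)`.
#' @export
#' @examples
#' esp(c(1, 2, 3), 2) # 1*2 + 1*3 + 2*3 = 11
esp <- function(w, k) {
  N <- length(w)
  if (k < 0 || k > N) abort("k must lie between 0 and length(w).")
  e <- c(1, numeric(k))
  for (wi in w) {
    if (k > 0) e[2:(k + 1)] <- e[2:(k + 1)] + wi * e[1:k]
  }
  e[k + 1]
}

# log e_k(w) with rescaling by max(w) so the DP stays inside double range
# for cohorts of hundreds of patients
.log_esp <- function(w, k) {
  if (k == 0L) return(0)
  s <- max(w)
  if (s == 0) return(-Inf)
  k * log(s) + log(esp(w / s, k))
}

#' Tilted patient weights under the occurrence alternative
#'
#' Under the null a gene pair lands in patient `i` with probability
#' proportional to the number of gene pairs the patient possesses, `w_i`.
#' Under the alternative, co-occurring placements get relative weight `rho`
#' and clonally exclusive placements `1 - rho`, giving
#' `w' = 2 w [rho (1 - r) + (1 - rho) r]` with `logit(rho) = delta`.
#' `delta = 0` (`rho = 1/2`) recovers the null weights.
#'
#' @param w Pair-count weights.
#' @param r Background exclusivity rates.
#' @param delta Occurrence shift on the logit scale.
#' @return Tilted weights.
#' @export
occurrence_alt_weights <- function(w, r, delta) {
  rho <- plogis(delta)
  2 * w * (rho * (1 - r) + (1 - rho) * r)
}

#' Log-probability of a selected patient set
#'
#' The probability that exactly the patients in `sel` exhibit the gene pair,
#' conditional on the set size, under the weighted-sampling null
#' (`delta = 0`) or a tilted alternative:
#' `log P(S) = sum_{i in S} log w'_i - log e_{|S|}(w')`.
#' Probabilities over all sets of the same size sum to one.
#'
#' @param sel Integer indices (or logical mask) of the selected patients.
#' @param w,r Cohort weights and background rates (all eligible patients).
#' @param delta Occurrence shift; 0 gives the null.
#' @return Log-probability (`-Inf` if a selected patient has zero weight).
#' @export
occurrence_log_prob <- function(sel, w, r, delta = 0) {
  if (is.logical(sel)) sel <- which(sel)
  k <- length(sel)
  if (k > length(w)) abort("selected set larger than the cohort.")
  wp <- occurrence_alt_weights(w, r, delta)
  if (any(wp[sel] == 0)) return(-Inf)
  sum(log(wp[sel])) - .log_esp(wp, k)
}

#' Occurrence likelihood-ratio test for a patient set
#'
#' Tests whether the identity of the patient set exhibiting a gene pair is
#' indicative of clonal co-occurrence or exclusivity: patients whose trees
#' favour exclusivity (higher `r`) receive more weight when `delta < 0`.
#' The set log-probability is maximised over `delta` in `[-bound, bound]`
#' and compared to the null (`delta = 0`); the p-value uses the chi-squared
#' approximation with one degree of freedom (enumerating all sets for an
#' exact version is prohibitive), and is therefore flagged approximate.
#'
#' Degenerate inputs — the whole cohort selected, or all background rates
#' equal (the tilt then cancels in the normaliser) — carry no information
#' and return an LLR of exactly 0.
#'
#' @inheritParams occurrence_log_prob
#' @param bound,inf_tol As in [placement_llr()].
#' @return List with `delta`, `llr` and `p`.
#' @export
occurrence_llr <- function(sel, w, r, bound = 10, inf_tol = 1e-6) {
  if (is.logical(sel)) sel <- which(sel)
  if (length(sel) < 1L) abort("the selected set must contain at least one patient.")
  if (length(sel) == length(w) || diff(range(r)) == 0) {
    return(list(delta = 0, llr = 0, p = 1))
  }
  f <- function(d) occurrence_log_prob(sel, w, r, d)
  opt <- optimize(f, c(-bound, bound), maximum = TRUE, tol = 1e-8)
  cand_x <- c(opt$maximum, -bound, bound, 0)
  cand_f <- c(opt$objective, f(-bound), f(bound), f(0))
  best <- which.max(cand_f)
  llr <- max(0, 2 * (cand_f[best] - f(0)))
  delta <- if (llr == 0) 0 else .report_delta(cand_x[best], bound, inf_tol)
  list(delta = delta, llr = llr, p = p_placement_chisq(llr))
}

#' Run the occurrence test on a collected gene pair
#'
#' The eligible cohort for the weighted-sampling null is, by default, all
#' patients possessing at least one gene pair (`w >= 1`); patients with fewer
#' than two genes can never exhibit a pair and carry zero selection
#' probability. Set `eligible_only = FALSE` to condition on the full cohort
#' instead (zero-weight patients then still contribute nothing).
#'
#' @param obs A `clonex_pair_obs` from [collect_pair()].
#' @param cohort The `clonex_cohort` the pair was collected from.
#' @param eligible_only Restrict the null to patients with `w >= 1`.
#' @inheritParams occurrence_llr
#' @return A `clonex_test` object.
#' @export
test_occurrence <- function(obs, cohort, eligible_only = TRUE, bound = 10,
                            inf_tol = 1e-6) {
  el <- .eligible_cohort(cohort, eligible_only)
  sel <- match(obs$patients$patient_id, el$patient_id)
  if (anyNA(sel)) abort("selected patients missing from the eligible cohort.")
  if (length(sel) == 0L) abort("empty patient set.")
  st <- occurrence_llr(sel, el$w, el$r, bound = bound, inf_tol = inf_tol)
  .new_test(obs, method = "occurrence", delta = st$delta, llr = st$llr,
            p = st$p, exact_used = FALSE, bound = bound)
}

# eligible patients for the occurrence/combined null; rates of patients whose
# trees have < 2 genes are undefined but such patients have w = 0 and drop out
.eligible_cohort <- function(cohort, eligible_only = TRUE) {
  el <- if (eligible_only) cohort[cohort$w >= 1, ] else cohort
  r <- el$r
  r[is.na(r)] <- 0
  list(patient_id = el$patient_id, w = as.numeric(el$w), r = r)
}
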
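test_that("the reduced combined LLR equals direct joint optimisation", {
  for (s in 1:8) {
    set.seed(s)
    N <- 6
    w <- sample(1:10, N, replace = TRUE)
    r <- runif(N, 0.05, 0.95)
    n_t <- sample(2:4, 1)
    S <- sample(N, n_t)
    O <- rbinom(n_t, 1, r[S])
    direct <- brute_combined_llr(S, O, w, r)
    reduced <- combined_llr(sum(O), n_t, w, r)$llr
    expect_equal(reduced, direct, tolerance = 1e-8)
  }
})

test_that("symmetric cohorts give a flat combined likelihood", {
  st <- combined_llr(2, 4, rep(3, 8), rep(0.5, 8))
  expect_equal(st$llr, 0, tolerance = 1e-8)
  # whole cohort selected with identical rates: degenerate, exactly zero
  expect_equal(combined_llr(1, 4, rep(2, 4), rep(0.3, 4))$llr, 0)
})

test_that("joint optimisation never exceeds the sum of the marginal LLRs", {
  set.seed(17)
  N <- 10
  w <- sample(2:12, N, replace = TRUE)
  r <- rbeta(N, 2, 3)
  for (s in 1:5) {
    set.seed(100 + s)
    n_t <- sample(3:6, 1)
    S <- sample(N, n_t)
    O <- rbinom(n_t, 1, r[S])
    inf <- r[S] > 0 & r[S] < 1
    llr_p <- placement_llr(r[S][inf], O[inf])$llr
    llr_o <- occurrence_llr(S, w, r)$llr
    llr_c <- combined_llr(sum(O), n_t, w, r)$llr
    expect_lte(llr_c, llr_p + llr_o + 1e-6)
  }
})

test_that("the null distribution of m matches brute-force enumeration", {
  for (s in 1:5) {
    set.seed(s)
    N <- sample(5:8, 1)
    w <- stats::rgamma(N, 2) + 0.2
    r <- runif(N)
    n_t <- sample(2:(N - 1), 1)
    dp <- combined_null_m(n_t, w, r)
    expect_equal(sum(dp), 1, tolerance = 1e-12)
    expect_equal(dp, brute_null_m(n_t, w, r), tolerance = 1e-10)
  }
  # no exclusivity anywhere: all mass on m = 0
  expect_equal(combined_null_m(3, rep(2, 6), rep(0, 6)),
               c(1, 0, 0, 0))
  # exchangeable cohort: binomial
  expect_equal(combined_null_m(4, rep(5, 9), rep(0.35, 9)),
               stats::dbinom(0:4, 4, 0.35), tolerance = 1e-12)
})

test_that("combined exact p-values obey ties, simulation, and monotonicity", {
  # single carrier in a symmetric cohort: both outcomes tie at 1/2
  expect_equal(p_combined_exact(0, 1, rep(2, 5), rep(0.5, 5)), 0.5)
  expect_equal(p_combined_exact(1, 1, rep(2, 5), rep(0.5, 5)), 0.5)

  set.seed(23)
  N <- 6
  w <- sample(1:9, N, replace = TRUE)
  r <- runif(N, 0.1, 0.9)
  n_t <- 3
  # simulation oracle: weighted set sampling then Bernoulli placements
  subs <- utils::combn(N, n_t)
  set_pr <- apply(subs, 2, function(s) prod(w[s]))
  set_pr <- set_pr / sum(set_pr)
  sims <- 20000
  m_sim <- vapply(seq_len(sims), function(i) {
    s <- subs[, sample(ncol(subs), 1, prob = set_pr)]
    sum(rbinom(n_t, 1, r[s]))
  }, numeric(1))
  p_emp <- tabulate(m_sim + 1, nbins = n_t + 1) / sims
  p_dp <- combined_null_m(n_t, w, r)
  expect_lt(max(abs(p_emp - p_dp)), 4 * max(sqrt(p_dp * (1 - p_dp) / sims)) + 1e-3)

  # p is non-increasing in the LLR of the observed count
  llr_m <- vapply(0:n_t, function(m) combined_llr(m, n_t, w, r)$llr, numeric(1))
  p_m <- vapply(0:n_t, function(m) p_combined_exact(m, n_t, w, r), numeric(1))
  ord <- order(llr_m)
  expect_true(all(diff(p_m[ord]) <= 1e-12))
})

test_that("the combined mid-p has null expectation one half", {
  set.seed(31)
  N <- 12
  w <- sample(3:20, N, replace = TRUE)
  r <- rbeta(N, 2, 3)
  n_t <- 5
  all_p <- vapply(0:n_t, function(m) p_combined_exact(m, n_t, w, r), numeric(1))
  p_m <- combined_null_m(n_t, w, r)
  expect_equal(sum(all_p * p_m), 0.5, tolerance = 1e-9)
})

test_that("Fisher combination and the combined test run on collected pairs", {
  expect_equal(fisher_combine(1, 1), 1)
  expect_lt(fisher_combine(0.01, 0.01), 0.01)

  cohort <- count_cohort(n_excl = 6, n_cooc = 1, n_l = 2, n_s = 2,
                         extra = list(linear_tree("B1", c("A", "B")),
                                      star_tree("B2", c("A", "B", "C"))))
  obs <- collect_pair(cohort, "J", "K")
  tst <- test_combined(obs, cohort)
  expect_s3_class(tst, "clonex_test")
  expect_equal(tst$m, obs$n_cx + obs$n_s)
  expect_gte(tst$llr, 0)
  expect_true(is.numeric(tst$p_fisher))
  expect_lt(tst$delta, 0)
})
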
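test_that("logit shifts move rates as published and fix the endpoints", {
  expect_equal(round(shift_rate(0.40, -4), 2), 0.97)
  expect_equal(round(shift_rate(0.40, -3), 2), 0.93)
  r <- c(0, 0.2, 0.5, 0.8, 1)
  expect_equal(shift_rate(r, 0), r)
  expect_equal(shift_rate(c(0, 1), -7), c(0, 1)) # uninformative fixed points
  expect_error(shift_rate(1.2, 0), "\\[0, 1\\]")
})

test_that("null log-likelihood sums Bernoulli terms and guards its domain", {
  expect_equal(loglik_placement_null(0.5, 1), log(0.5))
  expect_equal(loglik_placement_null(numeric(0), numeric(0)), 0)
  # fractional outcomes equal to the rates give the negative entropy sum
  r <- c(0.2, 0.4, 0.7)
  expect_equal(loglik_placement_null(r, r),
               sum(r * log(r) + (1 - r) * log(1 - r)))
  expect_error(loglik_placement_null(c(0, 0.5), c(1, 1)), "uninformative")
})

test_that("placement LLR matches closed forms and an independent optimiser", {
  # symmetric two-patient case: maximum sits at delta = 0
  st <- placement_llr(c(0.5, 0.5), c(1, 0))
  expect_equal(st$llr, 0, tolerance = 1e-8)

  # single patient at the bound: llr = 2 (log sigma(10) - log 0.5)
  st1 <- placement_llr(0.5, 1, bound = 10)
  expect_equal(st1$llr, 2 * (log(plogis(10)) - log(0.5)), tolerance = 1e-7)
  expect_identical(st1$delta, -Inf)

  # all-exclusive outcomes push the shift to the exclusivity bound
  st2 <- placement_llr(c(0.3, 0.6, 0.4), c(1, 1, 1))
  expect_identical(st2$delta, -Inf)

  # random instances against stats::optimize, and permutation invariance
  for (s in 1:10) {
    set.seed(s)
    n <- sample(2:8, 1)
    r <- runif(n, 0.05, 0.95)
    o <- rbinom(n, 1, r)
    mine <- placement_llr(r, o)
    eta <- qlogis(r)
    f <- function(d) sum(o * log(plogis(eta - d)) + (1 - o) * log(plogis(d - eta)))
    op <- optimize(f, c(-10, 10), maximum = TRUE, tol = 1e-10)
    expect_equal(mine$llr, 2 * (max(op$objective, f(-10), f(10)) - f(0)),
                 tolerance = 1e-7)
    expect_gte(mine$llr, 0)
    perm <- sample(n)
    expect_equal(placement_llr(r[perm], o[perm])$llr, mine$llr, tolerance = 1e-9)
  }
})

test_that("chi-squared p-values follow the one-df upper tail", {
  expect_equal(p_placement_chisq(0), 1)
  expect_equal(p_placement_chisq(stats::qchisq(0.95, 1)), 0.05)
  expect_equal(p_placement_chisq(1e6), 0)
  expect_error(p_placement_chisq(-1), "negative")
})

test_that("exact placement p equals brute-force pattern enumeration", {
  # half-tie symmetry cases
  expect_equal(p_placement_exact(0.5, 1), 0.5)
  expect_equal(p_placement_exact(0.5, 0), 0.5)
  expect_equal(p_placement_exact(c(0.5, 0.5), c(1, 1)), 0.25)

  for (s in 1:10) {
    set.seed(40 + s)
    n <- sample(2:6, 1)
    r <- runif(n, 0.05, 0.95)
    o <- rbinom(n, 1, r)
    expect_equal(p_placement_exact(r, o), brute_placement(r, o)$p,
                 tolerance = 1e-9)
  }

  expect_error(p_placement_exact(rep(0.4, 13), rep(1, 13), exact_max_n = 12),
               "chi-squared or Monte-Carlo")
  expect_error(p_placement_exact(c(0.4, 0.4), c(0.5, 1)), "binary")
})

test_that("pattern probabilities conserve mass", {
  for (s in 1:5) {
    set.seed(60 + s)
    r <- runif(sample(2:10, 1), 0.01, 0.99)
    expect_equal(sum(clonex:::.pb_dist(r)), 1, tolerance = 1e-12)
    if (length(r) <= 6) {
      expect_equal(sum(brute_placement(r, rbinom(length(r), 1, r))$prob), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("Monte-Carlo p-values converge to the exact test as noise vanishes", {
  set.seed(5)
  r <- runif(3, 0.2, 0.8)
  o <- rbinom(3, 1, r)
  pe <- p_placement_exact(r, o)
  pm <- p_placement_mc(r, o, nu = 1e8, M = 20000, seed = 42)
  expect_lt(abs(pm - pe), 3 * sqrt(pe * (1 - pe) / 20000) + 1e-3)

  # determinism and degenerate M
  expect_identical(p_placement_mc(r, o, seed = 7, M = 500),
                   p_placement_mc(r, o, seed = 7, M = 500))
  expect_true(p_placement_mc(r, o, M = 1, seed = 1) %in% c(0, 1))
})

test_that("minimum possible p bounds every achievable p", {
  expect_equal(min_possible_p(0.5), 0.5)

  # all r = 0.4: the most extreme outcome is all-exclusive
  r4 <- rep(0.4, 4)
  expect_equal(min_possible_p(r4), p_placement_exact(r4, rep(1, 4)),
               tolerance = 1e-12)

  for (s in 1:8) {
    set.seed(80 + s)
    n <- sample(1:6, 1)
    r <- runif(n, 0.05, 0.95)
    o <- rbinom(n, 1, r)
    expect_lte(min_possible_p(r), p_placement_exact(r, o) + 1e-12)
  }
})

test_that("mid-p exact p-values have null expectation one half", {
  set.seed(99)
  n <- 5
  reps <- 4000
  rmat <- matrix(rbeta(n * reps, 2, 3), nrow = n)
  omat <- matrix(rbinom(n * reps, 1, rmat), nrow = n)
  p <- clonex:::.p_exact_batch(rmat, omat)
  se <- stats::sd(p) / sqrt(reps)
  expect_lt(abs(mean(p) - 0.5), 3 * se)
})

test_that("chi-squared and exact null p-values converge as n grows", {
  set.seed(123)
  ks_dist <- vapply(c(4, 12), function(n) {
    reps <- 800
    rmat <- matrix(rbeta(n * reps, 2, 3), nrow = n)
    omat <- matrix(rbinom(n * reps, 1, rmat), nrow = n)
    pe <- clonex:::.p_exact_batch(rmat, omat)
    pc <- clonex:::.p_chisq_batch(rmat, omat)
    suppressWarnings(stats::ks.test(pe, pc)$statistic)
  }, numeric(1))
  expect_lt(ks_dist[2], ks_dist[1])
})

test_that("the placement test object reports counts and method flags", {
  cohort <- count_cohort(n_excl = 4, n_cooc = 1, n_l = 1, n_s = 1)
  obs <- collect_pair(cohort, "J", "K")
  tst <- test_placement(obs)
  expect_s3_class(tst, "clonex_test")
  expect_true(tst$exact_used)
  expect_equal(tst$n, 5)
  td <- tidy(tst)
  expect_equal(td$gene_pair, "J_K")
  expect_lt(td$delta, 0) # exclusivity-enriched
  # uninformative-only pair cannot be tested
  lin <- as_cohort(list(linear_tree("L1"), linear_tree("L2")))
  expect_error(test_placement(collect_pair(lin, "J", "K")), "no informative")
})
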
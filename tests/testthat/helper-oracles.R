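# Shared fixtures and brute-force oracles, all computed in code at test time.

# compact tree builder: edges as "child<parent" strings, genes as named list
make_tree <- function(..., genes = list(), patient = "P1", tree = "T1",
                      freq = NULL) {
  edges <- c(...)
  child <- sub("<.*$", "", edges)
  parent <- sub("^.*<", "", edges)
  parent[parent == "-"] <- NA_character_
  clonal_tree(patient, tree, stats::setNames(parent, child), genes,
              clone_freq = freq)
}

# an informative branched tree where `pair` sits on sibling branches
# (exclusive) or in one lineage (co-occurring); a third gene keeps the
# background rate strictly between 0 and 1
excl_tree <- function(patient, pair = c("J", "K"), other = "X") {
  make_tree("r<-", "c1<r", "c2<c1", "c3<c1", patient = patient,
            genes = stats::setNames(list(other, pair[1], pair[2]),
                                    c("c1", "c2", "c3")))
}

cooc_tree <- function(patient, pair = c("J", "K"), other = "X") {
  make_tree("r<-", "c1<r", "c2<c1", "c3<c1", patient = patient,
            genes = stats::setNames(list(pair[1], pair[2], other),
                                    c("c1", "c2", "c3")))
}

linear_tree <- function(patient, genes = c("J", "K")) {
  ids <- paste0("c", seq_along(genes))
  edges <- paste0(ids, "<", c("-", ids[-length(ids)]))
  do.call(make_tree, c(as.list(edges), list(
    patient = patient, genes = stats::setNames(as.list(genes), ids)
  )))
}

star_tree <- function(patient, genes = c("J", "K", "X")) {
  ids <- paste0("c", seq_along(genes))
  do.call(make_tree, c(as.list(c("r<-", paste0(ids, "<r"))), list(
    patient = patient, genes = stats::setNames(as.list(genes), ids)
  )))
}

# cohort shaped like a published count row: n_t carriers of pair (J, K) of
# which n_excl exclusive-informative, n_cooc co-occurring-informative,
# n_l linear and n_s star
count_cohort <- function(n_excl = 7, n_cooc = 1, n_l = 3, n_s = 4,
                         extra = list()) {
  trees <- c(
    lapply(seq_len(n_excl), function(i) excl_tree(sprintf("E%02d", i))),
    lapply(seq_len(n_cooc), function(i) cooc_tree(sprintf("C%02d", i))),
    lapply(seq_len(n_l), function(i) linear_tree(sprintf("L%02d", i))),
    lapply(seq_len(n_s), function(i) star_tree(sprintf("S%02d", i))),
    extra
  )
  as_cohort(trees)
}

# brute-force exact placement test by full 2^n pattern enumeration with
# stats::optimize as an independent maximiser
brute_placement <- function(rates, outcomes, bound = 10, tie_tol = 1e-7) {
  n <- length(rates)
  eta <- qlogis(rates)
  llr <- prob <- numeric(2^n)
  for (b in 0:(2^n - 1)) {
    bits <- (b %/% 2^(0:(n - 1))) %% 2
    ll <- function(d) {
      sum(bits * log(plogis(eta - d)) + (1 - bits) * log(plogis(d - eta)))
    }
    op <- optimize(ll, c(-bound, bound), maximum = TRUE, tol = 1e-10)
    llr[b + 1] <- 2 * (max(op$objective, ll(-bound), ll(bound)) - ll(0))
    prob[b + 1] <- prod(rates^bits * (1 - rates)^(1 - bits))
  }
  obs <- llr[sum(outcomes * 2^(0:(n - 1))) + 1]
  tie <- abs(llr - obs) <= tie_tol * max(1, abs(obs))
  list(p = sum(prob[llr > obs & !tie]) + 0.5 * sum(prob[tie]),
       llr = llr, prob = prob)
}

# brute-force elementary symmetric polynomial over explicit subsets
brute_esp <- function(w, k) {
  if (k == 0) return(1)
  sum(apply(utils::combn(length(w), k), 2, function(s) prod(w[s])))
}

# brute-force null distribution of the exclusive-tree count: enumerate all
# size-n_t subsets and all 2^n_t exclusivity patterns within each
brute_null_m <- function(n_t, w, r) {
  subs <- utils::combn(length(w), n_t)
  z <- brute_esp(w, n_t)
  out <- numeric(n_t + 1)
  for (ci in seq_len(ncol(subs))) {
    s <- subs[, ci]
    ps <- prod(w[s]) / z
    for (b in 0:(2^n_t - 1)) {
      bits <- (b %/% 2^(0:(n_t - 1))) %% 2
      out[sum(bits) + 1] <- out[sum(bits) + 1] +
        ps * prod(r[s]^bits * (1 - r[s])^(1 - bits))
    }
  }
  out
}

# direct optimisation of the full joint occurrence-plus-placement
# log-likelihood (selected set S, outcomes O), an independent implementation
# of the combined statistic
brute_combined_llr <- function(S, O, w, r, bound = 10) {
  n_t <- length(S)
  joint <- function(d) {
    rho <- plogis(d)
    wp <- 2 * w * (rho * (1 - r) + (1 - rho) * r)
    dd <- rho * (1 - r[S]) + (1 - rho) * r[S]
    sum(log(wp[S]) + O * log((1 - rho) * r[S] / dd) +
          (1 - O) * log(rho * (1 - r[S]) / dd)) -
      (n_t * log(max(wp)) + log(brute_esp(wp / max(wp), n_t)))
  }
  op <- optimize(joint, c(-bound, bound), maximum = TRUE, tol = 1e-10)
  2 * (max(op$objective, joint(-bound), joint(bound)) - joint(0))
}
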
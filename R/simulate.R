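#' Draw background exclusivity rates from the null beta model
#'
#' The null rate distribution is `Beta(2, 3)` (mean 0.4), chosen to resemble
#' the background clonal exclusivity rates seen in real single-cell tumour
#' cohorts.
#'
#' @param n Number of rates.
#' @param beta_a,beta_b Beta shape parameters (defaults 2 and 3).
#' @param seed Optional seed.
#' @return Numeric vector of rates in `(0, 1)`.
#' @export
sample_rates <- function(n, beta_a = 2, beta_b = 3, seed = NULL) {
  draw <- function() rbeta(n, beta_a, beta_b)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Draw binary exclusivity outcomes at (optionally shifted) rates
#'
#' Outcomes are Bernoulli at `shift_rate(r, delta)`: `delta = 0` is the null,
#' negative `delta` plants exclusivity enrichment.
#'
#' @param rates Background rates in `(0, 1)`.
#' @param delta Effect size on the logit scale.
#' @param seed Optional seed.
#' @return Integer 0/1 vector.
#' @export
simulate_outcomes <- function(rates, delta = 0, seed = NULL) {
  draw <- function() rbinom(length(rates), 1L, shift_rate(rates, delta))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# uniform ordered binary tree shape with n nodes by the Catalan-weighted
# recursive split; returns parent index vector (root = node 1, parent 0)
.rand_btree_parent <- function(n) {
  cat_n <- vapply(0:n, function(k) choose(2 * k, k) / (k + 1), numeric(1))
  parent <- integer(n)
  nxt <- 1L
  gen <- function(size, par) {
    if (size == 0L) return(invisible())
    id <- nxt
    nxt <<- nxt + 1L
    parent[id] <<- par
    sizes <- 0:(size - 1)
    pr <- cat_n[sizes + 1] * cat_n[size - sizes] # left-subtree size weights
    left <- sample.int(size, 1, prob = pr) - 1L
    gen(left, id)
    gen(size - 1L - left, id)
  }
  gen(n, 0L)
  parent
}

#' Generate a uniform random binary clone tree with random mutation placement
#'
#' Draws a rooted binary tree shape uniformly at random (Catalan-weighted
#' recursive construction) with `inner_branches` clones, then assigns each of
#' `mutations` labels to a branch uniformly at random with replacement. Every
#' clone corresponds to one branch, so the tree yields `inner_branches` clone
#' genotypes. Because the mutations are exchangeable under this construction,
#' collections of such trees form a null model with no clonal enrichment for
#' any designated pair.
#'
#' @param inner_branches Number of clones/branches (default 10).
#' @param mutations Number of mutation labels placed (default 20), named
#'   `g1, g2, ...`.
#' @param patient_id,tree_id Labels for the resulting tree.
#' @param seed Optional seed.
#' @return A [clonal_tree()].
#' @export
random_binary_tree <- function(inner_branches = 10, mutations = 20,
                               patient_id = "P1", tree_id = "T1", seed = NULL) {
  stopifnot(inner_branches >= 1, mutations >= 0)
  draw <- function() {
    par_idx <- .rand_btree_parent(inner_branches)
    ids <- as.character(seq_len(inner_branches))
    parent <- stats::setNames(ifelse(par_idx == 0L, NA_character_,
                                     as.character(par_idx)), ids)
    loc <- sample.int(inner_branches, mutations, replace = TRUE)
    bg <- split(sprintf("g%d", seq_len(mutations)), factor(loc, levels = seq_len(inner_branches)))
    names(bg) <- ids
    clonal_tree(patient_id, tree_id, parent, bg)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Exact placement p-values for many replicates at once. rmat/omat: n x R
# matrices of rates and binary outcomes. The per-replicate LLR depends on an
# outcome pattern only through its exclusive count (see .placement_llr_by_k),
# so each replicate needs n + 1 optimisations; replicates are packed into one
# wide vectorised golden-section sweep.
.p_exact_batch <- function(rmat, omat, bound = 10, tie_tol = 1e-9) {
  n <- nrow(rmat)
  R <- ncol(rmat)
  K <- n + 1L
  eta <- qlogis(rmat)
  ebig <- eta[, rep(seq_len(R), each = K), drop = FALSE]
  opt <- .max_gshift(ebig, rep(0:n, R), bound = bound)
  g0 <- .colSums(plogis(-eta, log.p = TRUE), n, R)
  llr <- matrix(pmax(0, 2 * (opt$value - rep(g0, each = K))), nrow = K)
  obs_k <- .colSums(omat, n, R) + 1
  vapply(seq_len(R), function(j) {
    lk <- llr[, j]
    pk <- .pb_dist(rmat[, j])
    ob <- lk[obs_k[j]]
    tie <- .tie_band(lk, ob, tie_tol)
    sum(pk[lk > ob & !tie]) + 0.5 * sum(pk[tie])
  }, numeric(1))
}

# chi-squared placement p-values for many replicates at once
.p_chisq_batch <- function(rmat, omat, bound = 10) {
  n <- nrow(rmat)
  R <- ncol(rmat)
  l0 <- .colSums(omat * log(rmat) + (1 - omat) * log1p(-rmat), n, R)
  opt <- .max_loglik_shift(qlogis(rmat), omat, bound = bound)
  p_placement_chisq(pmax(0, 2 * (opt$value - l0)))
}

#' Null calibration study of the placement test
#'
#' Simulates `reps` gene pairs under the null — rates drawn from
#' `Beta(beta_a, beta_b)` and outcomes Bernoulli at those rates (or at rates
#' shifted by `delta`, for power runs) — and computes the placement p-value
#' with the requested variant. Under the null a calibrated test rejects at
#' level `alpha` in at most a fraction `alpha` of replicates.
#'
#' @param n Patients per simulated pair.
#' @param reps Number of replicates.
#' @param test `"exact"`, `"chisq"` or `"mc"` (Monte-Carlo smoothed).
#' @param delta Effect size (0 = null).
#' @param alpha Significance level used for the rejection-rate summary.
#' @param nu,M Smoothing parameters for the `"mc"` variant.
#' @inheritParams sample_rates
#' @param bound Optimisation bound.
#' @return A `clonex_calibration` tibble with columns `rep` and `p`;
#'   attributes carry the settings, and [glance()] summarises the rejection
#'   rate with its binomial standard error.
#' @export
run_calibration <- function(n, reps = 1000, test = c("exact", "chisq", "mc"),
                            delta = 0, beta_a = 2, beta_b = 3, alpha = 0.05,
                            nu = 10, M = 1000, bound = 10, seed = NULL) {
  test <- match.arg(test)
  run <- function() {
    rmat <- matrix(rbeta(n * reps, beta_a, beta_b), nrow = n)
    rmat <- pmin(pmax(rmat, 1e-12), 1 - 1e-12)
    omat <- matrix(rbinom(n * reps, 1L, shift_rate(rmat, delta)), nrow = n)
    p <- switch(test,
      exact = .p_exact_batch(rmat, omat, bound = bound),
      chisq = .p_chisq_batch(rmat, omat, bound = bound),
      mc = vapply(seq_len(reps), function(j) {
        p_placement_mc(rmat[, j], omat[, j], nu = nu, M = M, bound = bound)
      }, numeric(1))
    )
    tibble::tibble(rep = seq_len(reps), p = p)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out,
            class = c("clonex_calibration", class(out)),
            test = test, n = n, delta = delta, alpha = alpha,
            rejection = mean(out$p <= alpha))
}

#' Power study of the exact placement test
#'
#' For each combination of effect size and sample size, simulates gene pairs
#' under the alternative (rates `Beta(beta_a, beta_b)` shifted by `delta` on
#' the logit scale) and reports the fraction of replicates whose exact
#' placement p-value falls at or below `alpha`.
#'
#' @param deltas Grid of effect sizes.
#' @param ns Grid of patient counts per pair.
#' @param reps Replicates per grid cell.
#' @inheritParams run_calibration
#' @return Tibble with columns `delta`, `n`, `reps`, `power`, `se`.
#' @export
run_power <- function(deltas, ns, reps = 1000, beta_a = 2, beta_b = 3,
                      alpha = 0.05, bound = 10, seed = NULL) {
  run <- function() {
    grid <- tidyr::expand_grid(delta = deltas, n = ns)
    purrr::pmap_dfr(grid, function(delta, n) {
      cal <- run_calibration(n, reps = reps, test = "exact", delta = delta,
                             beta_a = beta_a, beta_b = beta_b, alpha = alpha,
                             bound = bound)
      pow <- mean(cal$p <= alpha)
      tibble::tibble(delta = delta, n = n, reps = reps, power = pow,
                     se = sqrt(pow * (1 - pow) / reps))
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Confounding study: naive clone-level tests versus the placement test
#'
#' Generates `sets` collections of `trees_per_set` uniform random binary
#' trees with mutations placed uniformly (see [random_binary_tree()]); the
#' mutations are exchangeable, so there is no clonal enrichment and any
#' designated pair is a null case. For each set the naive independence tests
#' are run on the pooled clone contingency table, and the placement test
#' (chi-squared, exact and Monte-Carlo-smoothed) on the per-tree exclusivity
#' outcomes of the designated pair. The naive tests ignore the phylogenetic
#' dependence between clones of the same tree and reject far above the
#' nominal level, while the exact placement test stays calibrated.
#'
#' @param sets Number of simulated cohorts (default 400).
#' @param trees_per_set Trees (patients) per cohort (default 10).
#' @param inner_branches,mutations Tree-generation parameters (defaults 10
#'   and 20).
#' @inheritParams run_calibration
#' @return A `clonex_naive_comparison` tibble with columns `set`, `test`,
#'   `p`; [glance()] tabulates rejection rates at `alpha`.
#' @export
run_naive_comparison <- function(sets = 400, trees_per_set = 10,
                                 inner_branches = 10, mutations = 20,
                                 alpha = 0.05, nu = 10, M = 1000, bound = 10,
                                 seed = NULL) {
  pair <- c("g1", "g2") # mutations are exchangeable; any fixed pair is null
  run_one <- function(set) {
    trees <- lapply(seq_len(trees_per_set), function(t) {
      random_binary_tree(inner_branches, mutations,
                         patient_id = sprintf("S%dP%d", set, t),
                         tree_id = "T1")
    })
    tab <- matrix(0L, 2, 2)
    r <- o <- numeric(trees_per_set)
    for (t in seq_len(trees_per_set)) {
      g <- clone_genotypes(trees[[t]])
      hj <- g[pair[1], ] == 1L
      hk <- g[pair[2], ] == 1L
      tab <- tab + c(sum(hj & hk), sum(!hj & hk), sum(hj & !hk), sum(!hj & !hk))
      r[t] <- background_rate(trees[[t]])
      o[t] <- as.numeric(pair_relation(trees[[t]], pair[1], pair[2]) == "exclusive")
    }
    inf <- r > 0 & r < 1
    p_pl <- if (any(inf)) {
      c(
        chisq = p_placement_chisq(placement_llr(r[inf], o[inf], bound = bound)$llr),
        exact = p_placement_exact(r[inf], o[inf], bound = bound,
                                  exact_max_n = trees_per_set),
        mc = p_placement_mc(r[inf], o[inf], nu = nu, M = M, bound = bound)
      )
    } else {
      c(chisq = NA_real_, exact = NA_real_, mc = NA_real_)
    }
    tibble::tibble(
      set = set,
      test = c("fisher", "g_test", "log_or", "chisq", "exact", "mc"),
      p = c(fisher_p(tab), g_test_p(tab), log_or_z(tab)$p, unname(p_pl))
    )
  }
  run <- function() purrr::map_dfr(seq_len(sets), run_one)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out, class = c("clonex_naive_comparison", class(out)),
            alpha = alpha)
}

#' Plant a gene pair specification for [synth_cohort()]
#'
#' @param gene_j,gene_k Labels of the planted pair.
#' @param delta Planted effect size on the logit scale (negative =
#'   exclusivity enrichment).
#' @param n_patients Number of informative host patients carrying the pair.
#' @return A list understood by [synth_cohort()].
#' @export
planted_pair <- function(gene_j = "SIG1", gene_k = "SIG2", delta = -3,
                         n_patients = 10) {
  list(gene_j = gene_j, gene_k = gene_k, delta = delta, n_patients = n_patients)
}

# comparable = one clone lies on the other's root path (or same clone);
# returns a two-column matrix of clone-label pairs
.clone_pairs_by_relation <- function(tree, comparable = TRUE) {
  anc <- list()
  for (cl in tree$clones) {
    p <- tree$parent[[cl]]
    anc[[cl]] <- if (is.na(p)) cl else c(anc[[p]], cl)
  }
  prs <- t(combn(tree$clones, 2))
  comp <- apply(prs, 1, function(x) x[1] %in% anc[[x[2]]] || x[2] %in% anc[[x[1]]])
  same <- cbind(tree$clones, tree$clones)
  if (comparable) rbind(prs[comp, , drop = FALSE], same) else prs[!comp, , drop = FALSE]
}

#' Generate a synthetic cohort of clone trees
#'
#' Produces a cohort mixing linear, star and branched topologies — mirroring
#' the topology mixture of real single-cell tumour cohorts, where most trees
#' are linear — with background genes drawn from a common pool, and
#' optionally plants a gene pair with a chosen clonal exclusivity effect in a
#' set of informative (branched, mixed-rate) host patients. For each host the
#' exclusivity outcome is drawn as Bernoulli at the host's background rate
#' shifted by the planted `delta`, and the two genes are placed on
#' incomparable branches (exclusive) or on a common lineage (co-occurring)
#' accordingly.
#'
#' @param path Optional path: when given, the cohort is written there as the
#'   TSV edge-list schema understood by [read_cohort()], and the planted
#'   ground truth to `<path>.truth.tsv`.
#' @param n_patients Cohort size (default 40).
#' @param gene_pool Number of background gene labels (default 24).
#' @param genes_per_patient Background genes per patient (default 6).
#' @param p_linear,p_star Topology mixture; the rest are branched binary
#'   trees (defaults 0.55 and 0.05).
#' @param inner_branches Clones in branched trees (default 6).
#' @param planted Optional [planted_pair()] specification.
#' @param freq Add clone-frequency annotations (Dirichlet; default TRUE).
#' @param seed Optional seed; the emitted TSV is byte-reproducible for a
#'   fixed seed.
#' @return Invisibly, a list with the cohort (`clonex_cohort`), the edge-list
#'   tibble (`edges`) and the ground-truth tibble (`truth`, NULL when nothing
#'   is planted).
#' @export
synth_cohort <- function(path = NULL, n_patients = 40, gene_pool = 24,
                         genes_per_patient = 6, p_linear = 0.55, p_star = 0.05,
                         inner_branches = 6, planted = NULL, freq = TRUE,
                         seed = NULL) {
  run <- function() {
    pool <- sprintf("g%02d", seq_len(gene_pool))
    n_host <- if (is.null(planted)) 0L else planted$n_patients
    if (n_host > n_patients) abort("more planted hosts than patients.")
    trees <- vector("list", n_patients)
    host_idx <- seq_len(n_host)
    truth_rows <- list()
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%03d", i)
      genes <- sample(pool, genes_per_patient)
      if (i %in% host_idx) {
        # rejection-sample a branched tree with a mixed background rate
        repeat {
          tr <- .assign_genes_tree(pid, genes, "branched", inner_branches)
          rb <- background_rate(tr)
          if (rb > 0 && rb < 1) break
        }
        b <- rbinom(1L, 1L, shift_rate(rb, planted$delta))
        prs <- .clone_pairs_by_relation(tr, comparable = (b == 0L))
        pick <- prs[sample.int(nrow(prs), 1), ]
        bg <- tr$branch_genes
        bg[[pick[1]]] <- c(bg[[pick[1]]], planted$gene_j)
        bg[[pick[2]]] <- c(bg[[pick[2]]], planted$gene_k)
        tr <- clonal_tree(pid, "T1", tr$parent, bg)
        truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
          patient_id = pid, gene_j = planted$gene_j, gene_k = planted$gene_k,
          delta = planted$delta, background_rate = rb, exclusive = b == 1L
        )
      } else {
        u <- runif(1)
        topo <- if (u < p_linear) "linear" else if (u < p_linear + p_star) "star" else "branched"
        tr <- .assign_genes_tree(pid, genes, topo, inner_branches)
      }
      if (freq) {
        x <- stats::rgamma(length(tr$clones), 1)
        fr <- floor(1e6 * x / sum(x)) / 1e6
        tr$clone_freq <- stats::setNames(fr, tr$clones)
      }
      trees[[i]] <- tr
    }
    edges <- purrr::map_dfr(trees, function(t) {
      tibble::tibble(
        patient_id = t$patient_id, tree_id = t$tree_id, clone_id = t$clones,
        parent_id = ifelse(is.na(t$parent), "-", t$parent),
        genes = vapply(t$branch_genes, paste, character(1), collapse = ";"),
        freq = if (is.null(t$clone_freq)) NA_real_ else unname(t$clone_freq[t$clones])
      )
    })
    if (!freq) edges$freq <- NULL
    truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows) else NULL
    if (!is.null(path)) {
      readr::write_tsv(edges, path, progress = FALSE)
      if (!is.null(truth)) readr::write_tsv(truth, paste0(path, ".truth.tsv"), progress = FALSE)
    }
    invisible(list(cohort = as_cohort(trees), edges = edges, truth = truth))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# build one tree of the requested topology and spread genes over its branches
.assign_genes_tree <- function(pid, genes, topo, inner_branches) {
  k <- length(genes)
  if (topo == "linear") {
    ids <- as.character(seq_len(k))
    parent <- stats::setNames(c(NA_character_, head(ids, -1)), ids)
    bg <- stats::setNames(as.list(genes), ids)
  } else if (topo == "star") {
    ids <- as.character(0:k)
    parent <- stats::setNames(c(NA_character_, rep("0", k)), ids)
    bg <- stats::setNames(c(list(character(0)), as.list(genes)), ids)
  } else {
    par_idx <- .rand_btree_parent(inner_branches)
    ids <- as.character(seq_len(inner_branches))
    parent <- stats::setNames(ifelse(par_idx == 0L, NA_character_,
                                     as.character(par_idx)), ids)
    loc <- sample.int(inner_branches, k, replace = TRUE)
    bg <- split(genes, factor(loc, levels = seq_len(inner_branches)))
    names(bg) <- ids
  }
  clonal_tree(pid, "T1", parent, bg)
}
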
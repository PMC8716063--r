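#' Clone-level contingency table for a gene pair
#'
#' Pools the clones of every patient carrying the pair and cross-classifies
#' them by presence of each gene (inherited or acquired on the clone's own
#' branch). This deliberately ignores the phylogenetic dependence between
#' clones of the same tree and is used only to demonstrate how badly naive
#' independence tests are confounded on tree-structured data.
#'
#' @param cohort A `clonex_cohort`.
#' @param gene_j,gene_k Gene labels.
#' @param trees Use the `"first"` tree of each patient (default) or pool
#'   `"all"` posterior trees.
#' @return 2x2 integer matrix; rows = gene_j present/absent, columns =
#'   gene_k present/absent.
#' @export
clone_table <- function(cohort, gene_j, gene_k, trees = c("first", "all")) {
  trees <- match.arg(trees)
  tab <- matrix(0L, 2, 2, dimnames = list(
    c("j_present", "j_absent"), c("k_present", "k_absent")
  ))
  found <- FALSE
  for (ts in cohort$trees) {
    keep <- purrr::keep(ts, function(t) {
      g <- tree_genes(t)
      gene_j %in% g && gene_k %in% g
    })
    if (length(keep) == 0L) next
    found <- TRUE
    if (trees == "first") keep <- keep[1]
    for (t in keep) {
      g <- clone_genotypes(t)
      hj <- g[gene_j, ] == 1L
      hk <- g[gene_k, ] == 1L
      tab[1, 1] <- tab[1, 1] + sum(hj & hk)
      tab[1, 2] <- tab[1, 2] + sum(hj & !hk)
      tab[2, 1] <- tab[2, 1] + sum(!hj & hk)
      tab[2, 2] <- tab[2, 2] + sum(!hj & !hk)
    }
  }
  if (!found) abort(sprintf("pair %s_%s occurs in no patient.", gene_j, gene_k))
  tab
}

.degenerate_margins <- function(tab) {
  any(rowSums(tab) == 0) || any(colSums(tab) == 0)
}

#' Naive independence tests on a 2x2 clone table
#'
#' Standard tests applied to pooled clone genotypes: Fisher's exact test, the
#' G-test (likelihood-ratio chi-squared, 1 df, no Williams correction) and
#' the log odds ratio with the normal approximation. All p-values are
#' two-sided. `log_or_z` applies the Haldane-Anscombe correction (+0.5 on
#' every cell) whenever any cell is zero, and follows the convention that a
#' negative z-score indicates exclusivity (off-diagonal-heavy tables).
#' Tables with a zero row or column margin carry no information about
#' association and return `p = 1`.
#'
#' @param tab 2x2 contingency table from [clone_table()].
#' @return `fisher_p` and `g_test_p` return a p-value; `log_or_z` returns a
#'   list with `z` and `p`.
#' @export
fisher_p <- function(tab) {
  if (.degenerate_margins(tab)) return(1)
  stats::fisher.test(tab)$p.value
}

#' @rdname fisher_p
#' @export
g_test_p <- function(tab) {
  if (.degenerate_margins(tab)) return(1)
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  nz <- tab > 0
  g <- 2 * sum(tab[nz] * log(tab[nz] / expd[nz]))
  pchisq(max(0, g), df = 1, lower.tail = FALSE)
}

#' @rdname fisher_p
#' @export
log_or_z <- function(tab) {
  if (.degenerate_margins(tab)) return(list(z = 0, p = 1))
  t2 <- tab
  if (any(t2 == 0)) t2 <- t2 + 0.5
  lor <- log(t2[1, 1]) + log(t2[2, 2]) - log(t2[1, 2]) - log(t2[2, 1])
  se <- sqrt(sum(1 / t2))
  z <- lor / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Run the naive clone-level tests on a collected gene pair
#'
#' @param obs A `clonex_pair_obs` from [collect_pair()].
#' @param cohort The `clonex_cohort` the pair was collected from.
#' @param trees Passed to [clone_table()].
#' @return A `clonex_test` object whose headline p-value is the log-OR
#'   normal-approximation test, with `fisher_p`, `g_p` and `z` as extra
#'   fields.
#' @export
test_naive <- function(obs, cohort, trees = c("first", "all")) {
  tab <- clone_table(cohort, obs$gene_j, obs$gene_k, trees = trees)
  lz <- log_or_z(tab)
  .new_test(obs, method = "naive", delta = NA_real_, llr = NA_real_, p = lz$p,
            exact_used = FALSE, bound = NA_real_,
            extra = list(z = lz$z, fisher_p = fisher_p(tab), g_p = g_test_p(tab)))
}
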
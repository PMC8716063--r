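#' Tidy a single gene-pair test
#'
#' @param x A `clonex_test`.
#' @param ... Unused.
#' @return One-row tibble with the pair labels, the count columns (`n_t`,
#'   `n`, `n_cx`, `n_l`, `n_s`, `m`), the shift estimate `delta`, `llr`, `p`
#'   and the method flags.
#' @export
tidy.clonex_test <- function(x, ...) {
  base <- tibble::tibble(
    gene_pair = paste(x$gene_j, x$gene_k, sep = "_"),
    gene_j = x$gene_j, gene_k = x$gene_k,
    n_t = x$n_t, n = x$n, n_cx = x$n_cx, n_l = x$n_l, n_s = x$n_s, m = x$m,
    delta = x$delta, llr = x$llr, p = x$p,
    method = x$method, exact_used = x$exact_used, bound_hit = isTRUE(x$bound_hit)
  )
  extras <- x[setdiff(names(x), c(names(base), "bound"))]
  extras <- extras[vapply(extras, function(v) is.atomic(v) && length(v) == 1L, logical(1))]
  if (length(extras)) base <- dplyr::bind_cols(base, tibble::as_tibble(extras))
  base
}

#' @export
glance.clonex_test <- function(x, ...) {
  tibble::tibble(method = x$method, delta = x$delta, llr = x$llr, p = x$p)
}

#' Tidy the per-patient observations behind a gene pair
#'
#' @param x A `clonex_pair_obs`.
#' @param ... Unused.
#' @return The per-patient tibble (patient id, background rate, exclusivity
#'   outcome, informativeness).
#' @export
tidy.clonex_pair_obs <- function(x, ...) {
  x$patients
}

#' @export
glance.clonex_pair_obs <- function(x, ...) {
  tibble::tibble(
    gene_pair = paste(x$gene_j, x$gene_k, sep = "_"),
    n_t = x$n_t, n = x$n, n_cx = x$n_cx, n_l = x$n_l, n_s = x$n_s, m = x$m
  )
}

#' @export
tidy.clonex_results <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarise a cohort results table
#'
#' @param x A `clonex_results` tibble.
#' @param alpha Significance threshold on the BH-adjusted q-values.
#' @param ... Unused.
#' @return One-row tibble: method, pairs tested and removed, significant
#'   pairs at `alpha` split by sign of the shift.
#' @export
glance.clonex_results <- function(x, alpha = 0.05, ...) {
  removed <- attr(x, "removed")
  sig <- x$q <= alpha
  tibble::tibble(
    method = attr(x, "method"),
    n_pairs = nrow(x),
    n_removed = if (is.null(removed)) 0L else nrow(removed),
    n_sig = sum(sig),
    n_sig_exclusive = sum(sig & x$delta < 0),
    n_sig_cooccurring = sum(sig & x$delta > 0)
  )
}

#' @export
tidy.clonex_calibration <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarise a calibration run
#'
#' @param x A `clonex_calibration` tibble from [run_calibration()].
#' @param ... Unused.
#' @return One-row tibble with the variant, settings, rejection rate at the
#'   stored `alpha` and its binomial standard error.
#' @export
glance.clonex_calibration <- function(x, ...) {
  alpha <- attr(x, "alpha")
  rej <- mean(x$p <= alpha)
  tibble::tibble(
    test = attr(x, "test"), n = attr(x, "n"), delta = attr(x, "delta"),
    reps = nrow(x), alpha = alpha, rejection = rej,
    se = sqrt(rej * (1 - rej) / nrow(x)), mean_p = mean(x$p)
  )
}

#' @export
tidy.clonex_naive_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Rejection rates of the confounding study
#'
#' @param x A `clonex_naive_comparison` from [run_naive_comparison()].
#' @param ... Unused.
#' @return Tibble with one row per test: rejection rate at the stored alpha
#'   and its binomial standard error.
#' @export
glance.clonex_naive_comparison <- function(x, ...) {
  alpha <- attr(x, "alpha")
  x |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(
      reps = dplyr::n(),
      rejection = mean(.data$p <= alpha),
      se = sqrt(.data$rejection * (1 - .data$rejection) / .data$reps),
      .groups = "drop"
    )
}
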
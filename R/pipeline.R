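#' Enumerate candidate gene pairs in a cohort
#'
#' Lists unordered gene pairs carried by at least one patient, together with
#' the number of carriers and the number of *informative* carriers (patients
#' whose averaged background rate lies strictly between 0 and 1), and keeps
#' pairs with at least `min_informative` informative carriers. Pairs seen in
#' fewer informative patients carry too little placement signal to be
#' testable.
#'
#' @param cohort A `clonex_cohort`.
#' @param min_informative Minimum number of informative patients carrying
#'   both genes (default 4, i.e. `n > 3`); 0 keeps every observed pair.
#' @return Tibble with columns `gene_j`, `gene_k`, `n_carrier`,
#'   `n_informative`, sorted by decreasing `n_informative`.
#' @export
enumerate_pairs <- function(cohort, min_informative = 4) {
  inf <- !is.na(cohort$r) & cohort$r > 0 & cohort$r < 1
  carrier <- list()
  informative <- list()
  for (i in seq_len(nrow(cohort))) {
    g <- cohort$genes[[i]]
    if (length(g) < 2L) next
    prs <- combn(sort(g), 2)
    keys <- paste(prs[1, ], prs[2, ], sep = "\r")
    for (k in keys) {
      carrier[[k]] <- (carrier[[k]] %||% 0L) + 1L
      if (inf[i]) informative[[k]] <- (informative[[k]] %||% 0L) + 1L
    }
  }
  if (length(carrier) == 0L) {
    return(tibble::tibble(gene_j = character(0), gene_k = character(0),
                          n_carrier = integer(0), n_informative = integer(0)))
  }
  parts <- strsplit(names(carrier), "\r", fixed = TRUE)
  out <- tibble::tibble(
    gene_j = vapply(parts, `[`, character(1), 1),
    gene_k = vapply(parts, `[`, character(1), 2),
    n_carrier = unlist(carrier, use.names = FALSE),
    n_informative = vapply(names(carrier), function(k) informative[[k]] %||% 0L,
                           integer(1), USE.NAMES = FALSE)
  )
  out <- out[out$n_informative >= min_informative, ]
  dplyr::arrange(out, dplyr::desc(.data$n_informative), .data$gene_j, .data$gene_k)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper around `stats::p.adjust(p, "BH")`, provided so that the
#' adjustment used throughout the package is explicit and testable.
#'
#' @param p p-values.
#' @return Monotone step-up adjusted q-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Remove gene pairs that can never reach significance (alpha budgeting)
#'
#' For each pair, computes the minimum achievable p-value over all possible
#' outcomes given the background rates of its carrier patients (placement:
#' over the `2^n` exclusivity patterns; combined: over the `n_t + 1`
#' exclusive-tree counts). Pairs whose minimum exceeds `alpha` are removed
#' *before* testing so they do not dilute the multiple-testing correction.
#'
#' @param cohort A `clonex_cohort`.
#' @param pairs Tibble with columns `gene_j`, `gene_k` (e.g. from
#'   [enumerate_pairs()]).
#' @param alpha Significance level (default 0.05).
#' @param method `"placement"` or `"combined"`.
#' @param exact_max_n,bound,eligible_only Passed through to the tests.
#' @return List with `retained` and `removed` tibbles; both carry a `min_p`
#'   column.
#' @export
alpha_budget_filter <- function(cohort, pairs, alpha = 0.05,
                                method = c("placement", "combined"),
                                exact_max_n = 12, bound = 10,
                                eligible_only = TRUE) {
  method <- match.arg(method)
  el <- .eligible_cohort(cohort, eligible_only)
  min_p <- purrr::map2_dbl(pairs$gene_j, pairs$gene_k, function(j, k) {
    obs <- collect_pair(cohort, j, k)
    if (method == "placement") {
      rates <- obs$patients$r[obs$patients$informative]
      if (length(rates) == 0L || length(rates) > exact_max_n) return(NA_real_)
      min_possible_p(rates, bound = bound, exact_max_n = exact_max_n)
    } else {
      .combined_min_p(obs$n_t, el$w, el$r, bound = bound)
    }
  })
  pairs$min_p <- min_p
  keep <- is.na(min_p) | min_p <= alpha
  list(retained = pairs[keep, ], removed = pairs[!keep, ])
}

#' Test every eligible gene pair in a cohort
#'
#' The cohort-level pipeline: enumerate pairs carried by enough informative
#' patients, drop pairs that can never reach significance (alpha budgeting,
#' for the placement and combined methods), run the requested test on each
#' pair, adjust p-values with Benjamini-Hochberg, and rank by p-value
#' (ties broken by larger LLR).
#'
#' @param cohort A `clonex_cohort` from [read_cohort()] or [as_cohort()].
#' @param method `"combined"` (default), `"placement"`, `"occurrence"` or
#'   `"naive"`.
#' @param min_informative Pair-inclusion threshold (default 4 informative
#'   patients).
#' @param alpha Significance level used by the alpha-budget filter.
#' @param alpha_budget Apply the minimum-p filter (default TRUE; ignored for
#'   the occurrence and naive methods).
#' @param exact_max_n Exact/asymptotic switch for the placement test.
#' @param eligible_only Occurrence/combined null conditions on patients with
#'   at least one gene pair (default) or the full cohort.
#' @param bound Optimisation bound for the shift parameter.
#' @return A `clonex_results` tibble with columns `rank`, `gene_pair`,
#'   `gene_j`, `gene_k`, `n_t`, `n`, `n_cx`, `n_l`, `n_s`, `m`, `delta`,
#'   `llr`, `p`, `q`, `method`, `exact_used`, `bound_hit` (plus
#'   method-specific columns); pairs removed by the alpha budget are attached
#'   as `attr(, "removed")`.
#' @export
run_cohort <- function(cohort, method = c("combined", "placement", "occurrence", "naive"),
                       min_informative = 4, alpha = 0.05, alpha_budget = TRUE,
                       exact_max_n = 12, eligible_only = TRUE, bound = 10) {
  method <- match.arg(method)
  pairs <- enumerate_pairs(cohort, min_informative = min_informative)
  obs_list <- purrr::map2(pairs$gene_j, pairs$gene_k,
                          function(j, k) collect_pair(cohort, j, k))
  obs_list <- purrr::keep(obs_list, function(o) o$n_t > 0L)
  removed <- tibble::tibble(gene_j = character(0), gene_k = character(0),
                            min_p = numeric(0))
  # the combined-test statistics depend on the pair only through n_t, so one
  # computation per distinct n_t serves the filter and every test
  el <- .eligible_cohort(cohort, eligible_only)
  all_cache <- new.env(parent = emptyenv())
  get_all <- function(n_t) {
    key <- as.character(n_t)
    if (is.null(all_cache[[key]])) {
      all_cache[[key]] <- .combined_all(n_t, el$w, el$r, bound = bound)
    }
    all_cache[[key]]
  }
  if (alpha_budget && method %in% c("placement", "combined") &&
      length(obs_list) > 0L) {
    min_p <- vapply(obs_list, function(obs) {
      if (method == "placement") {
        rates <- obs$patients$r[obs$patients$informative]
        if (length(rates) == 0L || length(rates) > exact_max_n) return(NA_real_)
        min_possible_p(rates, bound = bound, exact_max_n = exact_max_n)
      } else {
        all <- get_all(obs$n_t)
        top <- max(all$llr)
        0.5 * sum(all$p_m[.tie_band(all$llr, top)])
      }
    }, numeric(1))
    drop <- !is.na(min_p) & min_p > alpha
    removed <- tibble::tibble(
      gene_j = vapply(obs_list[drop], `[[`, character(1), "gene_j"),
      gene_k = vapply(obs_list[drop], `[[`, character(1), "gene_k"),
      min_p = min_p[drop]
    )
    obs_list <- obs_list[!drop]
  }
  if (method == "placement") {
    obs_list <- purrr::keep(obs_list, function(o) o$n > 0L)
  }
  if (length(obs_list) == 0L) {
    warn("no gene pairs survive the filters; returning an empty table.")
    out <- tibble::tibble(rank = integer(0), gene_pair = character(0))
    return(structure(out, class = c("clonex_results", class(out)),
                     removed = removed, method = method))
  }
  rows <- purrr::map_dfr(obs_list, function(obs) {
    tst <- switch(method,
      placement = test_placement(obs, exact_max_n = exact_max_n, bound = bound),
      occurrence = test_occurrence(obs, cohort, eligible_only = eligible_only,
                                   bound = bound),
      combined = {
        all <- get_all(obs$n_t)
        p_fisher <- tryCatch({
          pp <- test_placement(obs, exact_max_n = exact_max_n, bound = bound)$p
          po <- test_occurrence(obs, cohort, eligible_only = eligible_only,
                                bound = bound)$p
          fisher_combine(pp, po)
        }, error = function(e) NA_real_)
        .new_test(obs, method = "combined", delta = all$delta[obs$m + 1],
                  llr = all$llr[obs$m + 1],
                  p = .combined_p_from_all(all, obs$m), exact_used = TRUE,
                  bound = bound, extra = list(p_fisher = p_fisher))
      },
      naive = test_naive(obs, cohort)
    )
    tidy(tst)
  })
  rows$q <- bh_adjust(rows$p)
  rows <- dplyr::arrange(rows, .data$p, dplyr::desc(.data$llr))
  rows <- dplyr::mutate(rows, rank = dplyr::row_number(), .before = 1)
  structure(rows, class = c("clonex_results", class(rows)),
            removed = removed, method = method)
}

#' Write a ranked results table to TSV
#'
#' Serialises infinite shifts as `"Inf"`/`"-Inf"` so the table round-trips
#' through plain text.
#'
#' @param results A `clonex_results` tibble.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  if ("delta" %in% names(out)) out$delta <- as.character(out$delta)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(results)
}
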
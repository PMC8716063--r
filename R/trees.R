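#' Construct a clone tree
#'
#' A clone tree is a rooted hierarchy of tumour clones for one patient sample.
#' Each non-root clone is reached by a branch, and `branch_genes` records the
#' genes mutated on the branch entering that clone. A clone's genotype is the
#' union of the branch genes along its root-to-clone path, so mutations are
#' inherited by all descendant clones.
#'
#' @param patient_id,tree_id Labels identifying the patient sample and the
#'   tree (patients may carry several posterior tree samples).
#' @param parent Named character vector mapping each clone label to its parent
#'   clone label; the root clone has parent `NA`.
#' @param branch_genes Named list mapping clone labels to character vectors of
#'   gene labels mutated on the branch entering that clone. Clones absent from
#'   the list carry no new mutations. A gene may appear on several branches
#'   (parallel evolution).
#' @param clone_freq Optional named numeric vector of clone fractions in
#'   `[0, 1]`; when present the values must sum to at most 1 (plus a small
#'   tolerance).
#'
#' @return An object of class `clonal_tree`: a list with elements
#'   `patient_id`, `tree_id`, `clones` (in root-first order), `parent`,
#'   `branch_genes` and `clone_freq`.
#' @export
#' @examples
#' clonal_tree("P1", "T1",
#'   parent = c(root = NA, c1 = "root", c2 = "root"),
#'   branch_genes = list(c1 = "FLT3", c2 = "NRAS")
#' )
clonal_tree <- function(patient_id, tree_id, parent, branch_genes = list(),
                        clone_freq = NULL) {
  clones <- names(parent)
  if (is.null(clones) || anyNA(clones) || anyDuplicated(clones)) {
    abort("`parent` must be a named vector with unique clone labels.")
  }
  parent <- as.character(parent)
  names(parent) <- clones
  root <- clones[is.na(parent)]
  if (length(root) != 1L) {
    abort(sprintf("tree %s/%s must have exactly one root clone, found %d.",
                  patient_id, tree_id, length(root)))
  }
  bad <- setdiff(parent[!is.na(parent)], clones)
  if (length(bad) > 0L) {
    abort(sprintf("tree %s/%s has unknown parent label(s): %s.",
                  patient_id, tree_id, paste(bad, collapse = ", ")))
  }
  ord <- .topo_order(parent, root)
  if (length(ord) != length(clones)) {
    abort(sprintf(
      "tree %s/%s has a cycle or disconnected clones (e.g. %s).",
      patient_id, tree_id, setdiff(clones, ord)[1]
    ))
  }
  if (length(branch_genes) > 0L) {
    unknown <- setdiff(names(branch_genes), clones)
    if (length(unknown) > 0L) {
      abort(sprintf("branch_genes refers to unknown clone(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
  }
  bg <- stats::setNames(vector("list", length(ord)), ord)
  for (cl in ord) {
    g <- branch_genes[[cl]]
    bg[[cl]] <- if (is.null(g)) character(0) else unique(as.character(g))
  }
  if (!is.null(clone_freq)) {
    unknown <- setdiff(names(clone_freq), clones)
    if (length(unknown) > 0L) {
      abort(sprintf("clone_freq refers to unknown clone(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
    if (any(clone_freq < 0 | clone_freq > 1, na.rm = TRUE)) {
      abort("clone_freq values must lie in [0, 1].")
    }
    if (sum(clone_freq, na.rm = TRUE) > 1 + 1e-6) {
      abort("clone_freq values must sum to at most 1.")
    }
  }
  out <- structure(
    list(
      patient_id = as.character(patient_id),
      tree_id = as.character(tree_id),
      clones = ord,
      parent = parent[ord],
      branch_genes = bg,
      clone_freq = clone_freq,
      genotypes = NULL
    ),
    class = "clonal_tree"
  )
  out$genotypes <- clone_genotypes(out) # cached: trees are immutable
  out
}

# root-first (BFS) clone order; returns fewer clones than the input when the
# parent map has a cycle or a disconnected component
.topo_order <- function(parent, root) {
  children <- split(names(parent), factor(parent, levels = names(parent)))
  ord <- character(0)
  frontier <- root
  while (length(frontier) > 0L) {
    ord <- c(ord, frontier)
    frontier <- unlist(children[frontier], use.names = FALSE)
  }
  ord
}

#' @export
print.clonal_tree <- function(x, ...) {
  cat(sprintf(
    "<clonal_tree> patient %s, tree %s: %d clones, %d genes\n",
    x$patient_id, x$tree_id, length(x$clones), length(tree_genes(x))
  ))
  invisible(x)
}

#' Genes mutated anywhere in a clone tree
#'
#' @param tree A [clonal_tree()].
#' @return Sorted character vector of gene labels.
#' @export
tree_genes <- function(tree) {
  sort(unique(unlist(tree$branch_genes, use.names = FALSE)))
}

#' Clone-genotype matrix of a tree
#'
#' Entry `(gene, clone)` is 1 iff the gene lies on the branch entering the
#' clone or any ancestral branch, i.e. the clone's root-to-clone path carries
#' the mutation. Genotypes are therefore monotone along any lineage: once a
#' mutation is acquired it is inherited by all descendants.
#'
#' @param tree A [clonal_tree()].
#' @return Integer 0/1 matrix with genes as rows and clones as columns
#'   (root-first order).
#' @export
clone_genotypes <- function(tree) {
  if (!is.null(tree$genotypes)) return(tree$genotypes)
  genes <- tree_genes(tree)
  m <- matrix(0L, nrow = length(genes), ncol = length(tree$clones),
              dimnames = list(genes, tree$clones))
  geno <- list()
  for (cl in tree$clones) {
    p <- tree$parent[[cl]]
    inherited <- if (is.na(p)) character(0) else geno[[p]]
    geno[[cl]] <- union(inherited, tree$branch_genes[[cl]])
    m[geno[[cl]], cl] <- 1L
  }
  m
}

#' Clonal relation of a gene pair within one tree
#'
#' A pair is clonally exclusive when no clone's genotype carries both genes:
#' the two mutations only ever appear in different clonal lineages. Otherwise
#' the pair is co-occurring (same branch, or ancestor/descendant branches).
#'
#' @param tree A [clonal_tree()].
#' @param gene_j,gene_k Gene labels; both must be mutated somewhere in the tree.
#' @return `"exclusive"` or `"co-occurring"`.
#' @export
pair_relation <- function(tree, gene_j, gene_k) {
  g <- clone_genotypes(tree)
  if (!gene_j %in% rownames(g)) abort(sprintf("gene %s not in tree.", gene_j))
  if (!gene_k %in% rownames(g)) abort(sprintf("gene %s not in tree.", gene_k))
  if (any(g[gene_j, ] == 1L & g[gene_k, ] == 1L)) "co-occurring" else "exclusive"
}

#' Background clonal exclusivity rate of a tree
#'
#' The fraction of unordered gene pairs in the tree that are clonally
#' exclusive. Linear chain trees give 0 (every pair shares the terminal
#' lineage); star trees with one gene per branch give 1.
#'
#' @param tree A [clonal_tree()] with at least two genes.
#' @return A rate in `[0, 1]`.
#' @export
background_rate <- function(tree) {
  g <- clone_genotypes(tree)
  ng <- nrow(g)
  if (ng < 2L) {
    abort("background rate is undefined for trees with fewer than 2 genes.")
  }
  # (i,j) entry of G G^T counts clones carrying both genes
  co <- tcrossprod(g)
  n_excl <- sum(co[upper.tri(co)] == 0L)
  n_excl / choose(ng, 2)
}

#' Remove low-frequency clones from a tree
#'
#' Clones with frequency below `min_freq` are merged into their parent: the
#' branch genes are re-attached to the parent's branch and any children are
#' re-parented, so the gene content of the tree is preserved. The root clone
#' is never removed. Trees without frequency annotations are returned
#' unchanged.
#'
#' @param tree A [clonal_tree()].
#' @param min_freq Minimum clone fraction to keep (default 0.01, i.e. 1%).
#' @return A [clonal_tree()].
#' @export
prune_low_freq_clones <- function(tree, min_freq = 0.01) {
  cf <- tree$clone_freq
  if (is.null(cf) || min_freq <= 0) return(tree)
  parent <- tree$parent
  bg <- tree$branch_genes
  root <- tree$clones[is.na(parent)]
  drop <- tree$clones[!is.na(cf[tree$clones]) &
                        cf[tree$clones] < min_freq &
                        tree$clones != root]
  for (cl in drop) { # root-first order: a clone's parent is already final
    p <- parent[[cl]]
    bg[[p]] <- unique(c(bg[[p]], bg[[cl]]))
    kids <- names(parent)[!is.na(parent) & parent == cl]
    parent[kids] <- p
    cf[p] <- sum(cf[c(p, cl)], na.rm = TRUE)
    parent <- parent[names(parent) != cl]
    bg[[cl]] <- NULL
    cf <- cf[names(cf) != cl]
  }
  clonal_tree(tree$patient_id, tree$tree_id, parent, bg,
              clone_freq = if (length(cf)) cf else NULL)
}

#' Assemble a cohort from a list of clone trees
#'
#' Groups trees by patient and derives, per patient: the gene set (union over
#' the patient's trees), the background clonal exclusivity rate `r` (the
#' per-tree rate averaged over trees with at least two genes; `NA` when no
#' tree has two genes), and the pair-count weight `w = choose(#genes, 2)` used
#' by the occurrence test.
#'
#' @param trees List of [clonal_tree()] objects.
#' @return A `clonex_cohort`: a tibble with one row per patient and columns
#'   `patient_id`, `n_trees`, `trees` (list), `genes` (list), `n_genes`, `w`,
#'   `r`.
#' @export
as_cohort <- function(trees) {
  stopifnot(is.list(trees), length(trees) > 0L)
  pid <- vapply(trees, function(t) t$patient_id, character(1))
  rows <- lapply(split(trees, factor(pid, levels = unique(pid))), function(ts) {
    ts <- ts[order(vapply(ts, function(t) t$tree_id, character(1)))]
    gene_set <- sort(unique(unlist(lapply(ts, tree_genes))))
    rates <- vapply(ts, function(t) {
      if (length(tree_genes(t)) >= 2L) background_rate(t) else NA_real_
    }, numeric(1))
    tibble::tibble(
      patient_id = ts[[1]]$patient_id,
      n_trees = length(ts),
      trees = list(ts),
      genes = list(gene_set),
      n_genes = length(gene_set),
      w = choose(length(gene_set), 2),
      r = if (all(is.na(rates))) NA_real_ else mean(rates, na.rm = TRUE)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("clonex_cohort", class(out))
  out
}

#' Read a cohort of clone trees from a TSV edge list
#'
#' The file has one row per clone with columns `patient_id`, `tree_id`,
#' `clone_id`, `parent_id` (sentinel `"-"` for the root), `genes`
#' (semicolon-separated labels, empty allowed) and optionally `freq` (clone
#' fraction). A header row is required. Clones with frequency below
#' `min_clone_freq` are merged into their parent before any statistic is
#' computed (see [prune_low_freq_clones()]).
#'
#' @param path Path to the TSV file.
#' @param min_clone_freq Clone-frequency filter threshold (default 0.01).
#' @return A `clonex_cohort` tibble; see [as_cohort()].
#' @export
read_cohort <- function(path, min_clone_freq = 0.01) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("patient_id", "tree_id", "clone_id", "parent_id", "genes")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("%s: missing required column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }
  raw$.line <- seq_len(nrow(raw)) + 1L # header is line 1
  bad <- raw$.line[is.na(raw$patient_id) | is.na(raw$tree_id) | is.na(raw$clone_id)]
  if (length(bad) > 0L) {
    abort(sprintf("%s: malformed row at line %d (missing id).", path, bad[1]))
  }
  if ("freq" %in% names(raw)) {
    fr <- suppressWarnings(as.numeric(raw$freq))
    bad <- raw$.line[!is.na(raw$freq) & is.na(fr)]
    if (length(bad) > 0L) {
      abort(sprintf("%s: malformed freq at line %d.", path, bad[1]))
    }
    raw$freq <- fr
  }
  trees <- lapply(split(raw, paste(raw$patient_id, raw$tree_id, sep = "\r")), function(d) {
    d <- d[order(d$.line), ]
    if (anyDuplicated(d$clone_id)) {
      dup <- d$clone_id[duplicated(d$clone_id)][1]
      abort(sprintf("%s: duplicate clone '%s' at line %d.",
                    path, dup, d$.line[duplicated(d$clone_id)][1]))
    }
    parent <- ifelse(d$parent_id %in% c("-", "") | is.na(d$parent_id),
                     NA_character_, d$parent_id)
    names(parent) <- d$clone_id
    unknown <- !is.na(parent) & !(parent %in% d$clone_id)
    if (any(unknown)) {
      abort(sprintf("%s: unknown parent '%s' at line %d.",
                    path, parent[unknown][1], d$.line[unknown][1]))
    }
    genes <- lapply(strsplit(ifelse(is.na(d$genes), "", d$genes), ";", fixed = TRUE),
                    function(g) trimws(g[nzchar(trimws(g))]))
    names(genes) <- d$clone_id
    freq <- if ("freq" %in% names(d) && !all(is.na(d$freq))) {
      stats::setNames(d$freq, d$clone_id)
    }
    tr <- withCallingHandlers(
      clonal_tree(d$patient_id[1], d$tree_id[1], parent, genes, clone_freq = freq),
      error = function(e) abort(sprintf(
        "%s: parse error near line %d: %s", path, d$.line[1], conditionMessage(e)
      ))
    )
    prune_low_freq_clones(tr, min_clone_freq)
  })
  # restore file order of patients
  first_line <- vapply(split(raw$.line, paste(raw$patient_id, raw$tree_id, sep = "\r")),
                       min, numeric(1))
  as_cohort(trees[order(first_line)])
}

#' Collect the cohort-wide observation for one gene pair
#'
#' Identifies the set `S` of patients carrying both genes in at least one
#' tree, and for each computes the exclusivity outcome `O_i`: the fraction of
#' that patient's trees containing both genes in which the pair is clonally
#' exclusive (0 or 1 for single-tree patients). A patient is uninformative for
#' the placement test when its averaged background rate is exactly 0 (all
#' linear trees) or 1 (all star trees).
#'
#' @param cohort A `clonex_cohort`.
#' @param gene_j,gene_k Gene labels.
#' @return A `clonex_pair_obs` object with the per-patient tibble (`patients`)
#'   and the counts `n_t` (patients with both genes), `n` (informative),
#'   `n_l`/`n_s` (uninformative with rate 0 / 1), `n_cx` (informative patients
#'   whose binarised outcome is exclusive) and `m = n_cx + n_s` (exclusive
#'   count including star trees, used by the combined test).
#' @export
collect_pair <- function(cohort, gene_j, gene_k) {
  rows <- purrr::pmap_dfr(
    list(cohort$patient_id, cohort$trees, cohort$r),
    function(pid, ts, r) {
      with_both <- purrr::keep(ts, function(t) {
        g <- tree_genes(t)
        gene_j %in% g && gene_k %in% g
      })
      if (length(with_both) == 0L) return(NULL)
      o <- mean(vapply(with_both, function(t) {
        pair_relation(t, gene_j, gene_k) == "exclusive"
      }, logical(1)))
      tibble::tibble(patient_id = pid, r = r, o = o,
                     n_trees_pair = length(with_both))
    }
  )
  if (nrow(rows) == 0L) {
    rows <- tibble::tibble(patient_id = character(0), r = numeric(0),
                           o = numeric(0), n_trees_pair = integer(0))
  }
  rows$informative <- !is.na(rows$r) & rows$r > 0 & rows$r < 1
  rows$excl <- rows$o >= 0.5 # binarised outcome
  n_t <- nrow(rows)
  n_l <- sum(!rows$informative & rows$r == 0)
  n_s <- sum(!rows$informative & rows$r == 1)
  n_cx <- sum(rows$informative & rows$excl)
  structure(
    list(
      gene_j = gene_j, gene_k = gene_k, patients = rows,
      n_t = n_t, n = n_t - n_l - n_s, n_l = n_l, n_s = n_s,
      n_cx = n_cx, m = n_cx + n_s
    ),
    class = "clonex_pair_obs"
  )
}

#' @export
print.clonex_pair_obs <- function(x, ...) {
  cat(sprintf(
    "<pair %s_%s> n_t=%d n=%d n_cx=%d n_l=%d n_s=%d m=%d\n",
    x$gene_j, x$gene_k, x$n_t, x$n, x$n_cx, x$n_l, x$n_s, x$m
  ))
  invisible(x)
}

#' Relabel cohort mutations to pathways
#'
#' Replaces every gene label by its pathway using a two-column mapping table;
#' duplicate pathway labels arising on one branch collapse to a single marker,
#' after which all per-patient statistics (`r`, `w`, gene sets) are
#' recomputed. Tests then report pathway pairs instead of gene pairs.
#'
#' @param cohort A `clonex_cohort`.
#' @param mapping Data frame with columns `gene` and `pathway`.
#' @param unmapped What to do with genes absent from `mapping`: `"error"`
#'   (default; the error lists the genes) or `"drop"` (remove them).
#' @return A relabelled `clonex_cohort`.
#' @export
map_to_pathways <- function(cohort, mapping, unmapped = c("error", "drop")) {
  unmapped <- match.arg(unmapped)
  stopifnot(all(c("gene", "pathway") %in% names(mapping)))
  lut <- stats::setNames(as.character(mapping$pathway), as.character(mapping$gene))
  all_genes <- sort(unique(unlist(cohort$genes)))
  missing_genes <- setdiff(all_genes, names(lut))
  if (length(missing_genes) > 0L && unmapped == "error") {
    abort(sprintf("unmapped gene(s): %s.", paste(missing_genes, collapse = ", ")))
  }
  trees <- unlist(cohort$trees, recursive = FALSE)
  relab <- lapply(trees, function(t) {
    bg <- lapply(t$branch_genes, function(g) {
      g <- g[g %in% names(lut)]
      unique(unname(lut[g]))
    })
    clonal_tree(t$patient_id, t$tree_id, t$parent, bg, clone_freq = t$clone_freq)
  })
  as_cohort(relab)
}
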
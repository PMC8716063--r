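test_that("clone genotypes inherit mutations along lineages", {
  # linear chain: the terminal clone carries everything upstream
  tr <- make_tree("c1<-", "c2<c1", genes = list(c1 = "A", c2 = "B"))
  g <- clone_genotypes(tr)
  expect_equal(g[, "c2"], c(A = 1L, B = 1L))
  expect_equal(g[, "c1"], c(A = 1L, B = 0L))

  # star: no clone carries two genes
  st <- star_tree("P1", genes = c("A", "B", "C"))
  gs <- clone_genotypes(st)
  expect_true(all(colSums(gs) <= 1))

  # a clone collects its whole ancestry: root branch A, then D, then H
  tr2 <- make_tree("c0<-", "c1<c0", "c2<c1",
                   genes = list(c0 = "A", c1 = "D", c2 = "H"))
  expect_equal(sort(names(which(clone_genotypes(tr2)[, "c2"] == 1L))),
               c("A", "D", "H"))
})

test_that("genotype matrices are monotone along root-to-leaf paths", {
  for (s in 1:20) {
    tr <- random_binary_tree(sample(2:8, 1), sample(5:15, 1), seed = s)
    g <- clone_genotypes(tr)
    for (cl in tr$clones) {
      p <- tr$parent[[cl]]
      if (!is.na(p)) expect_true(all(g[, cl] >= g[, p]))
    }
  }
})

test_that("pair relations distinguish lineage sharing from exclusivity", {
  same_branch <- make_tree("c1<-", genes = list(c1 = c("J", "K")))
  expect_equal(pair_relation(same_branch, "J", "K"), "co-occurring")

  chain <- linear_tree("P1", c("J", "K"))
  expect_equal(pair_relation(chain, "J", "K"), "co-occurring")

  sibs <- make_tree("r<-", "c1<r", "c2<r", genes = list(c1 = "J", c2 = "K"))
  expect_equal(pair_relation(sibs, "J", "K"), "exclusive")

  expect_error(pair_relation(sibs, "J", "Z"), "not in tree")
})

test_that("background rate matches brute force over the genotype matrix", {
  expect_equal(background_rate(linear_tree("P", c("A", "B", "C"))), 0)
  expect_equal(background_rate(star_tree("P", c("A", "B", "C"))), 1)
  # root gene C with children A, B: only (A, B) is exclusive
  tr <- make_tree("c0<-", "c1<c0", "c2<c0",
                  genes = list(c0 = "C", c1 = "A", c2 = "B"))
  expect_equal(background_rate(tr), 1 / 3)
  expect_error(background_rate(make_tree("c1<-", genes = list(c1 = "A"))),
               "fewer than 2")

  for (s in 21:35) {
    tr <- random_binary_tree(sample(2:8, 1), sample(4:12, 1), seed = s)
    g <- clone_genotypes(tr)
    prs <- utils::combn(rownames(g), 2)
    excl <- vapply(seq_len(ncol(prs)), function(i) {
      !any(g[prs[1, i], ] & g[prs[2, i], ])
    }, logical(1))
    expect_equal(background_rate(tr), mean(excl))
  }
})

test_that("tree validation rejects malformed inputs", {
  expect_error(clonal_tree("P", "T", c(a = NA, b = NA)), "exactly one root")
  expect_error(clonal_tree("P", "T", c(a = NA, b = "zz")), "unknown parent")
  expect_error(clonal_tree("P", "T", c(a = NA, b = "c", c = "b")),
               "cycle|disconnected")
  expect_error(clonal_tree("P", "T", c(a = NA, b = "a"),
                           clone_freq = c(a = 0.9, b = 0.9)), "sum")
})

test_that("low-frequency clones merge into their parent, preserving genes", {
  tr <- make_tree("c1<-", "c2<c1", "c3<c2",
                  genes = list(c1 = "A", c2 = "B", c3 = "C"),
                  freq = c(c1 = 0.6, c2 = 0.005, c3 = 0.395))
  pruned <- prune_low_freq_clones(tr, 0.01)
  expect_equal(sort(pruned$clones), c("c1", "c3"))
  expect_setequal(pruned$branch_genes$c1, c("A", "B"))
  expect_equal(tree_genes(pruned), tree_genes(tr))
  # genotype of the surviving leaf is unchanged
  expect_equal(clone_genotypes(pruned)[tree_genes(tr), "c3"],
               clone_genotypes(tr)[tree_genes(tr), "c3"])

  # property: filtering never changes the gene set
  for (s in 1:10) {
    tr <- random_binary_tree(6, 10, seed = 100 + s)
    tr$clone_freq <- stats::setNames(withr::with_seed(s, {
      x <- stats::rgamma(6, 0.5)
      x / sum(x)
    }), tr$clones)
    expect_equal(tree_genes(prune_low_freq_clones(tr, 0.05)), tree_genes(tr))
  }
})

test_that("cohort TSV reading round-trips and applies the clone filter", {
  sc <- synth_cohort(seed = 77)
  fp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sc$edges, fp)
  cohort <- read_cohort(fp, min_clone_freq = 0)
  expect_s3_class(cohort, "clonex_cohort")
  expect_equal(nrow(cohort), 40)
  expect_equal(cohort$r, sc$cohort$r, tolerance = 1e-12)
  expect_equal(cohort$w, sc$cohort$w)
  expect_equal(cohort$w, choose(cohort$n_genes, 2))

  # the 1% clone filter may change rates but never the gene sets
  pruned <- read_cohort(fp, min_clone_freq = 0.01)
  expect_true(all(mapply(identical, pruned$genes, cohort$genes)))
})

test_that("malformed cohort files fail with the offending line", {
  fp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\ttree_id\tclone_id\tparent_id\tgenes",
               "P1\tT1\tc1\t-\tA",
               "P1\tT1\tc2\tzz\tB"), fp)
  expect_error(read_cohort(fp), "unknown parent.*line 3")

  writeLines(c("patient_id\ttree_id\tclone_id\tparent_id\tgenes",
               "P1\tT1\tc1\tc2\tA",
               "P1\tT1\tc2\tc1\tB"), fp)
  expect_error(read_cohort(fp), "parse error")
})

test_that("pair collection produces the published count structure", {
  # 15 carriers: 7 exclusive + 1 co-occurring informative, 3 linear, 4 star
  cohort <- count_cohort(n_excl = 7, n_cooc = 1, n_l = 3, n_s = 4)
  obs <- collect_pair(cohort, "J", "K")
  expect_equal(obs$n_t, 15)
  expect_equal(obs$n, 8)
  expect_equal(obs$n_cx, 7)
  expect_equal(obs$n_l, 3)
  expect_equal(obs$n_s, 4)
  expect_equal(obs$m, 11) # n_cx + n_s
  expect_equal(obs$n_t, obs$n + obs$n_l + obs$n_s)

  # absent pair
  empty <- collect_pair(cohort, "J", "NOPE")
  expect_equal(empty$n_t, 0)

  # two posterior trees, exclusive in exactly one -> O = 0.5
  t1 <- excl_tree("PX")
  t2 <- cooc_tree("PX")
  t2$tree_id <- "T2"
  posterior <- as_cohort(list(t1, t2))
  obs2 <- collect_pair(posterior, "J", "K")
  expect_equal(obs2$patients$o, 0.5)
})

test_that("count identities hold on random synthetic cohorts", {
  for (s in 1:5) {
    sc <- synth_cohort(n_patients = 20, planted = planted_pair(n_patients = 5),
                       seed = 200 + s)
    prs <- enumerate_pairs(sc$cohort, min_informative = 1)
    for (i in head(seq_len(nrow(prs)), 10)) {
      obs <- collect_pair(sc$cohort, prs$gene_j[i], prs$gene_k[i])
      expect_equal(obs$n_t, obs$n + obs$n_l + obs$n_s)
      expect_true(obs$n_cx >= 0 && obs$n_cx <= obs$n)
      expect_true(obs$m >= 0 && obs$m <= obs$n_t)
    }
  }
})

test_that("pathway mapping collapses markers and recomputes weights", {
  tr <- make_tree("c1<-", "c2<c1", genes = list(c1 = c("KRAS", "NRAS"), c2 = "TP53"))
  cohort <- as_cohort(list(tr))
  mapping <- data.frame(gene = c("KRAS", "NRAS", "TP53"),
                        pathway = c("RAS", "RAS", "P53"))
  mapped <- map_to_pathways(cohort, mapping)
  expect_setequal(mapped$genes[[1]], c("RAS", "P53"))
  expect_equal(mapped$w, choose(2, 2))
  expect_equal(mapped$trees[[1]][[1]]$branch_genes$c1, "RAS")

  # identity mapping changes nothing
  idm <- data.frame(gene = c("KRAS", "NRAS", "TP53"),
                    pathway = c("KRAS", "NRAS", "TP53"))
  same <- map_to_pathways(cohort, idm)
  expect_equal(same$genes, cohort$genes)
  expect_equal(same$r, cohort$r)

  # unmapped gene: error listing it, or dropped with recomputed pair count
  part <- data.frame(gene = c("KRAS", "NRAS"), pathway = c("RAS", "RAS"))
  expect_error(map_to_pathways(cohort, part), "TP53")
  dropped <- map_to_pathways(cohort, part, unmapped = "drop")
  expect_equal(dropped$genes[[1]], "RAS")
  expect_equal(dropped$w, 0)
})
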
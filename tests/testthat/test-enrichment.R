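test_that("GMT parsing validates, deduplicates and round-trips", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst\tg1\tg2\tg3",
               "setB\tsecond\tg2\tg3\tg4\tg5\tg6"), f)
  gc <- read_gmt(f)
  expect_length(gc$sets, 2)
  expect_equal(lengths(gc$sets), c(setA = 3L, setB = 5L))

  writeLines(c("setA\td\tg1\tg1\tg2"), f)
  expect_warning(gc2 <- read_gmt(f), "duplicate member")
  expect_equal(gc2$sets$setA, c("g1", "g2"))

  writeLines(c("setA\td\tg1", "setA\td\tg2"), f)
  expect_error(read_gmt(f), "duplicate set name")
  writeLines("setA\tdescription_only", f)
  expect_error(read_gmt(f), "line 1")

  gc3 <- gene_set_collection(list(x = c("a", "b"), y = c("c")),
                             c(x = "one", y = "two"))
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gc3, f2)
  expect_equal(read_gmt(f2), gc3)
})

test_that("hypergeometric ORA matches worked values and the enumeration
           oracle", {
  pop <- sprintf("g%02d", 1:20)
  sets <- gene_set_collection(list(term = pop[1:5]))
  res <- ora_hypergeometric(pop[1:10], pop, sets)
  expect_equal(res$k, 5)
  expect_equal(round(res$p, 6), 0.016254)
  expect_equal(res$fold_enrichment, 2.0)

  pop2 <- sprintf("h%02d", 1:10)
  sets2 <- gene_set_collection(list(term = pop2[1:2]))
  res2 <- ora_hypergeometric(pop2[c(1, 2, 5, 6, 7)], pop2, sets2)
  expect_equal(round(res2$p, 5), 0.22222)

  # k = 0 gives p = 1
  sets3 <- gene_set_collection(list(term = pop[15:18]))
  res3 <- ora_hypergeometric(pop[1:5], pop, sets3)
  expect_equal(res3$p, 1)

  expect_error(ora_hypergeometric(c(pop[1], "zz"), pop, sets),
               "not in population: zz")

  # p equals exhaustive enumeration over all study draws for N <= 12
  set.seed(4)
  for (case in list(c(8, 3, 4), c(10, 4, 5), c(12, 5, 6), c(9, 2, 3))) {
    N <- case[1]; K <- case[2]; n <- case[3]
    ids <- sprintf("x%02d", seq_len(N))
    sc <- gene_set_collection(list(t = ids[seq_len(K)]))
    for (k in 0:min(n, K)) {
      study <- c(ids[seq_len(k)], ids[(K + 1):(K + n - k)])
      p_pkg <- ora_hypergeometric(study, ids, sc)$p
      expect_equal(p_pkg, oracle_hyper_upper(N, K, n, k), tolerance = 1e-12)
    }
  }
})

test_that("the GSEA running sum matches the worked example and conserves", {
  ids <- paste0("g", 1:5)
  sc <- c(3, 2, 1, -1, -2)
  r <- gsea_enrichment_score(ids, sc, c("g1", "g3"))
  expect_equal(round(r$running, 5), c(0.75, 0.41667, 0.66667, 0.33333, 0))
  expect_equal(r$es, 0.75)
  expect_equal(r$leading_edge, "g1")

  r2 <- gsea_enrichment_score(ids, sc, "g5")
  expect_equal(r2$es, -1.0)
  expect_equal(r2$leading_edge, "g5")

  expect_error(gsea_enrichment_score(ids, sc, ids), "strict subset")
  expect_error(gsea_enrichment_score(ids, sc, "none"), "strict subset")

  # conservation: the walk always ends at zero
  set.seed(6)
  for (i in 1:25) {
    N <- sample(10:200, 1)
    ids_i <- sprintf("p%03d", seq_len(N))
    sc_i <- sort(rnorm(N), decreasing = TRUE)
    set_i <- sample(ids_i, sample(seq_len(N - 1), 1))
    run <- gsea_enrichment_score(ids_i, sc_i, set_i)$running
    expect_equal(run[N], 0, tolerance = 1e-9)
  }
})

test_that("ES is invariant to monotone rescaling at weight 0 and to
           positive scaling at any weight", {
  set.seed(8)
  N <- 60
  ids <- sprintf("p%02d", seq_len(N))
  sc <- sort(rnorm(N), decreasing = TRUE)
  st <- sample(ids, 12)
  e0 <- gsea_enrichment_score(ids, sc, st, weight = 0)$es
  e0b <- gsea_enrichment_score(ids, exp(sc), st, weight = 0)$es
  expect_equal(e0, e0b)
  e1 <- gsea_enrichment_score(ids, sc, st, weight = 1)$es
  e1b <- gsea_enrichment_score(ids, 7.3 * sc, st, weight = 1)$es
  expect_equal(e1, e1b)
})

test_that("permutation GSEA is seeded, flags the planted set, and has
           calibrated decoy p-values", {
  # modest signal fraction so uniform decoys carry little true enrichment
  ds <- generate_dataset(synth_config(n_proteins = 1000, frac_up = 0.05,
                                      frac_down = 0.02,
                                      seed = 12, detect_x0 = -100,
                                      blank_frac = 0, n_blanks = 0))
  gs <- generate_gene_sets(ds$truth, n_decoys = 10, set_size = 40,
                           enrich_frac = 0.8, seed = 13)
  tab <- differential_table(log2(ds$matrix), ds$metadata)
  o <- order(tab$t, decreasing = TRUE)
  res <- gsea_run(tab$protein_id[o], tab$t[o], gs$collection,
                  n_perm = 200, seed = 5)
  res_same <- gsea_run(tab$protein_id[o], tab$t[o], gs$collection,
                       n_perm = 200, seed = 5)
  expect_identical(res, res_same)
  planted <- res[res$term == "planted_set", ]
  expect_true(planted$significant)
  expect_gt(planted$es, 0)
  expect_true(all(res$p_perm >= 1 / 201 & res$p_perm <= 1))
  expect_equal(sign(res$nes), sign(res$es))
  # decoys are mostly not flagged
  expect_lte(sum(res$significant[res$term != "planted_set"]), 2)
})

test_that("decoy permutation p-values are stochastically uniform", {
  set.seed(9)
  N <- 300
  ids <- sprintf("p%03d", seq_len(N))
  sc <- sort(rnorm(N), decreasing = TRUE)
  sets <- lapply(1:50, function(i) sample(ids, 20))
  names(sets) <- sprintf("decoy%02d", 1:50)
  res <- gsea_run(ids, sc, gene_set_collection(sets), n_perm = 1000,
                  seed = 17)
  ks <- suppressWarnings(stats::ks.test(res$p_perm, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("category tallies count assignments, not proteins", {
  ann <- data.frame(protein_id = c("a", "b", "c", "c"),
                    category = c("lysosome", "lysosome", "ER", "mito"),
                    stringsAsFactors = FALSE)
  out <- category_tally(c("a", "b", "c", "d"), ann)
  expect_equal(out$count[out$category == "lysosome"], 2L)
  expect_equal(out$count[out$category == "ER"], 1L)
  expect_equal(out$count[out$category == "unannotated"], 1L)
  # 5 assignments total: c contributes to both ER and mito
  expect_equal(sum(out$count), 5L)
  expect_equal(sum(out$fraction), 1)
  empty <- category_tally(character(0), ann)
  expect_equal(nrow(empty), 0)
})
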
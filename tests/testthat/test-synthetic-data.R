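test_that("config invariants are enforced with named messages", {
  expect_error(synth_config(frac_up = 0.6, frac_down = 0.5), "frac_up")
  expect_error(synth_config(n_per_group = 1), "n_per_group")
  expect_error(synth_config(detect_s = 0), "detect_s")
  expect_error(synth_config(sigma_cell = -1), "SD")
  expect_error(synth_config(fc_log2_range = c(-0.1, 2)), "fc_log2_range")
})

test_that("generation is seed-deterministic and respects planted counts", {
  cfg <- synth_config(n_proteins = 400, seed = 42)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)

  cfg2 <- synth_config(frac_up = 0.1, frac_down = 0.05, n_proteins = 2000,
                       seed = 7)
  ds <- generate_dataset(cfg2)
  expect_equal(sum(ds$truth$true_class == "up"), 200)
  expect_equal(sum(ds$truth$true_class == "down"), 100)
  expect_true(all(ds$truth$true_log2fc[ds$truth$true_class == "null"] == 0))
  nn <- ds$truth$true_class != "null"
  expect_true(all(abs(ds$truth$true_log2fc[nn]) >= log2(1.5)))
  # shape: proteins x (2 * n_per_group + n_blanks)
  expect_equal(dim(ds$matrix), c(2000, 24 + 3))
  # interleaved batches: never confounded with group
  cells <- ds$metadata[!ds$metadata$is_blank, ]
  expect_equal(unname(table(cells$group, cells$batch)["control", ]),
               c(6, 6), ignore_attr = TRUE)
})

test_that("blanks live on an independent random stream", {
  base <- generate_dataset(synth_config(n_proteins = 300, n_blanks = 0,
                                        seed = 9))
  with_blanks <- generate_dataset(synth_config(n_proteins = 300,
                                               n_blanks = 4, seed = 9))
  expect_identical(base$matrix, with_blanks$matrix[, 1:24])
})

test_that("detection follows the logistic curve in true abundance", {
  cfg <- synth_config(n_proteins = 20000, seed = 5, blank_frac = 0,
                      n_blanks = 0, frac_up = 0, frac_down = 0,
                      batch_gamma_sd = 1e-6, sigma_cell = 0.3)
  ds <- generate_dataset(cfg)
  # reconstruct approximate true log2 intensity from the stated model:
  # observed values are 2^x exactly where detected
  x <- log2(ds$matrix)
  det_rate <- rowMeans(!is.na(ds$matrix))
  mean_x <- rowMeans(x, na.rm = TRUE)
  # use per-protein mean observed log2 as abundance proxy, bin into deciles
  ok <- !is.na(mean_x)
  dec <- cut(mean_x[ok], stats::quantile(mean_x[ok], 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  rate <- tapply(det_rate[ok], dec, mean)
  expect_true(all(diff(rate) >= -1e-9))  # non-decreasing in abundance
  # MNAR by construction: strong positive rank correlation
  expect_gt(stats::cor(mean_x[ok], det_rate[ok], method = "spearman"), 0.5)
  # empirical rate vs logistic value at decile midpoints, within 3 SE;
  # the proxy abundance is mildly selection-biased so compare only the
  # interior deciles where censoring bias is small
  mid <- tapply(mean_x[ok], dec, stats::median)
  n_per <- tapply(det_rate[ok], dec, length) * 24
  pred <- stats::plogis((mid - cfg$detect_x0) / cfg$detect_s)
  se <- sqrt(pred * (1 - pred) / n_per)
  hi <- which(pred > 0.9)
  expect_true(all(abs(rate[hi] - pred[hi]) <= 3 * se[hi] + 0.01))
})

test_that("null-protein group differences shrink as 1/sqrt(n_per_group)", {
  diffs <- vapply(c(4, 16), function(npg) {
    cfg <- synth_config(n_proteins = 1000, n_per_group = npg, seed = 21,
                        frac_up = 0, frac_down = 0, blank_frac = 0,
                        n_blanks = 0, detect_x0 = 0)
    ds <- generate_dataset(cfg)
    x <- log2(ds$matrix)
    g <- ds$metadata$group
    mean(abs(rowMeans(x[, g == "storage"]) - rowMeans(x[, g == "control"])))
  }, numeric(1))
  # quadrupling n halves the mean absolute difference (ratio ~ 2)
  expect_gt(diffs[1] / diffs[2], 1.6)
  expect_lt(diffs[1] / diffs[2], 2.4)
})

test_that("gene-set generation plants the requested composition", {
  ds <- generate_dataset(synth_config(n_proteins = 1000, frac_up = 0.2,
                                      seed = 3))
  gs <- generate_gene_sets(ds$truth, n_decoys = 10, set_size = 100,
                           enrich_frac = 0.8, seed = 4)
  expect_length(gs$collection$sets, 11)
  planted <- gs$collection$sets$planted_set
  expect_equal(sum(ds$truth$true_class[planted] == "up"), 80)
  expect_equal(sum(ds$truth$true_class[planted] == "null"), 20)
  expect_identical(gs$truth$planted_set, planted)

  # enrich_frac = 1 with enough up proteins: all members up-class
  gs2 <- generate_gene_sets(ds$truth, n_decoys = 0, set_size = 50,
                            enrich_frac = 1, seed = 4)
  expect_true(all(ds$truth$true_class[gs2$collection$sets$planted_set] == "up"))
  expect_error(generate_gene_sets(ds$truth, set_size = 2000), "set_size")
})

test_that("PPI generation plants an exact clique", {
  ds <- generate_dataset(synth_config(n_proteins = 500, seed = 3))
  pp <- generate_ppi(ds$truth, clique_size = 5, n_nodes = 30,
                     edge_prob = 0, seed = 8)
  g <- pp$graph
  expect_equal(nrow(g$edges), choose(5, 2))
  deg <- table(c(g$edges$node1, g$edges$node2))
  expect_true(all(deg == 4))
  expect_setequal(names(deg), pp$truth$clique_nodes)
  expect_error(generate_ppi(ds$truth, clique_size = 1), "clique_size")
})

test_that("planted clique takes the top MCC ranks over sparse background", {
  ds <- generate_dataset(synth_config(n_proteins = 500, seed = 3))
  pp <- generate_ppi(ds$truth, clique_size = 6, n_nodes = 60,
                     edge_prob = 0.02, seed = 15)
  tab <- mcc_scores(pp$graph)
  expect_setequal(tab$node[1:6], pp$truth$clique_nodes)
})

test_that("written matrix and metadata round-trip exactly", {
  ds <- generate_dataset(synth_config(n_proteins = 120, seed = 6))
  mf <- withr::local_tempfile(fileext = ".tsv")
  sf <- withr::local_tempfile(fileext = ".tsv")
  write_protein_matrix(ds$matrix, mf)
  write_sample_metadata(ds$metadata, sf)
  m2 <- read_protein_matrix(mf)
  expect_equal(m2, ds$matrix)
  meta2 <- read_sample_metadata(sf)
  expect_equal(meta2, ds$metadata)
  # and the re-written file is byte-identical
  mf2 <- withr::local_tempfile(fileext = ".tsv")
  write_protein_matrix(m2, mf2)
  expect_identical(readLines(mf), readLines(mf2))
})
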
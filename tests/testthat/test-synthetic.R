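test_that("genome simulation is deterministic, packed, and valid", {
  cfg <- sim_config(n_genes = 40, n_chroms = 4)
  g1 <- simulate_genome(cfg, seed = 5)
  g2 <- simulate_genome(cfg, seed = 5)
  expect_identical(g1, g2)
  expect_false(identical(g1, simulate_genome(cfg, seed = 6)))
  expect_true(all(g1$start < g1$end))
  expect_true(all(g1$end - g1$start >= 1000 & g1$end - g1$start <= 10000))
  # non-overlap within each chromosome
  for (ch in unique(g1$chrom)) {
    s <- g1[g1$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  one_per <- simulate_genome(sim_config(n_genes = 4, n_chroms = 4), seed = 1)
  expect_equal(as.integer(table(one_per$chrom)[paste0("chr", 1:4)]), rep(1L, 4))
})

test_that("zero-noise rhythmic traces lie exactly on their cosine", {
  cfg <- sim_config(n_genes = 50, noise_cv = 0, frac_non_expressed = 0,
                    frac_rhythmic = 1)
  genes <- simulate_genome(cfg, seed = 2)
  ex <- simulate_expression(genes, cfg, seed = 2)
  t <- times_from_labels(colnames(ex$counts))
  for (i in seq_len(5)) {
    tr <- ex$truth[i, ]
    expected <- tr$baseline * (1 + tr$true_amplitude * cos(2 * pi * (t - tr$true_phase) / 24))
    expect_equal(unname(ex$counts[i, ]), expected, tolerance = 1e-12)
  }
})

test_that("expression classes follow configured fractions", {
  cfg <- sim_config(n_genes = 2000)
  genes <- simulate_genome(cfg, seed = 3)
  ex <- simulate_expression(genes, cfg, seed = 3)
  expect_true(all(table(ex$truth$expression_class) > 0))
  # realized rhythmic fraction within the binomial 99% CI of 0.37
  ci <- qbinom(c(0.005, 0.995), 2000, 0.37) / 2000
  frac <- mean(ex$truth$expression_class == "rhythmic")
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])

  none <- simulate_expression(genes, sim_config(n_genes = 2000, frac_rhythmic = 0),
                              seed = 3)
  expect_false(any(none$truth$expression_class == "rhythmic"))
})

test_that("occupancy peaks track gene phase minus the configured lag", {
  cfg <- sim_config(n_genes = 100, noise_cv = 0, frac_non_expressed = 0.2)
  genes <- simulate_genome(cfg, seed = 4)
  ex <- simulate_expression(genes, cfg, seed = 4)
  occ <- simulate_occupancy(genes, ex$truth, cfg, seed = 4)
  # non-expressed genes receive no peak
  neg <- ex$truth$gene_id[ex$truth$expression_class == "non-expressed"]
  expect_length(intersect(occ$peak_gene$gene_id, neg), 0)
  expect_equal(sort(occ$peak_gene$gene_id),
               sort(ex$truth$gene_id[ex$truth$expression_class != "non-expressed"]))
  # occupancy trace peaks one sampling step before expression at the 4-h grid
  t <- times_from_labels(colnames(occ$signal))
  rg <- which(ex$truth[match(occ$peak_gene$gene_id, ex$truth$gene_id),
                       "expression_class"] == "rhythmic")
  for (i in rg[1:5]) {
    gene <- occ$peak_gene$gene_id[i]
    tr <- ex$truth[ex$truth$gene_id == gene, ]
    occ_peak_t <- t[which.max(occ$signal[i, 1:6])]
    expr_peak_t <- t[which.max(ex$counts[gene, 1:6])]
    expected_shift <- circular_phase_diff(occ_peak_t, expr_peak_t)
    expect_lte(expected_shift, 4)  # one sampling step at lag 2 h
  }
  # zero lag => identical phase of the mean traces
  cfg0 <- sim_config(n_genes = 100, noise_cv = 0, lag_hours = 0,
                     frac_non_expressed = 0.2)
  occ0 <- simulate_occupancy(genes, ex$truth, cfg0, seed = 4)
  calls_occ <- detect_rhythms(occ0$signal)
  ph <- ex$truth$true_phase[match(occ0$peak_gene$gene_id, ex$truth$gene_id)]
  keep <- !is.na(ph)
  expect_lt(max(circular_phase_diff(calls_occ$phase_h[keep], ph[keep])), 0.3)
})

test_that("simulated loops respect design constraints and span rule", {
  ds <- small_sim()
  expect_true(all(ds$loops$pet_count >= 5))
  expect_true(all(ds$loops$fdr < 0.05))
  intra <- ds$loops$chrom_a == ds$loops$chrom_b
  span <- abs((ds$loops$start_b + ds$loops$end_b) / 2 -
                (ds$loops$start_a + ds$loops$end_a) / 2)
  expect_true(all(span[intra] > 8000))
  expect_equal(as.integer(table(ds$loops$time_label)[c("t08", "t20")]),
               c(600L, 600L))
  # every loop's gene pair is recorded in truth
  expect_equal(nrow(ds$loop_truth), nrow(ds$loops))
  expect_true(all(ds$loop_truth$gene_a %in% ds$genes$gene_id))
})

test_that("full phase coherence forces RG-RG spans at or below 4 h", {
  cfg <- sim_config(n_genes = 300, n_loops_per_time = 400, rr_coherence = 1,
                    neg_loop_frac = 0,
                    csc_design = list(n_am = 5, n_pm = 5, n_static = 5,
                                      degree_min = 3, degree_max = 5))
  ds <- simulate_dataset(cfg, seed = 9)
  ph <- setNames(ds$truth$true_phase, ds$truth$gene_id)
  bg <- ds$loop_truth[ds$loop_truth$origin == "background", ]
  rr <- !is.na(ph[bg$gene_a]) & !is.na(ph[bg$gene_b])
  spans <- circular_phase_diff(ph[bg$gene_a[rr]], ph[bg$gene_b[rr]])
  expect_true(all(spans <= 4))
})

test_that("designed CSC degrees are realized exactly in the emitted loops", {
  ds <- small_sim()
  deg <- function(tl) {
    tr <- ds$loop_truth[ds$loop_truth$time_label == tl, ]
    both <- c(tr$gene_a, tr$gene_b)
    tab <- table(both)
    function(g) if (g %in% names(tab)) unname(tab[g]) else 0L
  }
  d08 <- deg("t08"); d20 <- deg("t20")
  for (i in seq_len(nrow(ds$csc_truth))) {
    expect_equal(d08(ds$csc_truth$node_gene[i]), ds$csc_truth$deg_am[i])
    expect_equal(d20(ds$csc_truth$node_gene[i]), ds$csc_truth$deg_pm[i])
  }
})

test_that("tissue panel gives rhythmic genes broader expression", {
  ds <- small_sim()
  expect_equal(nrow(ds$tissue_fpkm), 20)
  breadth <- colSums(ds$tissue_fpkm > 1)
  cls <- ds$truth$expression_class[match(colnames(ds$tissue_fpkm), ds$truth$gene_id)]
  expect_gt(mean(breadth[cls == "rhythmic"]), mean(breadth[cls == "non-rhythmic"]))
  expect_true(all(breadth[cls == "non-expressed"] == 0))
})

test_that("dataset generation is fully deterministic and writable", {
  cfg <- sim_config(n_genes = 120, n_loops_per_time = 150,
                    csc_design = list(n_am = 3, n_pm = 3, n_static = 3,
                                      degree_min = 3, degree_max = 4))
  d1 <- simulate_dataset(cfg, seed = 77)
  d2 <- simulate_dataset(cfg, seed = 77)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$loops, d2$loops)
  expect_identical(d1$tissue_fpkm, d2$tissue_fpkm)

  dir <- file.path(tempdir(), "ds-out")
  paths <- write_dataset(d1, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(read_gene_models(paths[["genes"]]), d1$genes, ignore_attr = TRUE)
  back <- read_loops(paths[["loops_t08"]], "t08")
  expect_equal(back[, 1:8], d1$loops[d1$loops$time_label == "t08", 1:8],
               ignore_attr = TRUE)
})
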
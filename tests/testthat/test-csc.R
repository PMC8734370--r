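make_pairs <- function(a, b) {
  data.frame(gene_a = a, gene_b = b, pet_count = 10L, stringsAsFactors = FALSE)
}

test_that("CSCs emerge at degree >= 3 with distinct-partner degrees", {
  pairs_am <- make_pairs(c("hub", "hub", "hub", "hub", "low", "low"),
                         c("a", "b", "c", "c", "x", "y"))  # hub: {a,b,c}; dup ignored
  pairs_pm <- make_pairs("hub", "a")
  cscs <- build_cscs(pairs_am, pairs_pm)
  expect_equal(cscs$node_gene, "hub")                # 'low' has degree 2
  expect_equal(cscs$degree_am, 3)                    # duplicate partner counts once
  expect_equal(cscs$degree_pm, 1)
  expect_setequal(cscs$linked_am[[1]], c("a", "b", "c"))
  expect_false("hub" %in% cscs$linked_am[[1]])
  expect_equal(cscs$degree_am, length(cscs$linked_am[[1]]))
})

test_that("degree-ratio classification follows the >3 rule with absent-time cases", {
  cscs <- data.frame(node_gene = paste0("n", 1:5),
                     degree_am = c(9, 4, 6, 2, 13),
                     degree_pm = c(2, 4, 0, 9, 4), stringsAsFactors = FALSE)
  cscs$linked_am <- replicate(5, character(0), simplify = FALSE)
  cscs$linked_pm <- replicate(5, character(0), simplify = FALSE)
  out <- classify_cscs(cscs)
  expect_equal(out$csc_class,
               c("AM-specific",   # 9:2 = 4.5 > 3
                 "static",        # 4:4 = 1
                 "AM-specific",   # PM degree 0
                 "PM-specific",   # 9:2
                 "AM-specific"))  # 13:4 > 3
  # boundary: exactly 3x is static; idempotent
  b <- classify_cscs(data.frame(node_gene = "e", degree_am = 9, degree_pm = 3,
                                linked_am = I(list(character(0))),
                                linked_pm = I(list(character(0)))))
  expect_equal(b$csc_class, "static")
  expect_identical(classify_cscs(out), out)
})

test_that("CSC composition tallies linked-gene classes with flags", {
  labels <- make_labels(c("hub", "r1", "r2", "n1", "e1"),
                        c("RG", "RG", "RG", "NG", "NEG"))
  cscs <- data.frame(node_gene = "hub", degree_am = 3, degree_pm = 0,
                     stringsAsFactors = FALSE)
  cscs$linked_am <- list(c("r1", "r2", "n1"))
  cscs$linked_pm <- list(character(0))
  cscs$csc_class <- "AM-specific"
  comp <- csc_composition(cscs, labels)
  am <- comp[comp$time_label == "t08", ]
  expect_equal(am$frac_rg, 2 / 3)
  expect_equal(am$rg_ng_ratio, 2)
  expect_equal(am$node_class, "RG")
  pm <- comp[comp$time_label == "t20", ]
  expect_true(pm$empty)
  expect_true(is.na(pm$frac_rg))
  cscs$linked_am <- list(c("r1", "ghost"))
  expect_error(csc_composition(cscs, labels), "missing a label")

  all_rg <- cscs
  all_rg$linked_am <- list(c("r1", "r2"))
  expect_equal(csc_composition(all_rg, labels)$frac_rg[1], 1)
})

test_that("static CSC overlap fractions follow set arithmetic", {
  cscs <- data.frame(node_gene = c("s1", "s2", "s3"),
                     degree_am = c(3, 3, 2), degree_pm = c(2, 3, 3),
                     csc_class = "static", stringsAsFactors = FALSE)
  cscs$linked_am <- list(c("a", "b", "c"), c("x", "y", "z"), c("p", "q"))
  cscs$linked_pm <- list(c("c", "d"), c("x", "y", "z"), c("r", "s", "t"))
  ov <- static_linked_overlap(cscs)
  expect_equal(ov$frac_common[ov$node_gene == "s1"], 1 / 4)  # {c} of {a,b,c,d}
  expect_equal(ov$frac_common[ov$node_gene == "s2"], 1)      # identical sets
  expect_equal(ov$frac_common[ov$node_gene == "s3"], 0)      # disjoint
  expect_equal(ov$frac_common + ov$frac_am_specific + ov$frac_pm_specific,
               rep(1, 3))
})

test_that("phase enrichment test hits degenerate and maximal endpoints", {
  set.seed(13)
  pool <- paste0("g", 1:200)
  labels <- make_labels(pool, rep("RG", 200),
                        phases = runif(200, 0, 24), amplitudes = runif(200, 1, 2))
  cfg <- circa_config(n_perm = 199, phase_halfwidth = 2, amplitude_quantile = 0)
  cscs <- data.frame(node_gene = paste0("g", 1:10), degree_am = 4, degree_pm = 0,
                     csc_class = "AM-specific", stringsAsFactors = FALSE)
  cscs$linked_am <- lapply(1:10, function(i) sample(pool, 4))
  cscs$linked_pm <- replicate(10, character(0), simplify = FALSE)

  # degenerate: target = pool (halfwidth 12 covers every phase)
  cfg_all <- cfg; cfg_all$phase_halfwidth <- 12
  res <- phase_enrichment_test(cscs, labels, phase_center = 8, pool = pool,
                               cfg = cfg_all, seed = 4)
  expect_equal(res$n_target, 200)
  expect_equal(res$observed, mean(lengths(cscs$linked_am)) + 1)  # node counted
  expect_true(all(res$null == res$observed))
  expect_equal(res$p_value, 1)

  # maximal enrichment: CSCs built entirely from morning-phase genes
  labels2 <- labels
  labels2$phase_h <- c(rep(8, 50), runif(150, 12, 24))
  target_ids <- pool[1:50]
  cscs2 <- cscs
  cscs2$node_gene <- sample(target_ids, 10)
  cscs2$linked_am <- lapply(cscs2$node_gene,
                            function(nd) sample(setdiff(target_ids, nd), 4))
  res2 <- phase_enrichment_test(cscs2, labels2, phase_center = 8, pool = pool,
                                cfg = cfg, seed = 4)
  expect_equal(res2$observed, 5)
  expect_equal(res2$p_value, 1 / 200)

  expect_error(phase_enrichment_test(cscs, labels, 8, pool = pool[1:3],
                                     cfg = cfg_all), "pool smaller")
})

test_that("null mean of the permutation distribution matches hypergeometric expectation", {
  set.seed(17)
  pool <- paste0("g", 1:300)
  labels <- make_labels(pool, rep("RG", 300),
                        phases = runif(300, 0, 24), amplitudes = 1)
  cfg <- circa_config(n_perm = 1000, phase_halfwidth = 2, amplitude_quantile = 0)
  cscs <- data.frame(node_gene = sample(pool, 20), degree_am = 6, degree_pm = 0,
                     csc_class = "AM-specific", stringsAsFactors = FALSE)
  cscs$linked_am <- lapply(1:20, function(i) sample(pool, 6))
  cscs$linked_pm <- replicate(20, character(0), simplify = FALSE)
  res <- phase_enrichment_test(cscs, labels, phase_center = 8, pool = pool,
                               cfg = cfg, seed = 23)
  mean_size <- mean(vapply(seq_len(nrow(cscs)),
                           function(i) length(unique(c(cscs$node_gene[i],
                                                       cscs$linked_am[[i]]))),
                           numeric(1)))
  expected <- mean_size * res$n_target / length(pool)
  expect_equal(mean(res$null), expected, tolerance = 0.05)
  # permutation engine determinism
  res_b <- phase_enrichment_test(cscs, labels, phase_center = 8, pool = pool,
                                 cfg = cfg, seed = 23)
  expect_identical(res$null, res_b$null)
})

test_that("empirical p-values are near-uniform under an exchangeable null", {
  set.seed(29)
  pool <- paste0("g", 1:300)
  cfg <- circa_config(n_perm = 199, phase_halfwidth = 2, amplitude_quantile = 0)
  pvals <- vapply(1:60, function(r) {
    labels <- make_labels(pool, rep("RG", 300),
                          phases = runif(300, 0, 24), amplitudes = 1)
    cscs <- data.frame(node_gene = sample(pool, 40),
                       degree_am = 5, degree_pm = 0, csc_class = "AM-specific",
                       stringsAsFactors = FALSE)
    cscs$linked_am <- lapply(1:40, function(i) sample(pool, sample(3:10, 1)))
    cscs$linked_pm <- replicate(40, character(0), simplify = FALSE)
    phase_enrichment_test(cscs, labels, phase_center = 8, pool = pool,
                          cfg = cfg, seed = 1000 + r)$p_value
  }, numeric(1))
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  expect_lte(mean(pvals <= 0.05), 0.15)
})
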
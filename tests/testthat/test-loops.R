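test_that("loop filtering applies FDR, PET, and intra-span rules", {
  loops <- rbind(
    make_loop("chr1", 1000, 2000, "chr1", 5000, 6000),           # span 4000: out
    make_loop("chr1", 1000, 2000, "chr1", 50000, 51000, pet = 4, fdr = 0.001),  # pet: out
    make_loop("chr1", 1000, 2000, "chr1", 50000, 51000, pet = 10, fdr = 0.2),   # fdr: out
    make_loop("chr1", 1000, 2000, "chr1", 50000, 51000, pet = 10, fdr = 0.01),  # keep
    make_loop("chr1", 100, 200, "chr2", 100, 200, pet = 6, fdr = 0.01)          # inter: keep
  )
  kept <- filter_loops(loops)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$chrom_b, c("chr1", "chr2"))
  # idempotent and order-independent
  expect_equal(filter_loops(kept), kept)
  rev_kept <- filter_loops(loops[rev(seq_len(nrow(loops))), ])
  expect_setequal(paste(rev_kept$start_a, rev_kept$chrom_b),
                  paste(kept$start_a, kept$chrom_b))
})

test_that("gene pairs derive from peak-mediated anchors with dedup and classes", {
  genes <- data.frame(gene_id = c("rg1", "rg2", "ng1", "neg1"),
                      chrom = "chr1",
                      start = c(1000, 50000, 100000, 150000),
                      end = c(3000, 52000, 102000, 152000),
                      strand = "+", stringsAsFactors = FALSE)
  peaks <- data.frame(peak_id = paste0("p", 1:4), chrom = "chr1",
                      start = genes$start, end = genes$start + 500,
                      summit = genes$start + 250, stringsAsFactors = FALSE)
  peak_map <- data.frame(peak_id = peaks$peak_id, gene_id = genes$gene_id,
                         stringsAsFactors = FALSE)
  labels <- make_labels(genes$gene_id, c("RG", "RG", "NG", "NEG"),
                        phases = c(8, 10, NA, NA))
  loops <- rbind(
    make_loop("chr1", 1000, 1500, "chr1", 50000, 50500),   # rg1-rg2
    make_loop("chr1", 1100, 1400, "chr1", 50100, 50400),   # duplicate pair
    make_loop("chr1", 1000, 1500, "chr1", 100000, 100500), # rg1-ng1
    make_loop("chr1", 50000, 50500, "chr1", 150000, 150500), # rg2-neg1
    make_loop("chr1", 900000, 900100, "chr1", 990000, 990100) # maps to nothing
  )
  pairs <- loops_to_gene_pairs(loops, peaks, peak_map, labels, genes)
  expect_equal(nrow(pairs), 3)                      # dedup + unmapped dropped
  key <- paste(pairs$gene_a, pairs$gene_b)
  expect_setequal(key, c("rg1 rg2", "ng1 rg1", "neg1 rg2"))
  expect_equal(pairs$pair_class[key == "rg1 rg2"], "RR")
  expect_equal(pairs$pair_class[key == "ng1 rg1"], "RN")
  expect_equal(pairs$pair_class[key == "neg1 rg2"], "NEG-associated")
  expect_equal(pairs$n_loops[key == "rg1 rg2"], 2)  # two loops, one pair
  expect_equal(pairs$phase_span[key == "rg1 rg2"], 2)
  expect_true(all(is.na(pairs$phase_span[pairs$pair_class != "RR"])))
  # exhaustive & exclusive classification
  expect_true(all(pairs$pair_class %in% c("RR", "RN", "NN", "NEG-associated")))
})

test_that("time-point comparison declares loops common only on two-anchor overlap", {
  t1 <- rbind(
    make_loop("chr1", 1000, 2000, "chr1", 50000, 51000),
    make_loop("chr1", 9000, 9500, "chr1", 80000, 80500),
    make_loop("chr2", 100, 200, "chr2", 90000, 90200)
  )
  t2 <- rbind(
    make_loop("chr1", 1500, 2500, "chr1", 50500, 51500, time_label = "t20"),  # overlaps both
    make_loop("chr1", 9000, 9500, "chr1", 200000, 200500, time_label = "t20") # one side only
  )
  cmp <- compare_time_points(t1, t2)
  expect_equal(nrow(cmp$common_t1), 1)
  expect_equal(cmp$common_t1$start_a, 1000)
  expect_equal(nrow(cmp$specific_t1), 2)
  expect_equal(nrow(cmp$common_t2), 1)
  expect_equal(nrow(cmp$specific_t2), 1)
  expect_equal(cmp$summary$frac_specific, 3 / 5)
  # identity: comparing a set with itself yields all-common
  self <- compare_time_points(t1, t1)
  expect_equal(nrow(self$specific_t1), 0)
  expect_equal(nrow(self$specific_t2), 0)
})

test_that("pair coexpression matches direct Pearson correlation", {
  labs <- all_time_labels()
  expr <- rbind(a = cosine_trace(10, 5, 8), b = cosine_trace(20, 8, 20),
                c = cosine_trace(10, 5, 8), flat = rep(3, 12))
  colnames(expr) <- labs
  pairs <- data.frame(gene_a = c("a", "a", "a"), gene_b = c("c", "b", "flat"),
                      stringsAsFactors = FALSE)
  out <- pair_coexpression(pairs, expr)
  expect_equal(out$pcc[1], 1)
  expect_equal(out$pcc[2], -1)     # anti-phase cosines
  expect_true(is.na(out$pcc[3]))
  expect_equal(out$pcc_flag[3], "zero_variance")
  # independent noise pairs center on zero
  set.seed(21)
  noise <- matrix(rnorm(2000 * 12), 2000, dimnames = list(paste0("n", 1:2000), labs))
  np <- data.frame(gene_a = paste0("n", 1:1000), gene_b = paste0("n", 1001:2000))
  mean_pcc <- mean(pair_coexpression(np, noise)$pcc)
  expect_lt(abs(mean_pcc), 3 / sqrt(1000 * 9))  # ~3 SE of the mean pair PCC
})

test_that("matched random pairs reproduce the observed distance histogram", {
  ds <- small_sim()
  genes <- ds$genes
  pool <- ds$truth$gene_id[ds$truth$expression_class != "non-expressed"]
  gi <- match(pool, genes$gene_id)
  mid <- (genes$start[gi] + genes$end[gi]) / 2
  set.seed(5)
  ia <- sample(length(pool), 300, replace = TRUE)
  ib <- sample(length(pool), 300, replace = TRUE)
  keep <- ia != ib & genes$chrom[gi[ia]] == genes$chrom[gi[ib]] &
    abs(mid[ia] - mid[ib]) > 0
  observed <- data.frame(gene_a = pool[ia[keep]], gene_b = pool[ib[keep]],
                         distance = abs(mid[ia[keep]] - mid[ib[keep]]))
  draws <- matched_random_pairs(observed, pool, genes, n_draws = 2, seed = 11)
  expect_length(draws, 2)
  expect_equal(nrow(draws[[1]]), nrow(observed))
  bins <- function(d) table(floor(log10(d) / 0.25))
  expect_equal(bins(draws[[1]]$distance), bins(observed$distance))
  # determinism contract
  again <- matched_random_pairs(observed, pool, genes, n_draws = 2, seed = 11)
  expect_identical(draws, again)
  different <- matched_random_pairs(observed, pool, genes, n_draws = 2, seed = 12)
  expect_false(identical(draws, different))
  # KS agreement between observed and matched distances
  ks <- compare_distributions(observed$distance, draws[[1]]$distance)
  expect_gt(ks$p_value, 0.01)
})

test_that("KS comparison hits analytic endpoints", {
  expect_equal(compare_distributions(1:50, 1:50)$statistic, 0)
  expect_equal(compare_distributions(1:50, 101:150)$statistic, 1)
  set.seed(8)
  a <- runif(1000); b <- runif(1000, 0.5, 1.5)
  expect_lt(abs(compare_distributions(a, b)$statistic - 0.5), 0.08)
  expect_error(compare_distributions(1, 1:10), "at least 2")
})

test_that("coherent RG-RG loop spans dominate matched random RG pairs", {
  ds <- small_sim()
  calls <- detect_rhythms(suppressWarnings(normalize_diurnal(ds$counts)))
  labels <- classify_gene_expression(ds$counts, calls)
  peak_map <- ds$occupancy$peak_gene
  loops08 <- filter_loops(ds$loops[ds$loops$time_label == "t08", ])
  pairs <- loops_to_gene_pairs(loops08, ds$occupancy$peaks, peak_map, labels, ds$genes)
  rr <- pairs[pairs$pair_class == "RR", ]
  rg <- labels$gene_id[labels$expression_class == "RG"]
  set.seed(31)
  rnd_a <- sample(rg, 600, replace = TRUE)
  rnd_b <- sample(rg, 600, replace = TRUE)
  keep <- rnd_a != rnd_b
  ph <- setNames(labels$phase_h, labels$gene_id)
  random_spans <- circular_phase_diff(ph[rnd_a[keep]], ph[rnd_b[keep]])
  expect_gt(nrow(rr), 20)
  expect_lt(median(rr$phase_span), median(random_spans))
  ks <- suppressWarnings(stats::ks.test(rr$phase_span, random_spans,
                                        alternative = "greater"))
  expect_lt(ks$p.value, 0.01)
})
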
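# End-to-end orchestration: simulate -> rhythm -> annotate -> loops -> CSC ->
# network -> aggregate profile, with a plain-file output directory, a summary
# report, and a run manifest. A single seed controls every stochastic stage.

#' Run the complete pipeline on a simulated dataset
#'
#' Simulates a dataset, detects rhythms in expression and occupancy,
#' classifies genes and peaks, derives and classifies gene pairs per time
#' point, builds and classifies CSCs with a phase-enrichment test, builds
#' AM/PM networks with a two-hop expansion from morning-phase hub seeds, and
#' computes the TSS-centered aggregate profile of AM-specific nodes. All
#' stage outputs are plain files (TSV/BED/BEDPE/narrowPeak/JSON) so stages
#' can be diffed and rerun; a markdown report and a JSON manifest (config
#' snapshot, seed, file digests, stage timings) are written alongside.
#'
#' @param sim_cfg a [sim_config()].
#' @param cfg a [circa_config()].
#' @param out_dir output directory.
#' @param seed master seed (defaults to `sim_cfg$seed`).
#' @param n_perm_enrichment permutations for the CSC enrichment tests
#'   (defaults to `cfg$n_perm`).
#' @return (invisibly) a list with every intermediate object, the report
#'   table, and the manifest.
#' @export
run_all <- function(sim_cfg = sim_config(), cfg = circa_config(), out_dir,
                    seed = sim_cfg$seed, n_perm_enrichment = cfg$n_perm) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    val
  }

  ds <- stage("simulate", simulate_dataset(sim_cfg, seed))
  files <- stage("write_inputs", write_dataset(ds, file.path(out_dir, "inputs")))

  expr_norm <- stage("normalize", normalize_diurnal(ds$counts))
  calls_expr <- stage("rhythm_expression", detect_rhythms(expr_norm, cfg))
  calls_occ <- stage("rhythm_occupancy", detect_rhythms(ds$occupancy$signal, cfg))

  labels <- stage("classify_genes",
                  classify_gene_expression(ds$counts, calls_expr, cfg))
  fpkm <- rowMeans(ds$counts)
  peak_map <- stage("assign_peaks",
                    assign_peaks_to_genes(ds$occupancy$peaks, ds$genes, fpkm, cfg))

  loops_am <- stage("filter_loops_am",
                    filter_loops(ds$loops[ds$loops$time_label == "t08", ], cfg))
  loops_pm <- stage("filter_loops_pm",
                    filter_loops(ds$loops[ds$loops$time_label == "t20", ], cfg))
  pairs_am <- stage("pairs_am", loops_to_gene_pairs(loops_am, ds$occupancy$peaks,
                                                    peak_map, labels, ds$genes))
  pairs_pm <- stage("pairs_pm", loops_to_gene_pairs(loops_pm, ds$occupancy$peaks,
                                                    peak_map, labels, ds$genes))
  tp <- stage("compare_time_points", compare_time_points(loops_am, loops_pm))

  # phase relationship occupancy -> expression over truth-expressed pairs
  pairing <- data.frame(feature_a = ds$occupancy$peak_gene$peak_id,
                        feature_b = ds$occupancy$peak_gene$gene_id,
                        stringsAsFactors = FALSE)
  lag <- stage("phase_lag", mean_phase_lag(calls_occ, calls_expr, pairing))
  pcor <- stage("signal_correlation",
                signal_expression_correlation(ds$occupancy$signal, expr_norm, pairing))

  cscs <- stage("build_cscs", classify_cscs(build_cscs(pairs_am, pairs_pm, cfg), cfg))
  composition <- stage("csc_composition", csc_composition(cscs, labels))
  enr_cfg <- cfg; enr_cfg$n_perm <- n_perm_enrichment
  pool <- labels$gene_id[labels$expression_class != "NEG"]
  enrich_am <- stage("enrichment_am", phase_enrichment_test(
    cscs[cscs$csc_class == "AM-specific", ], labels, phase_center = 8,
    pool = pool, cfg = enr_cfg, time_label = "t08", seed = seed + 10L))
  enrich_pm <- stage("enrichment_pm", phase_enrichment_test(
    cscs[cscs$csc_class == "PM-specific", ], labels, phase_center = 20,
    pool = pool, cfg = enr_cfg, time_label = "t20", seed = seed + 11L))

  breadth <- expression_breadth(ds$tissue_fpkm, cfg)
  g_am <- stage("graph_am", build_graph(pairs_am, labels, breadth, ds$genes))
  g_pm <- stage("graph_pm", build_graph(pairs_pm, labels, breadth, ds$genes))
  # seeds: the most-connected rhythmic morning-phase nodes of the AM graph
  am_deg <- igraph::degree(g_am)
  rg_morning <- labels$gene_id[labels$expression_class == "RG" &
                                 circular_phase_diff(labels$phase_h, 8) <= 4]
  seed_pool <- intersect(names(sort(am_deg, decreasing = TRUE)), rg_morning)
  net_seeds <- utils::head(seed_pool, 7)
  net_am <- stage("network_am", hop_expand(g_am, net_seeds, hops = 2))
  net_pm <- if (all(!net_seeds %in% igraph::V(g_pm)$name)) NULL else {
    stage("network_pm", suppressWarnings(hop_expand(g_pm, net_seeds, hops = 2)))
  }
  nd <- stage("diff_networks", diff_networks(g_am, g_pm))

  am_nodes <- cscs$node_gene[cscs$csc_class == "AM-specific"]
  prof_am <- stage("profile_am", tss_centered_profile(pairs_am, ds$genes, am_nodes))
  prof_pm <- stage("profile_pm", tss_centered_profile(pairs_pm, ds$genes, am_nodes))

  report <- build_report(ds, cfg, calls_expr, calls_occ, labels, pairs_am, pairs_pm,
                         tp, lag, pcor, cscs, enrich_am, enrich_pm,
                         net_am, net_pm, net_seeds)
  utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c("# circaloop run report", "",
               sprintf("- %s: %s", report$metric, report$value)),
             file.path(out_dir, "report.md"))
  utils::write.table(calls_expr, file.path(out_dir, "rhythm_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(labels, file.path(out_dir, "gene_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pairs_am, file.path(out_dir, "pairs_t08.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pairs_pm, file.path(out_dir, "pairs_t20.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  csc_flat <- cscs[, c("node_gene", "degree_am", "degree_pm", "csc_class")]
  utils::write.table(csc_flat, file.path(out_dir, "cscs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_graph(net_am, file.path(out_dir, "network_am.graphml"), "graphml")

  manifest <- list(
    package_version = as.character(utils::packageVersion("circaloop")),
    seed = seed,
    sim_config = unclass(sim_cfg),
    run_config = unclass(cfg),
    input_digests = as.list(tools::md5sum(unname(files))),
    stage_seconds = as.list(timings)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(dataset = ds, calls_expr = calls_expr, calls_occ = calls_occ,
                 labels = labels, peak_map = peak_map,
                 pairs_am = pairs_am, pairs_pm = pairs_pm, time_points = tp,
                 lag = lag, correlation = pcor, cscs = cscs,
                 composition = composition,
                 enrichment = list(am = enrich_am, pm = enrich_pm),
                 graphs = list(am = g_am, pm = g_pm),
                 networks = list(am = net_am, pm = net_pm, seeds = net_seeds),
                 network_diff = nd,
                 profiles = list(am = prof_am, pm = prof_pm),
                 report = report, manifest = manifest, out_dir = out_dir))
}

build_report <- function(ds, cfg, calls_expr, calls_occ, labels, pairs_am,
                         pairs_pm, tp, lag, pcor, cscs, enrich_am, enrich_pm,
                         net_am, net_pm, net_seeds) {
  pct <- function(x) sprintf("%.1f%%", 100 * x)
  cls_tab <- table(factor(labels$expression_class, c("RG", "NG", "NEG")))
  pair_tab <- table(factor(c(pairs_am$pair_class, pairs_pm$pair_class),
                           c("RR", "RN", "NN", "NEG-associated")))
  csc_tab <- table(factor(cscs$csc_class, c("AM-specific", "PM-specific", "static")))
  rose <- table(cut(labels$phase_h[labels$expression_class == "RG"],
                    breaks = seq(0, 24, 4), include.lowest = TRUE))
  comps_pm <- if (is.null(net_pm)) NA_integer_ else igraph::count_components(net_pm)
  data.frame(
    metric = c("n_genes", "rhythmic_fraction_expressed", "rhythmic_occupancy_fraction",
               "phase_rose_0_4_8_12_16_20",
               "mean_phase_lag_h", "overall_signal_expression_pcc",
               "n_RG", "n_NG", "n_NEG",
               "pair_pct_RR", "pair_pct_RN", "pair_pct_NN", "pair_pct_NEG",
               "loops_time_specific_fraction",
               "n_csc_am", "n_csc_pm", "n_csc_static",
               "enrichment_p_am", "enrichment_p_pm",
               "network_seeds", "am_network_components", "pm_network_components"),
    value = c(nrow(ds$genes),
              pct(mean(calls_expr$is_rhythmic[rowSums(ds$counts[calls_expr$feature_id, ]) >
                                                cfg$expressed_min])),
              pct(mean(calls_occ$is_rhythmic)),
              paste(as.integer(rose), collapse = "/"),
              sprintf("%.2f", lag$mean_lag_h),
              sprintf("%.2f", pcor$overall),
              cls_tab[["RG"]], cls_tab[["NG"]], cls_tab[["NEG"]],
              pct(unname(pair_tab["RR"] / sum(pair_tab))),
              pct(unname(pair_tab["RN"] / sum(pair_tab))),
              pct(unname(pair_tab["NN"] / sum(pair_tab))),
              pct(unname(pair_tab["NEG-associated"] / sum(pair_tab))),
              pct(tp$summary$frac_specific),
              csc_tab[["AM-specific"]], csc_tab[["PM-specific"]], csc_tab[["static"]],
              sprintf("%.4g", enrich_am$p_value), sprintf("%.4g", enrich_pm$p_value),
              paste(net_seeds, collapse = ","),
              igraph::count_components(net_am), comps_pm),
    stringsAsFactors = FALSE
  )
}

#' Score pipeline output against simulation truth
#'
#' Computes the recovery metrics of a synthetic run: balanced accuracy of
#' RG/NG/NEG classification against the designed classes, circular mean
#' absolute phase error over genes both truly and detectably rhythmic, the
#' error of the recovered occupancy-expression lag against the configured
#' lead, and the fraction of designed CSC nodes recovered with their designed
#' class.
#'
#' @param run result list from [run_all()] (or a list with compatible
#'   `dataset`, `labels`, `lag`, `cscs` members).
#' @return one-row data.frame of recovery metrics.
#' @export
validate_against_truth <- function(run) {
  ds <- run$dataset
  truth_cls <- c("rhythmic" = "RG", "non-rhythmic" = "NG", "non-expressed" = "NEG")
  want <- truth_cls[ds$truth$expression_class]
  got <- run$labels$expression_class[match(ds$truth$gene_id, run$labels$gene_id)]
  if (any(is.na(got))) stop("truth/output gene id mismatch")
  recall <- vapply(unique(want), function(cl) mean(got[want == cl] == cl), numeric(1))
  balanced_acc <- mean(recall)

  rg <- ds$truth$expression_class == "rhythmic" & got == "RG"
  phase_err <- circular_phase_diff(
    run$labels$phase_h[match(ds$truth$gene_id[rg], run$labels$gene_id)],
    ds$truth$true_phase[rg])
  lag_err <- abs(run$lag$mean_lag_h - ds$cfg$lag_hours)

  truth_csc <- ds$csc_truth
  got_csc <- run$cscs[match(truth_csc$node_gene, run$cscs$node_gene), "csc_class"]
  csc_recovery <- mean(!is.na(got_csc) & got_csc == truth_csc$designed_class)

  data.frame(balanced_accuracy = balanced_acc,
             phase_mae_h = mean(phase_err),
             phase_median_ae_h = stats::median(phase_err),
             lag_error_h = lag_err,
             csc_class_recovery = csc_recovery)
}
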
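# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes — a morning-clustered rhythmic transcriptome (~37% of
# expressed genes), RNAPII occupancy leading expression by a configurable
# lag, loop sets at 08:00/20:00 whose gene pairs are preferentially
# phase-coherent, and a designed mixture of AM/PM/static spatial clusters —
# together with ground-truth labels so every downstream stage is testable.

#' Synthetic-dataset configuration
#'
#' Defaults mirror the study conditions: 2000 genes on 4 chromosomes sampled
#' at six time points over two replicate days; 37% of genes rhythmic with
#' phases concentrated around 08:00; 30% non-expressed; occupancy leading
#' expression by 2 h; multiplicative noise with CV 0.15; 3000 loops per time
#' point with 70% of rhythmic-rhythmic loops drawn phase-coherent; and 60
#' designed AM-specific, PM-specific and static cluster nodes each.
#'
#' @param n_genes number of genes.
#' @param n_chroms number of chromosomes.
#' @param frac_rhythmic probability a gene is truly rhythmic.
#' @param frac_non_expressed probability a gene is non-expressed.
#' @param phase_mean_h circular mean of true phases (hours).
#' @param phase_kappa von Mises concentration of true phases (0 = uniform).
#' @param lag_hours occupancy lead over mRNA, hours in `[0, 12)`.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise on each sample.
#' @param n_loops_per_time total loops emitted at each of t08 and t20.
#' @param csc_design list with `n_am`, `n_pm`, `n_static` designed node
#'   counts and `degree_min`/`degree_max` spoke-degree range.
#' @param rr_coherence probability that a rhythmic-rhythmic background loop
#'   is drawn with circular phase span <= 4 h.
#' @param neg_loop_frac fraction of background loops anchored at a
#'   non-expressed gene (annotation-artifact anchors; mechanism deliberately
#'   unspecified, see the methods vignette).
#' @param n_tissues tissues in the expression-breadth panel.
#' @param amp_range range of relative cosine amplitudes for rhythmic genes.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-gene
#'   baseline expression.
#' @param seed default seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_chroms = 4,
                       frac_rhythmic = 0.37, frac_non_expressed = 0.30,
                       phase_mean_h = 8, phase_kappa = 2,
                       lag_hours = 2, noise_cv = 0.15,
                       n_loops_per_time = 3000,
                       csc_design = list(n_am = 60, n_pm = 60, n_static = 60,
                                         degree_min = 3, degree_max = 9),
                       rr_coherence = 0.7, neg_loop_frac = 0.05,
                       n_tissues = 20, amp_range = c(0.4, 0.9),
                       baseline_meanlog = log(100), baseline_sdlog = 0.6,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_genes >= cfg$n_chroms,
    cfg$frac_rhythmic >= 0, cfg$frac_rhythmic <= 1,
    cfg$frac_non_expressed >= 0, cfg$frac_non_expressed <= 1,
    cfg$frac_rhythmic + cfg$frac_non_expressed <= 1,
    cfg$lag_hours >= 0, cfg$lag_hours < 12,
    cfg$noise_cv >= 0, cfg$rr_coherence >= 0, cfg$rr_coherence <= 1,
    cfg$neg_loop_frac >= 0, cfg$neg_loop_frac < 1
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate non-overlapping gene models
#'
#' Genes are placed sequentially per chromosome with lengths drawn uniformly
#' from 1--10 kb and inter-gene gaps from 1--20 kb; strands are random.
#' Deterministic given `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return gene-model data.frame (`gene_id, chrom, start, end, strand`) with
#'   a `chrom_sizes` attribute.
#' @export
simulate_genome <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(cfg$n_genes >= cfg$n_chroms)
  with_seed(seed, {
    per <- diff(floor(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
    rows <- vector("list", cfg$n_chroms)
    sizes <- numeric(cfg$n_chroms)
    idx0 <- 0L
    for (k in seq_len(cfg$n_chroms)) {
      m <- per[k]
      gaps <- sample(1000:20000, m, replace = TRUE)
      lens <- sample(1000:10000, m, replace = TRUE)
      starts <- cumsum(gaps) + c(0, cumsum(lens))[seq_len(m)]
      ends <- starts + lens
      rows[[k]] <- data.frame(
        gene_id = sprintf("g%05d", idx0 + seq_len(m)),
        chrom = sprintf("chr%d", k),
        start = starts, end = ends,
        strand = sample(c("+", "-"), m, replace = TRUE),
        stringsAsFactors = FALSE
      )
      sizes[k] <- ends[m] + 10000
      idx0 <- idx0 + m
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
    names(sizes) <- sprintf("chr%d", seq_len(cfg$n_chroms))
    attr(genes, "chrom_sizes") <- sizes
    genes
  })
}

# Multiplicative lognormal noise with unit mean and the configured CV.
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a diurnal expression count matrix with truth labels
#'
#' Rhythmic genes follow `m * (1 + A * cos(2*pi*(t - phi)/24))` with
#' multiplicative lognormal noise; non-rhythmic genes a constant mean with
#' the same noise; non-expressed genes near-zero counts. Both replicate days
#' share the true phase, so day-to-day variation enters only through noise.
#'
#' @param genes gene models from [simulate_genome()].
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `counts` (genes x 12 samples) and `truth` (data.frame
#'   `gene_id, expression_class, true_phase, true_amplitude, baseline`).
#' @export
simulate_expression <- function(genes, cfg = sim_config(), seed = cfg$seed) {
  with_seed(seed, {
    n <- nrow(genes)
    u <- stats::runif(n)
    cls <- ifelse(u < cfg$frac_rhythmic, "rhythmic",
                  ifelse(u < cfg$frac_rhythmic + cfg$frac_non_expressed,
                         "non-expressed", "non-rhythmic"))
    phase <- rep(NA_real_, n)
    nr <- sum(cls == "rhythmic")
    phase[cls == "rhythmic"] <-
      rvonmises(nr, mu = cfg$phase_mean_h / 24 * 2 * pi, kappa = cfg$phase_kappa) /
      (2 * pi) * 24
    amp <- rep(NA_real_, n)
    amp[cls == "rhythmic"] <- stats::runif(nr, cfg$amp_range[1], cfg$amp_range[2])
    base <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)

    labs <- time_labels()
    t <- times_from_labels(labs)
    counts <- matrix(0, n, length(labs), dimnames = list(genes$gene_id, labs))
    for (i in seq_len(n)) {
      counts[i, ] <- switch(cls[i],
        "rhythmic" = base[i] * (1 + amp[i] * cos(2 * pi * (t - phase[i]) / 24)) *
          lognormal_noise(length(t), cfg$noise_cv),
        "non-rhythmic" = base[i] * lognormal_noise(length(t), cfg$noise_cv),
        "non-expressed" = stats::rpois(length(t), 0.2)
      )
    }
    truth <- data.frame(gene_id = genes$gene_id, expression_class = cls,
                        true_phase = phase, true_amplitude = amp,
                        baseline = base, stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

# Strand-aware TSS of each gene (0-based position).
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

#' Simulate per-time RNAPII occupancy peaks
#'
#' Every expressed gene receives one promoter peak with its summit just
#' inside the gene body near the TSS. Rhythmic genes' peak intensity traces
#' oscillate at `gene phase - lag_hours` (mod 24), so polymerase recruitment
#' leads transcript accumulation; non-rhythmic genes get flat noisy traces.
#' Non-expressed genes receive no peak.
#'
#' @param genes gene models.
#' @param truth truth labels from [simulate_expression()].
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `peaks` (data.frame `peak_id, chrom, start, end,
#'   summit`), `signal` (peaks x 12 sample matrix), and `peak_gene`
#'   (data.frame `peak_id, gene_id` truth mapping).
#' @export
simulate_occupancy <- function(genes, truth, cfg = sim_config(), seed = cfg$seed) {
  with_seed(seed, {
    expressed <- truth$expression_class != "non-expressed"
    g <- genes[expressed, , drop = FALSE]
    tr <- truth[expressed, , drop = FALSE]
    n <- nrow(g)
    tss <- gene_tss(g)
    plus <- g$strand == "+"
    start <- ifelse(plus, pmax(0, tss - 200), tss - 300)
    end <- ifelse(plus, tss + 300, tss + 200)
    summit <- ifelse(plus, tss + 50, tss - 50)
    labs <- time_labels()
    t <- times_from_labels(labs)
    base <- stats::rlnorm(n, log(50), 0.5)
    sig <- matrix(0, n, length(labs),
                  dimnames = list(sprintf("p%05d", seq_len(n)), labs))
    rhythmic <- tr$expression_class == "rhythmic"
    occ_phase <- (tr$true_phase - cfg$lag_hours) %% 24
    for (i in seq_len(n)) {
      mean_trace <- if (rhythmic[i]) {
        base[i] * (1 + tr$true_amplitude[i] * cos(2 * pi * (t - occ_phase[i]) / 24))
      } else rep(base[i], length(t))
      sig[i, ] <- mean_trace * lognormal_noise(length(t), cfg$noise_cv)
    }
    peaks <- data.frame(peak_id = rownames(sig), chrom = g$chrom,
                        start = start, end = end, summit = summit,
                        stringsAsFactors = FALSE)
    list(peaks = peaks,
         signal = sig,
         peak_gene = data.frame(peak_id = peaks$peak_id, gene_id = g$gene_id,
                                stringsAsFactors = FALSE))
  })
}

# Promoter anchor interval (TSS +- 250 bp, clipped at 0) for loop emission.
promoter_anchor <- function(genes) {
  tss <- gene_tss(genes)
  data.frame(chrom = genes$chrom, start = pmax(0, tss - 250), end = tss + 250,
             stringsAsFactors = FALSE)
}

loop_row <- function(anch, i, j, pet, fdr, time_label) {
  data.frame(chrom_a = anch$chrom[i], start_a = anch$start[i], end_a = anch$end[i],
             chrom_b = anch$chrom[j], start_b = anch$start[j], end_b = anch$end[j],
             pet_count = pet, fdr = fdr, time_label = time_label,
             stringsAsFactors = FALSE)
}

#' Simulate loop sets at t08 and t20 with designed spatial clusters
#'
#' Designed node genes receive star-shaped loop sets: AM-design nodes have
#' degree >= `degree_min` at t08 and degree 0--1 at t20 (so the degree ratio
#' exceeds the classification threshold); PM-design nodes are symmetric;
#' static nodes have equal degrees at both times with ~10% of linked genes in
#' common. Remaining loops are background pairs among expressed genes;
#' rhythmic-rhythmic background pairs are drawn with circular phase span
#' <= 4 h with probability `rr_coherence`. All anchors are gene promoter
#' windows, every intrachromosomal loop spans > 8 kb between anchor
#' midpoints, and every loop satisfies `pet >= 5`, `fdr < 0.05`.
#'
#' @param genes gene models.
#' @param truth truth labels from [simulate_expression()].
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `loops` (BEDPE-style data.frame for both time labels),
#'   `loop_truth` (per-loop `time_label, gene_a, gene_b, origin`), and
#'   `csc_truth` (`node_gene, designed_class, deg_am, deg_pm`).
#' @export
simulate_loops <- function(genes, truth, cfg = sim_config(), seed = cfg$seed) {
  with_seed(seed, {
    des <- cfg$csc_design
    anch <- promoter_anchor(genes)
    mid <- midpoint0(anch$start, anch$end)
    idx_of <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)
    expressed_ids <- truth$gene_id[truth$expression_class != "non-expressed"]
    rhythmic_ids <- truth$gene_id[truth$expression_class == "rhythmic"]
    neg_ids <- truth$gene_id[truth$expression_class == "non-expressed"]
    phase_of <- stats::setNames(truth$true_phase, truth$gene_id)

    n_nodes <- des$n_am + des$n_pm + des$n_static
    if (length(expressed_ids) < n_nodes + des$degree_max * 3) {
      stop("CSC design exceeds available expressed genes")
    }
    nodes <- sample(expressed_ids, n_nodes)
    node_class <- rep(c("AM-specific", "PM-specific", "static"),
                      c(des$n_am, des$n_pm, des$n_static))
    # background pairs avoid designed nodes so designed degrees stay exact
    partner_pool <- setdiff(expressed_ids, nodes)
    bg_pool <- partner_pool
    bg_rhythmic <- intersect(rhythmic_ids, bg_pool)

    # distance rule: same chrom needs mid-to-mid span > 8 kb
    ok_pair <- function(a, b) {
      ia <- idx_of[[a]]; ib <- idx_of[[b]]
      anch$chrom[ia] != anch$chrom[ib] || abs(mid[ia] - mid[ib]) > 8000
    }
    # spokes mix genomically local partners (within 20 gene ranks, still
    # > 8 kb away) with genome-wide ones, giving clusters the distance decay
    # real loop sets show
    gene_rank <- stats::ave(seq_len(nrow(genes)), genes$chrom, FUN = seq_along)
    names(gene_rank) <- genes$gene_id
    draw_partners <- function(node, k, pool, local_frac = 0.5) {
      pool <- setdiff(pool, node)
      ni <- idx_of[[node]]
      local <- pool[genes$chrom[idx_of[pool]] == genes$chrom[ni] &
                      abs(gene_rank[pool] - gene_rank[[node]]) <= 20]
      got <- character(0)
      n_local <- min(length(local), round(local_frac * k))
      for (g in sample(local)) {
        if (length(got) >= n_local) break
        if (ok_pair(node, g)) got <- c(got, g)
      }
      for (g in sample(setdiff(pool, got))) {
        if (length(got) >= k) break
        if (ok_pair(node, g)) got <- c(got, g)
      }
      if (length(got) < k) stop("CSC design infeasible: not enough distant partners")
      got
    }

    loops <- list(); tr_rows <- list(); csc_rows <- list()
    add_star <- function(node, partners, time_label, origin) {
      ia <- idx_of[[node]]; ib <- idx_of[partners]
      loops[[length(loops) + 1]] <<- loop_row(
        anch, rep(ia, length(ib)), ib,
        pet = sample(5:40, length(ib), replace = TRUE),
        fdr = stats::runif(length(ib), 0, 0.049), time_label = time_label)
      tr_rows[[length(tr_rows) + 1]] <<- data.frame(
        time_label = time_label, gene_a = node, gene_b = partners,
        origin = origin, stringsAsFactors = FALSE)
    }

    for (i in seq_len(n_nodes)) {
      nd <- nodes[i]
      d_hi <- sample(max(des$degree_min, 4):des$degree_max, 1)
      if (node_class[i] == "static") {
        d <- sample(des$degree_min:max(des$degree_min, 6), 1)
        n_common <- max(1L, round(0.18 * d))
        common <- draw_partners(nd, n_common, partner_pool)
        spec_am <- draw_partners(nd, d - n_common, setdiff(partner_pool, common))
        spec_pm <- draw_partners(nd, d - n_common,
                                 setdiff(partner_pool, c(common, spec_am)))
        add_star(nd, c(common, spec_am), "t08", "static_node")
        add_star(nd, c(common, spec_pm), "t20", "static_node")
        csc_rows[[length(csc_rows) + 1]] <- data.frame(
          node_gene = nd, designed_class = "static", deg_am = d, deg_pm = d,
          stringsAsFactors = FALSE)
      } else {
        d_lo <- sample(0:1, 1)
        hi_t <- if (node_class[i] == "AM-specific") "t08" else "t20"
        lo_t <- if (hi_t == "t08") "t20" else "t08"
        partners <- draw_partners(nd, d_hi, partner_pool)
        add_star(nd, partners, hi_t, paste0(tolower(substr(node_class[i], 1, 2)), "_node"))
        if (d_lo > 0) {
          add_star(nd, draw_partners(nd, d_lo, partner_pool), lo_t,
                   paste0(tolower(substr(node_class[i], 1, 2)), "_node"))
        }
        csc_rows[[length(csc_rows) + 1]] <- data.frame(
          node_gene = nd, designed_class = node_class[i],
          deg_am = if (hi_t == "t08") d_hi else d_lo,
          deg_pm = if (hi_t == "t20") d_hi else d_lo,
          stringsAsFactors = FALSE)
      }
    }

    # background loops fill each time point up to n_loops_per_time
    draw_background <- function(time_label, n_bg) {
      a_vec <- b_vec <- character(n_bg); origin <- character(n_bg)
      for (k in seq_len(n_bg)) {
        repeat {
          if (length(neg_ids) > 0 && stats::runif(1) < cfg$neg_loop_frac) {
            a <- sample(neg_ids, 1); b <- sample(bg_pool, 1); org <- "background_neg"
          } else {
            a <- sample(bg_pool, 1)
            coherent <- a %in% bg_rhythmic && stats::runif(1) < cfg$rr_coherence
            if (coherent) {
              near <- bg_rhythmic[circular_phase_diff(phase_of[bg_rhythmic],
                                                      phase_of[[a]]) <= 4]
              near <- setdiff(near, a)
              b <- if (length(near)) sample(near, 1) else sample(setdiff(bg_pool, a), 1)
            } else {
              b <- sample(setdiff(bg_pool, a), 1)
            }
            org <- "background"
          }
          if (a != b && ok_pair(a, b)) break
        }
        a_vec[k] <- a; b_vec[k] <- b; origin[k] <- org
      }
      loops[[length(loops) + 1]] <<- loop_row(
        anch, idx_of[a_vec], idx_of[b_vec],
        pet = sample(5:40, n_bg, replace = TRUE),
        fdr = stats::runif(n_bg, 0, 0.049), time_label = time_label)
      tr_rows[[length(tr_rows) + 1]] <<- data.frame(
        time_label = time_label, gene_a = a_vec, gene_b = b_vec,
        origin = origin, stringsAsFactors = FALSE)
    }
    current <- do.call(rbind, tr_rows)
    for (tl in c("t08", "t20")) {
      n_designed <- sum(current$time_label == tl)
      if (n_designed > cfg$n_loops_per_time) {
        stop("csc_design emits more loops than n_loops_per_time")
      }
      draw_background(tl, cfg$n_loops_per_time - n_designed)
    }

    loops <- canonical_loops(do.call(rbind, loops))
    list(loops = loops,
         loop_truth = do.call(rbind, tr_rows),
         csc_truth = do.call(rbind, csc_rows))
  })
}

#' Simulate a tissue-by-gene FPKM panel for expression breadth
#'
#' Truth-rhythmic genes are drawn broadly expressed (high tissue counts);
#' non-rhythmic genes span narrow-to-broad breadths; non-expressed genes stay
#' below the FPKM threshold everywhere.
#'
#' @param genes gene models.
#' @param truth truth labels.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return FPKM matrix, `n_tissues` rows x genes columns.
#' @export
simulate_tissue_panel <- function(genes, truth, cfg = sim_config(), seed = cfg$seed) {
  with_seed(seed, {
    nt <- cfg$n_tissues
    m <- matrix(stats::runif(nt * nrow(genes), 0, 0.5), nt, nrow(genes),
                dimnames = list(sprintf("tissue%02d", seq_len(nt)), genes$gene_id))
    for (i in seq_len(nrow(genes))) {
      b <- switch(truth$expression_class[i],
                  "rhythmic" = sample(seq(max(1, nt - 4), nt), 1),
                  "non-rhythmic" = sample(seq_len(max(1, nt - 6)), 1),
                  "non-expressed" = 0L)
      if (b > 0) {
        m[sample(nt, b), i] <- 1 + stats::rlnorm(b, log(8), 0.5)
      }
    }
    m
  })
}

#' Simulate a complete study dataset
#'
#' Runs genome, expression, occupancy, loop, and tissue-panel simulation with
#' per-stage seeds derived deterministically from `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed.
#' @return list with `genes`, `chrom_sizes`, `counts`, `truth`, `occupancy`,
#'   `loops`, `loop_truth`, `csc_truth`, `tissue_fpkm`, `cfg`, `seed`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = cfg$seed) {
  genes <- simulate_genome(cfg, seed + 1L)
  expr <- simulate_expression(genes, cfg, seed + 2L)
  occ <- simulate_occupancy(genes, expr$truth, cfg, seed + 3L)
  lp <- simulate_loops(genes, expr$truth, cfg, seed + 4L)
  tis <- simulate_tissue_panel(genes, expr$truth, cfg, seed + 5L)
  list(genes = genes, chrom_sizes = attr(genes, "chrom_sizes"),
       counts = expr$counts, truth = expr$truth,
       occupancy = occ, loops = lp$loops, loop_truth = lp$loop_truth,
       csc_truth = lp$csc_truth, tissue_fpkm = tis, cfg = cfg, seed = seed)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits gene models (BED6), per-clock-time peak files (narrowPeak, signal =
#' mean of the two replicate days), the expression matrix (TSV), loop files
#' (BEDPE per time label), the tissue panel (TSV), and truth labels (JSON).
#'
#' @param ds dataset from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genes = file.path(dir, "genes.bed"),
             expression = file.path(dir, "expression.tsv"),
             tissue = file.path(dir, "tissue_fpkm.tsv"),
             truth = file.path(dir, "truth.json"))
  write_gene_models(ds$genes, paths["genes"])
  write_matrix(ds$counts, paths["expression"], id_col = "gene_id")
  write_matrix(ds$tissue_fpkm, paths["tissue"], id_col = "tissue")
  for (tl in clock_labels()) {
    p <- ds$occupancy$peaks
    p$signal <- rowMeans(ds$occupancy$signal[, paste0(c("d1_", "d2_"), tl), drop = FALSE])
    f <- file.path(dir, paste0("peaks_", tl, ".narrowPeak"))
    write_peaks(p, f)
    paths[paste0("peaks_", tl)] <- f
  }
  for (tl in unique(ds$loops$time_label)) {
    f <- file.path(dir, paste0("loops_", tl, ".bedpe"))
    write_loops(ds$loops[ds$loops$time_label == tl, ], f)
    paths[paste0("loops_", tl)] <- f
  }
  jsonlite::write_json(
    list(truth = ds$truth, loop_truth = ds$loop_truth, csc_truth = ds$csc_truth,
         peak_gene = ds$occupancy$peak_gene, seed = ds$seed),
    paths["truth"], dataframe = "columns", na = "null", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
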
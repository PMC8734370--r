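# Loop filtering, gene-pair derivation and classification, time-point
# comparison, coexpression, and distance-matched random controls.

#' Filter raw loops
#'
#' Keeps loops with `fdr < fdr_max` and `pet_count >= min_pet`; an
#' intrachromosomal loop must additionally span more than `min_intra_span`
#' between anchor midpoints (shorter products are treated as self-ligation
#' artifacts). Interchromosomal loops are exempt from the span test.
#' Idempotent and order-independent.
#'
#' @param loops loop data.frame.
#' @param cfg a [circa_config()].
#' @return the retained loops.
#' @export
filter_loops <- function(loops, cfg = circa_config()) {
  intra <- loops$chrom_a == loops$chrom_b
  span <- abs(midpoint0(loops$start_b, loops$end_b) -
                midpoint0(loops$start_a, loops$end_a))
  keep <- loops$fdr < cfg$fdr_max & loops$pet_count >= cfg$min_pet &
    (!intra | span > cfg$min_intra_span)
  out <- loops[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Anchor -> gene sets via overlapping peaks and their assigned genes.
anchor_genes <- function(chrom, start, end, peaks, peak_gene_map) {
  gr_anch <- as_granges0(chrom, start, end)
  gr_peaks <- as_granges0(peaks$chrom, peaks$start, peaks$end)
  hits <- GenomicRanges::findOverlaps(gr_anch, gr_peaks, ignore.strand = TRUE)
  gid <- peak_gene_map$gene_id[match(peaks$peak_id[S4Vectors::subjectHits(hits)],
                                     peak_gene_map$peak_id)]
  ok <- !is.na(gid)
  split(gid[ok], factor(S4Vectors::queryHits(hits)[ok], levels = seq_along(chrom)))
}

#' Derive unique interacting gene pairs from loops
#'
#' Each loop anchor is mapped to genes through the RNAPII peaks it overlaps
#' and their peak-to-gene assignment; every combination of genes on the two
#' sides yields a candidate pair. Self-pairs are dropped, pairs are
#' unordered, and duplicates collapse to one pair with summed PET support.
#' Pair classes follow the gene labels: any member NEG gives
#' `"NEG-associated"` (taking precedence), both RG gives `"RR"`, one RG gives
#' `"RN"`, otherwise `"NN"`.
#'
#' @param loops filtered loop data.frame (one time label).
#' @param peaks peak data.frame for the same time point.
#' @param peak_gene_map data.frame `peak_id, gene_id` from
#'   [assign_peaks_to_genes()].
#' @param labels gene labels from [classify_gene_expression()].
#' @param genes gene models, used for pair genomic distance (TSS-anchor
#'   midpoints are not needed; distance = midpoint distance of gene bodies).
#' @return data.frame `gene_a, gene_b, pair_class, pet_count, n_loops,
#'   distance` (`NA` distance = interchromosomal), `phase_span` (RR only).
#' @export
loops_to_gene_pairs <- function(loops, peaks, peak_gene_map, labels, genes) {
  ga <- anchor_genes(loops$chrom_a, loops$start_a, loops$end_a, peaks, peak_gene_map)
  gb <- anchor_genes(loops$chrom_b, loops$start_b, loops$end_b, peaks, peak_gene_map)
  pieces <- lapply(seq_len(nrow(loops)), function(i) {
    a <- unique(ga[[i]]); b <- unique(gb[[i]])
    if (length(a) == 0 || length(b) == 0) return(NULL)
    eg <- expand.grid(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
    eg <- eg[eg$gene_a != eg$gene_b, , drop = FALSE]
    if (nrow(eg) == 0) return(NULL)
    eg$pet_count <- loops$pet_count[i]
    eg
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pair_class = character(0), pet_count = integer(0),
                      n_loops = integer(0), distance = numeric(0),
                      phase_span = numeric(0)))
  }
  raw <- do.call(rbind, pieces)
  swap <- raw$gene_a > raw$gene_b
  tmp <- raw$gene_a[swap]; raw$gene_a[swap] <- raw$gene_b[swap]; raw$gene_b[swap] <- tmp
  key <- paste(raw$gene_a, raw$gene_b, sep = "\r")
  agg_pet <- tapply(raw$pet_count, key, sum)
  agg_n <- tapply(raw$pet_count, key, length)
  uk <- names(agg_pet)
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  pairs <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                      pet_count = as.integer(agg_pet), n_loops = as.integer(agg_n),
                      stringsAsFactors = FALSE)
  pairs$pair_class <- classify_pair(pairs$gene_a, pairs$gene_b, labels)
  gi_a <- match(pairs$gene_a, genes$gene_id)
  gi_b <- match(pairs$gene_b, genes$gene_id)
  same <- genes$chrom[gi_a] == genes$chrom[gi_b]
  pairs$distance <- ifelse(same,
                           abs(midpoint0(genes$start[gi_b], genes$end[gi_b]) -
                                 midpoint0(genes$start[gi_a], genes$end[gi_a])),
                           NA_real_)
  la <- match(pairs$gene_a, labels$gene_id)
  lb <- match(pairs$gene_b, labels$gene_id)
  pairs$phase_span <- ifelse(pairs$pair_class == "RR",
                             circular_phase_diff(labels$phase_h[la], labels$phase_h[lb]),
                             NA_real_)
  rownames(pairs) <- NULL
  pairs
}

# Pair class from two gene labels; NEG membership takes precedence.
classify_pair <- function(gene_a, gene_b, labels) {
  cls <- stats::setNames(labels$expression_class, labels$gene_id)
  ca <- cls[gene_a]; cb <- cls[gene_b]
  if (any(is.na(ca)) || any(is.na(cb))) stop("pair gene missing from labels")
  ifelse(ca == "NEG" | cb == "NEG", "NEG-associated",
         ifelse(ca == "RG" & cb == "RG", "RR",
                ifelse(ca == "RG" | cb == "RG", "RN", "NN")))
}

#' Compare loop sets between two time points
#'
#' A loop is common when a loop at the other time point overlaps it on both
#' anchors (>= 1 bp each, after canonical anchor ordering); otherwise it is
#' time-specific. The test is symmetric.
#'
#' @param loops_t1,loops_t2 filtered loop data.frames.
#' @return list with `common_t1`, `common_t2`, `specific_t1`, `specific_t2`
#'   data.frames and a `summary` row of counts and fractions.
#' @export
compare_time_points <- function(loops_t1, loops_t2) {
  match_other <- function(x, y) {
    if (nrow(x) == 0 || nrow(y) == 0) return(rep(FALSE, nrow(x)))
    ha <- GenomicRanges::findOverlaps(as_granges0(x$chrom_a, x$start_a, x$end_a),
                                      as_granges0(y$chrom_a, y$start_a, y$end_a),
                                      ignore.strand = TRUE)
    hb <- GenomicRanges::findOverlaps(as_granges0(x$chrom_b, x$start_b, x$end_b),
                                      as_granges0(y$chrom_b, y$start_b, y$end_b),
                                      ignore.strand = TRUE)
    ka <- paste(S4Vectors::queryHits(ha), S4Vectors::subjectHits(ha))
    kb <- paste(S4Vectors::queryHits(hb), S4Vectors::subjectHits(hb))
    both <- intersect(ka, kb)
    idx <- unique(as.integer(sub(" .*", "", both)))
    seq_len(nrow(x)) %in% idx
  }
  c1 <- match_other(loops_t1, loops_t2)
  c2 <- match_other(loops_t2, loops_t1)
  n_total <- nrow(loops_t1) + nrow(loops_t2)
  list(common_t1 = loops_t1[c1, , drop = FALSE],
       common_t2 = loops_t2[c2, , drop = FALSE],
       specific_t1 = loops_t1[!c1, , drop = FALSE],
       specific_t2 = loops_t2[!c2, , drop = FALSE],
       summary = data.frame(
         n_t1 = nrow(loops_t1), n_t2 = nrow(loops_t2),
         n_common_t1 = sum(c1), n_common_t2 = sum(c2),
         n_specific = sum(!c1) + sum(!c2),
         frac_specific = if (n_total) (sum(!c1) + sum(!c2)) / n_total else NA_real_))
}

#' Pearson coexpression of gene pairs over the time course
#'
#' @param pairs gene-pair data.frame.
#' @param expr expression matrix (genes x samples).
#' @return `pairs` with a `pcc` column; zero-variance members give `NA` with
#'   `pcc_flag = "zero_variance"`.
#' @export
pair_coexpression <- function(pairs, expr) {
  ia <- match(pairs$gene_a, rownames(expr))
  ib <- match(pairs$gene_b, rownames(expr))
  if (any(is.na(ia)) || any(is.na(ib))) stop("pair gene missing from expression matrix")
  sda <- apply(expr[ia, , drop = FALSE], 1, stats::sd)
  sdb <- apply(expr[ib, , drop = FALSE], 1, stats::sd)
  ok <- sda > 0 & sdb > 0
  pcc <- rep(NA_real_, nrow(pairs))
  pcc[ok] <- vapply(which(ok), function(k) stats::cor(expr[ia[k], ], expr[ib[k], ]),
                    numeric(1))
  pairs$pcc <- pcc
  pairs$pcc_flag <- ifelse(ok, "ok", "zero_variance")
  pairs
}

#' Distance-matched random gene-pair controls
#'
#' Observed intrachromosomal pair distances are binned in log10 bins of the
#' given width; each draw samples, per bin, the observed number of random
#' same-chromosome pairs from the candidate pool whose distance falls in
#' that bin. Interchromosomal observed pairs are matched by random
#' cross-chromosome pool pairs. A bin the pool cannot populate is widened
#' symmetrically with a warning. Deterministic given `seed`.
#'
#' @param observed_pairs data.frame with a `distance` column (`NA` =
#'   interchromosomal).
#' @param pool character vector of candidate gene ids.
#' @param genes gene models (coordinates for the pool).
#' @param n_draws number of control sets.
#' @param seed integer seed.
#' @param bin_width log10 bin width.
#' @param pool_factor how many candidate random pairs to pre-sample per
#'   needed pair.
#' @return list of data.frames (`gene_a, gene_b, distance`), one per draw.
#' @export
matched_random_pairs <- function(observed_pairs, pool, genes, n_draws = 1,
                                 seed = 1, bin_width = 0.25, pool_factor = 60) {
  obs_d <- observed_pairs$distance
  n_inter <- sum(is.na(obs_d))
  obs_d <- obs_d[!is.na(obs_d)]
  gi <- match(pool, genes$gene_id)
  if (any(is.na(gi))) stop("pool gene missing from gene models")
  gmid <- midpoint0(genes$start[gi], genes$end[gi])
  gchr <- genes$chrom[gi]
  with_seed(seed, {
    # pre-sample a large candidate set of random pool pairs
    n_cand <- max(1000, pool_factor * (length(obs_d) + n_inter))
    ia <- sample(length(pool), n_cand, replace = TRUE)
    ib <- sample(length(pool), n_cand, replace = TRUE)
    keep <- ia != ib
    ia <- ia[keep]; ib <- ib[keep]
    same <- gchr[ia] == gchr[ib]
    cand_intra <- data.frame(gene_a = pool[ia[same]], gene_b = pool[ib[same]],
                             distance = abs(gmid[ia[same]] - gmid[ib[same]]),
                             stringsAsFactors = FALSE)
    cand_inter <- data.frame(gene_a = pool[ia[!same]], gene_b = pool[ib[!same]],
                             distance = NA_real_, stringsAsFactors = FALSE)
    cand_intra <- cand_intra[cand_intra$distance > 0, , drop = FALSE]

    breaks_of <- function(d) floor(log10(d) / bin_width)
    obs_bin <- breaks_of(obs_d)
    cand_bin <- breaks_of(cand_intra$distance)
    need <- table(obs_bin)
    draws <- vector("list", n_draws)
    for (dr in seq_len(n_draws)) {
      sel <- integer(0)
      for (bn in names(need)) {
        b <- as.integer(bn); k <- need[[bn]]
        in_bin <- which(cand_bin == b)
        widen <- 0L
        while (length(in_bin) == 0 && widen < 40L) {
          widen <- widen + 1L
          in_bin <- which(cand_bin >= b - widen & cand_bin <= b + widen)
        }
        if (widen > 0L) {
          warning("empty distance bin ", bn, " widened by ", widen, " bin(s)")
        }
        if (length(in_bin) == 0) stop("candidate pool cannot cover distance bin ", bn)
        sel <- c(sel, sample(in_bin, k, replace = length(in_bin) < k))
      }
      out <- cand_intra[sel, , drop = FALSE]
      if (n_inter > 0) {
        if (nrow(cand_inter) == 0) stop("no interchromosomal candidates in pool")
        out <- rbind(out, cand_inter[sample(nrow(cand_inter), n_inter,
                                            replace = nrow(cand_inter) < n_inter), ])
      }
      rownames(out) <- NULL
      draws[[dr]] <- out
    }
    draws
  })
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper over [stats::ks.test()] returning the statistic and p-value;
#' used for phase-span and distance-distribution contrasts.
#'
#' @param sample_a,sample_b numeric samples (each `n >= 2`).
#' @return list with `statistic` and `p_value`.
#' @export
compare_distributions <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("compare_distributions needs at least 2 values per sample")
  }
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
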
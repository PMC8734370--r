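# Peak-to-gene assignment, RG/NG/NEG gene classification, anchor/basal peak
# classification, and tissue expression breadth.

#' Assign peaks to genes by summit position
#'
#' A peak belongs to a gene when its summit falls within the gene body plus a
#' 500 bp extension on the promoter side (strand-aware by default; the
#' direction is configurable since peaks of a pre-initiation-complex factor
#' sit at promoters). When a summit lies in the window of two or more genes
#' the gene with the highest FPKM wins; FPKM ties break to the smaller
#' `gene_id` so the mapping is deterministic.
#'
#' @param peaks peak data.frame (`peak_id, chrom, start, end, summit`).
#' @param genes gene-model data.frame.
#' @param fpkm named numeric vector of per-gene FPKM (mean over the time
#'   course); required for every candidate gene.
#' @param cfg a [circa_config()]; uses `gene_extension` and
#'   `extension_direction`.
#' @return data.frame `peak_id, gene_id` (`NA` for unassigned peaks).
#' @export
assign_peaks_to_genes <- function(peaks, genes, fpkm, cfg = circa_config()) {
  ext <- cfg$gene_extension
  plus <- genes$strand == "+"
  ws <- genes$start; we <- genes$end
  if (cfg$extension_direction %in% c("upstream", "both")) {
    ws <- ifelse(plus, ws - ext, ws)
    we <- ifelse(plus, we, we + ext)
  }
  if (cfg$extension_direction %in% c("downstream", "both")) {
    ws <- ifelse(plus, ws, ws - ext)
    we <- ifelse(plus, we + ext, we)
  }
  ws <- pmax(0, ws)
  gr_genes <- as_granges0(genes$chrom, ws, we)
  gr_summit <- as_granges0(peaks$chrom, peaks$summit, peaks$summit + 1)
  hits <- GenomicRanges::findOverlaps(gr_summit, gr_genes, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  gid <- genes$gene_id[sh]
  if (any(!gid %in% names(fpkm))) {
    stop("fpkm missing for candidate gene(s): ",
         paste(utils::head(setdiff(gid, names(fpkm))), collapse = ", "))
  }
  # highest FPKM wins; ties broken by lexicographically smaller gene_id
  ord <- order(qh, -fpkm[gid], gid)
  keep <- !duplicated(qh[ord])
  assigned <- rep(NA_character_, nrow(peaks))
  assigned[qh[ord][keep]] <- gid[ord][keep]
  data.frame(peak_id = peaks$peak_id, gene_id = assigned, stringsAsFactors = FALSE)
}

#' Classify genes as RG / NG / NEG
#'
#' Non-expressed (NEG) when the summed raw counts over all time points are at
#' or below `expressed_min`; otherwise rhythmically expressed (RG) when the
#' rhythm call is significant, else non-rhythmically expressed (NG). RG rows
#' carry the fitted phase and amplitude.
#'
#' @param counts raw count matrix (genes x 12 samples).
#' @param rhythm_calls data.frame from [detect_rhythms()] on the (normalized)
#'   counts; every call must correspond to a row of `counts`.
#' @param cfg a [circa_config()].
#' @return data.frame `gene_id, expression_class, phase_h, amplitude,
#'   mean_expr`.
#' @export
classify_gene_expression <- function(counts, rhythm_calls, cfg = circa_config()) {
  if (any(!rhythm_calls$feature_id %in% rownames(counts))) {
    stop("rhythm call for gene absent from counts: ",
         setdiff(rhythm_calls$feature_id, rownames(counts))[1])
  }
  total <- rowSums(counts)
  idx <- match(rownames(counts), rhythm_calls$feature_id)
  rhythmic <- !is.na(idx) & rhythm_calls$is_rhythmic[ifelse(is.na(idx), 1L, idx)]
  cls <- ifelse(total <= cfg$expressed_min, "NEG", ifelse(rhythmic, "RG", "NG"))
  data.frame(
    gene_id = rownames(counts),
    expression_class = cls,
    phase_h = ifelse(cls == "RG", rhythm_calls$phase_h[idx], NA_real_),
    amplitude = ifelse(cls == "RG", rhythm_calls$amplitude[idx], NA_real_),
    mean_expr = rowMeans(counts),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify peaks as loop anchors or basal promoters
#'
#' Each peak is widened by `anchor_extension_frac` of its width on each side
#' and called an anchor if the widened interval overlaps (>= 1 bp) any loop
#' anchor of the given time point's loop set; otherwise it is a basal
#' promoter peak without chromatin interactions. Classification is per time
#' point: the same peak may be an anchor at 08:00 and basal at 20:00.
#'
#' @param peaks peak data.frame.
#' @param loops filtered loop data.frame for one time point.
#' @param cfg a [circa_config()].
#' @return data.frame `peak_id, site_class` with `site_class` in
#'   `{"anchor", "basal"}`.
#' @export
classify_peak_sites <- function(peaks, loops, cfg = circa_config()) {
  ext <- round(cfg$anchor_extension_frac * (peaks$end - peaks$start))
  gr_peaks <- as_granges0(peaks$chrom, pmax(0, peaks$start - ext), peaks$end + ext)
  gr_anch <- c(as_granges0(loops$chrom_a, loops$start_a, loops$end_a),
               as_granges0(loops$chrom_b, loops$start_b, loops$end_b))
  hit <- GenomicRanges::countOverlaps(gr_peaks, gr_anch, ignore.strand = TRUE) > 0
  data.frame(peak_id = peaks$peak_id,
             site_class = ifelse(hit, "anchor", "basal"),
             stringsAsFactors = FALSE)
}

#' Expression breadth across a tissue panel
#'
#' Number of tissues in which a gene exceeds the FPKM threshold (strictly
#' greater than `breadth_fpkm_min`).
#'
#' @param tissue_fpkm FPKM matrix, tissues x genes.
#' @param cfg a [circa_config()].
#' @return named integer vector, one count per gene.
#' @export
expression_breadth <- function(tissue_fpkm, cfg = circa_config()) {
  colSums(tissue_fpkm > cfg$breadth_fpkm_min)
}
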
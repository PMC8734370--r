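# Binned contact matrices with iterative correction, and strand-aware
# TSS-centered aggregate interaction profiles in gene-rank space.

#' Bin loop contacts into per-chromosome matrices
#'
#' Each intrachromosomal contact increments the `(bin_a, bin_b)` and
#' `(bin_b, bin_a)` cells by its PET count (a same-bin contact increments the
#' diagonal cell once), so every matrix is symmetric by construction. Bins
#' are taken at anchor midpoints.
#'
#' @param loops loop data.frame.
#' @param resolution bin size in bp (e.g. 100000, 50000, 10000).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return named list of `contact_matrix` objects (fields `chrom,
#'   resolution, counts, normalized`), one per chromosome in `chrom_sizes`.
#' @export
bin_contacts <- function(loops, resolution, chrom_sizes) {
  stopifnot(resolution > 0, length(chrom_sizes) > 0, !is.null(names(chrom_sizes)))
  intra <- loops[loops$chrom_a == loops$chrom_b, , drop = FALSE]
  unknown <- setdiff(unique(c(loops$chrom_a, loops$chrom_b)), names(chrom_sizes))
  if (length(unknown)) stop("loop on undeclared chromosome: ", unknown[1])
  out <- lapply(names(chrom_sizes), function(ch) {
    nb <- ceiling(chrom_sizes[[ch]] / resolution)
    m <- matrix(0, nb, nb)
    sel <- intra[intra$chrom_a == ch, , drop = FALSE]
    if (nrow(sel)) {
      ma <- midpoint0(sel$start_a, sel$end_a)
      mb <- midpoint0(sel$start_b, sel$end_b)
      if (any(ma >= chrom_sizes[[ch]] | mb >= chrom_sizes[[ch]])) {
        stop("contact beyond declared length of ", ch)
      }
      ba <- floor(ma / resolution) + 1
      bb <- floor(mb / resolution) + 1
      for (k in seq_len(nrow(sel))) {
        m[ba[k], bb[k]] <- m[ba[k], bb[k]] + sel$pet_count[k]
        if (ba[k] != bb[k]) m[bb[k], ba[k]] <- m[bb[k], ba[k]] + sel$pet_count[k]
      }
    }
    structure(list(chrom = ch, resolution = resolution, counts = m,
                   normalized = FALSE), class = "contact_matrix")
  })
  stats::setNames(out, names(chrom_sizes))
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Matrix balancing: rows and columns are repeatedly divided by their
#' marginal relative to the mean marginal until the maximum relative
#' marginal deviation among non-empty rows falls below `tol` (or `max_iter`
#' is reached). All-zero rows are left untouched; symmetry and the zero
#' pattern are preserved, and the procedure is idempotent at its fixed
#' point.
#'
#' @param cm a `contact_matrix` (or plain symmetric matrix).
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on relative marginal deviation.
#' @return the balanced `contact_matrix` (or matrix) with `normalized = TRUE`.
#' @export
ice_normalize <- function(cm, max_iter = 100, tol = 1e-5) {
  is_cm <- inherits(cm, "contact_matrix")
  m <- if (is_cm) cm$counts else cm
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("ice_normalize requires a symmetric matrix")
  nz <- rowSums(m) > 0
  if (any(nz)) {
    for (it in seq_len(max_iter)) {
      marg <- rowSums(m)
      mm <- mean(marg[nz])
      if (max(abs(marg[nz] / mm - 1)) < tol) break
      s <- marg / mm
      s[!nz] <- 1
      m <- m / outer(s, s)
    }
  }
  if (is_cm) {
    cm$counts <- m
    cm$normalized <- TRUE
    cm
  } else m
}

#' TSS-centered aggregate interaction profile in gene-rank space
#'
#' For each node gene, the window of `flank` genes upstream and downstream in
#' genomic order (101 positions for `flank = 50`) is centered at the node;
#' every interacting gene pair with both members in the window contributes
#' its weight at the pair's offset cell. Windows of minus-strand nodes are
#' flipped so that positive offsets are always downstream of the node's TSS.
#' Cells truncated at chromosome ends contribute to the per-cell sample
#' count only where defined; the returned profile is the element-wise mean.
#'
#' @param pairs gene-pair data.frame (`gene_a, gene_b`, optional `pet_count`).
#' @param genes gene models (order within a chromosome by start coordinate,
#'   ties broken by gene id).
#' @param node_genes character vector of node gene ids; absentees are
#'   skipped with a warning.
#' @param flank window half-width in genes (default 50).
#' @param binary count each interacting pair as 1 instead of its PET weight.
#' @return list with `profile` (mean matrix, `2*flank+1` square), `sums`,
#'   `n` (per-cell sample counts), and `offsets`.
#' @export
tss_centered_profile <- function(pairs, genes, node_genes, flank = 50,
                                 binary = FALSE) {
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  g <- genes[ord, ]
  rank_in_chrom <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along)
  n_in_chrom <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = length)
  info <- data.frame(gene_id = g$gene_id, chrom = g$chrom, rank = rank_in_chrom,
                     n_chrom = n_in_chrom, strand = g$strand,
                     stringsAsFactors = FALSE)
  rownames(info) <- info$gene_id

  K <- flank
  W <- 2 * K + 1
  sums <- matrix(0, W, W)
  nmat <- matrix(0, W, W)
  wt <- if (binary || !"pet_count" %in% names(pairs)) rep(1, nrow(pairs)) else pairs$pet_count

  missing <- setdiff(node_genes, info$gene_id)
  if (length(missing)) {
    warning("node gene(s) absent from annotation skipped: ",
            paste(utils::head(missing), collapse = ", "))
    node_genes <- setdiff(node_genes, missing)
  }
  offs <- seq(-K, K)
  for (nd in node_genes) {
    ni <- info[nd, ]
    flip <- ni$strand == "-"
    # genomic offsets that exist on this chromosome, in node-oriented units
    genomic <- if (flip) -offs else offs
    defined <- ni$rank + genomic >= 1 & ni$rank + genomic <= ni$n_chrom
    nmat <- nmat + outer(defined, defined)
    same <- pairs$gene_a %in% info$gene_id & pairs$gene_b %in% info$gene_id
    if (!any(same)) next
    pa <- info[pairs$gene_a[same], ]; pb <- info[pairs$gene_b[same], ]
    w <- wt[same]
    on_chr <- pa$chrom == ni$chrom & pb$chrom == ni$chrom
    da <- pa$rank - ni$rank; db <- pb$rank - ni$rank
    if (flip) { da <- -da; db <- -db }
    inwin <- on_chr & abs(da) <= K & abs(db) <= K
    for (k in which(inwin)) {
      i <- da[k] + K + 1; j <- db[k] + K + 1
      sums[i, j] <- sums[i, j] + w[k]
      if (i != j) sums[j, i] <- sums[j, i] + w[k]
    }
  }
  profile <- ifelse(nmat > 0, sums / nmat, NA_real_)
  list(profile = profile, sums = sums, n = nmat, offsets = offs)
}
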
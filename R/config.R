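#' Analysis run configuration
#'
#' Collects every tunable threshold used across the pipeline. Defaults are the
#' study's published operating points: rhythm calls at BH `q < 0.05` within a
#' 20--28 h period window; loops retained at `FDR < 0.05`, `PET >= 5`, and an
#' intrachromosomal span above 8 kb; loop anchors taken as peaks extended by
#' 10% on each side; CSC node genes at degree >= 3 with an AM:PM (or PM:AM)
#' degree ratio > 3 separating time-specific from static clusters; core
#' network nodes at degree >= 32; peak-to-gene assignment within the gene body
#' plus a 500 bp promoter-side extension; expression breadth at FPKM > 1; and
#' 1000 permutations for empirical enrichment p-values.
#'
#' @param q_threshold BH q-value below which a feature is called rhythmic.
#' @param period_min,period_max period window bounds in hours.
#' @param period_step grid step (hours) for period selection.
#' @param min_pet minimum PET count for a retained loop.
#' @param fdr_max maximum loop FDR.
#' @param min_intra_span minimum anchor-midpoint distance (bp) for an
#'   intrachromosomal loop; shorter products are treated as self-ligation.
#' @param node_min_degree minimum distinct-partner degree for a CSC node gene.
#' @param core_min_degree degree threshold for core network nodes.
#' @param csc_ratio degree fold-change above which a CSC is time-specific.
#' @param n_perm number of permutations for empirical p-values.
#' @param seed default seed for stochastic stages.
#' @param gene_extension promoter-side extension (bp) for peak assignment.
#' @param extension_direction which side of the gene the extension is applied
#'   to: `"upstream"` (default, strand-aware promoter side), `"downstream"`,
#'   or `"both"`.
#' @param anchor_extension_frac fractional widening of peaks when testing
#'   overlap with loop anchors (0.10 = +-10%).
#' @param breadth_fpkm_min FPKM above which a gene counts as expressed in a
#'   tissue for expression breadth.
#' @param expressed_min summed raw counts over the 12 samples above which a
#'   gene is considered expressed (the study's threshold is unpublished; 10 is
#'   the configurable default here).
#' @param phase_halfwidth half-width (hours) of the phase window used by the
#'   CSC enrichment target set.
#' @param amplitude_quantile quantile of rhythmic-gene amplitudes above which
#'   a gene counts as "high amplitude" for the enrichment target set.
#' @return A list of class `circa_config`.
#' @examples
#' cfg <- circa_config()
#' cfg$min_pet
#' @export
circa_config <- function(q_threshold = 0.05,
                         period_min = 20, period_max = 28, period_step = 0.5,
                         min_pet = 5, fdr_max = 0.05, min_intra_span = 8000,
                         node_min_degree = 3, core_min_degree = 32, csc_ratio = 3,
                         n_perm = 1000, seed = 1,
                         gene_extension = 500,
                         extension_direction = c("upstream", "downstream", "both"),
                         anchor_extension_frac = 0.10,
                         breadth_fpkm_min = 1.0,
                         expressed_min = 10,
                         phase_halfwidth = 2,
                         amplitude_quantile = 0.5) {
  extension_direction <- match.arg(extension_direction)
  cfg <- list(
    q_threshold = q_threshold, period_min = period_min, period_max = period_max,
    period_step = period_step, min_pet = min_pet, fdr_max = fdr_max,
    min_intra_span = min_intra_span, node_min_degree = node_min_degree,
    core_min_degree = core_min_degree, csc_ratio = csc_ratio, n_perm = n_perm,
    seed = as.integer(seed), gene_extension = gene_extension,
    extension_direction = extension_direction,
    anchor_extension_frac = anchor_extension_frac,
    breadth_fpkm_min = breadth_fpkm_min, expressed_min = expressed_min,
    phase_halfwidth = phase_halfwidth, amplitude_quantile = amplitude_quantile
  )
  num <- cfg[setdiff(names(cfg), c("extension_direction", "seed"))]
  if (any(!vapply(num, is.numeric, logical(1))) || any(unlist(num) < 0)) {
    stop("all circa_config thresholds must be non-negative numbers")
  }
  stopifnot(cfg$period_min < cfg$period_max, cfg$q_threshold > 0, cfg$min_pet >= 1)
  class(cfg) <- "circa_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @param cfg a `circa_config` object.
#' @return `read_config` returns a `circa_config`; `write_config` returns the
#'   path invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(circa_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "circa_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.circa_config <- function(x, ...) {
  cat("circaloop run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
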
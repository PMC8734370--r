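# Chromatin spatial clusters: star-shaped node-gene neighborhoods, AM/PM/
# static classification by degree ratio, composition, and permutation-based
# phase enrichment.

#' Build chromatin spatial clusters from per-time gene pairs
#'
#' A CSC is a node gene together with its distinct loop-partner (linked)
#' genes at each time point. One CSC is emitted for every gene whose maximum
#' degree over the two time points reaches `node_min_degree`; linked sets are
#' recorded for both times (possibly empty). Stars may overlap: a gene can be
#' a node of its own CSC and a linked gene of another.
#'
#' @param pairs_am,pairs_pm gene-pair data.frames from
#'   [loops_to_gene_pairs()] for the AM (t08) and PM (t20) loop sets.
#' @param cfg a [circa_config()].
#' @return data.frame with `node_gene, degree_am, degree_pm` and list-columns
#'   `linked_am`, `linked_pm`.
#' @export
build_cscs <- function(pairs_am, pairs_pm, cfg = circa_config()) {
  partners <- function(pairs) {
    if (nrow(pairs) == 0) return(list())
    both <- rbind(data.frame(node = pairs$gene_a, partner = pairs$gene_b,
                             stringsAsFactors = FALSE),
                  data.frame(node = pairs$gene_b, partner = pairs$gene_a,
                             stringsAsFactors = FALSE))
    lapply(split(both$partner, both$node), unique)
  }
  am <- partners(pairs_am)
  pm <- partners(pairs_pm)
  all_nodes <- union(names(am), names(pm))
  deg_am <- vapply(all_nodes, function(g) length(am[[g]] %||% character(0)), integer(1))
  deg_pm <- vapply(all_nodes, function(g) length(pm[[g]] %||% character(0)), integer(1))
  keep <- pmax(deg_am, deg_pm) >= cfg$node_min_degree
  out <- data.frame(node_gene = all_nodes[keep],
                    degree_am = unname(deg_am[keep]), degree_pm = unname(deg_pm[keep]),
                    stringsAsFactors = FALSE)
  out$linked_am <- lapply(out$node_gene, function(g) am[[g]] %||% character(0))
  out$linked_pm <- lapply(out$node_gene, function(g) pm[[g]] %||% character(0))
  rownames(out) <- NULL
  out
}

#' Classify CSCs as AM-specific, PM-specific, or static
#'
#' A node present only in the AM loop set (PM degree 0) is AM-specific, and
#' symmetrically for PM. Nodes present at both times are AM-specific when the
#' AM:PM degree ratio exceeds `csc_ratio`, PM-specific when PM:AM exceeds it,
#' and static otherwise (degree fold-change at or below the threshold).
#'
#' @param cscs data.frame from [build_cscs()].
#' @param cfg a [circa_config()].
#' @return `cscs` with a `csc_class` column; idempotent.
#' @export
classify_cscs <- function(cscs, cfg = circa_config()) {
  a <- cscs$degree_am; p <- cscs$degree_pm
  cscs$csc_class <- ifelse(p == 0, "AM-specific",
                    ifelse(a == 0, "PM-specific",
                    ifelse(a / p > cfg$csc_ratio, "AM-specific",
                    ifelse(p / a > cfg$csc_ratio, "PM-specific", "static"))))
  cscs
}

#' Expression-class composition of CSCs
#'
#' Per CSC and time point: counts and fractions of RG/NG/NEG among the linked
#' genes, the rhythmic:non-rhythmic linked ratio, and the node gene's own
#' class. CSCs with an empty linked set at a time point get `NA` fractions
#' and are flagged.
#'
#' @param cscs classified CSC data.frame.
#' @param labels gene labels from [classify_gene_expression()].
#' @return long data.frame, one row per CSC x time point.
#' @export
csc_composition <- function(cscs, labels) {
  cls <- stats::setNames(labels$expression_class, labels$gene_id)
  one <- function(node, linked, time_label, csc_class) {
    if (any(!linked %in% names(cls))) {
      stop("linked gene missing a label: ", setdiff(linked, names(cls))[1])
    }
    if (!node %in% names(cls)) stop("node gene missing a label: ", node)
    n <- length(linked)
    k <- c(RG = sum(cls[linked] == "RG"), NG = sum(cls[linked] == "NG"),
           NEG = sum(cls[linked] == "NEG"))
    data.frame(node_gene = node, time_label = time_label, csc_class = csc_class,
               node_class = unname(cls[node]), n_linked = n,
               n_rg = unname(k["RG"]), n_ng = unname(k["NG"]), n_neg = unname(k["NEG"]),
               frac_rg = if (n) unname(k["RG"]) / n else NA_real_,
               frac_ng = if (n) unname(k["NG"]) / n else NA_real_,
               frac_neg = if (n) unname(k["NEG"]) / n else NA_real_,
               rg_ng_ratio = if (k["NG"] > 0) unname(k["RG"] / k["NG"]) else NA_real_,
               empty = n == 0, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(cscs)), function(i) {
    rbind(one(cscs$node_gene[i], cscs$linked_am[[i]], "t08", cscs$csc_class[i]),
          one(cscs$node_gene[i], cscs$linked_pm[[i]], "t20", cscs$csc_class[i]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linked-gene overlap of static CSCs between time points
#'
#' For each static CSC with both linked sets non-empty: the common fraction
#' is `|AM intersect PM| / |AM union PM|`; AM- and PM-specific fractions are
#' the complementary shares of the union.
#'
#' @param cscs classified CSC data.frame.
#' @return data.frame `node_gene, n_common, n_union, frac_common,
#'   frac_am_specific, frac_pm_specific`.
#' @export
static_linked_overlap <- function(cscs) {
  st <- cscs[cscs$csc_class == "static", , drop = FALSE]
  rows <- lapply(seq_len(nrow(st)), function(i) {
    a <- st$linked_am[[i]]; p <- st$linked_pm[[i]]
    if (length(a) == 0 || length(p) == 0) return(NULL)
    u <- union(a, p); cm <- intersect(a, p)
    data.frame(node_gene = st$node_gene[i], n_common = length(cm),
               n_union = length(u), frac_common = length(cm) / length(u),
               frac_am_specific = length(setdiff(a, p)) / length(u),
               frac_pm_specific = length(setdiff(p, a)) / length(u),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(node_gene = character(0), n_common = integer(0),
                      n_union = integer(0), frac_common = numeric(0),
                      frac_am_specific = numeric(0), frac_pm_specific = numeric(0))
  }
  rownames(out) <- NULL
  out
}

# Member gene set of one CSC at a time point (node plus linked by default).
csc_members <- function(cscs, time_label, include_node = TRUE) {
  linked <- if (time_label == "t08") cscs$linked_am else cscs$linked_pm
  lapply(seq_len(nrow(cscs)), function(i) {
    if (include_node) unique(c(cscs$node_gene[i], linked[[i]])) else linked[[i]]
  })
}

#' Permutation test for phase enrichment in CSCs
#'
#' The target set is the rhythmic genes whose amplitude is above the
#' configured quantile of rhythmic amplitudes and whose phase lies within
#' `phase_halfwidth` hours (circular) of `phase_center`. The observed
#' statistic is the mean number of target genes per CSC (node plus linked
#' genes by default). The null redraws `|target|` genes uniformly from
#' `pool` and recomputes the mean, `n_perm` times; the empirical p-value uses
#' the add-one estimator `(1 + #(null >= observed)) / (n_perm + 1)` so it is
#' never zero. Deterministic given `seed`.
#'
#' @param cscs classified CSC data.frame (typically one class).
#' @param labels gene labels with `phase_h` and `amplitude` for RG genes.
#' @param phase_center target phase center (hours).
#' @param pool character vector of genes the null draws from.
#' @param cfg a [circa_config()]; uses `phase_halfwidth`,
#'   `amplitude_quantile`, `n_perm`.
#' @param time_label which linked sets to use (`"t08"` or `"t20"`).
#' @param include_node count the node gene as a member (default `TRUE`).
#' @param seed integer seed.
#' @return list with `observed`, `null` (numeric vector of length `n_perm`),
#'   `p_value`, `n_target`, `target`.
#' @export
phase_enrichment_test <- function(cscs, labels, phase_center, pool,
                                  cfg = circa_config(), time_label = "t08",
                                  include_node = TRUE, seed = cfg$seed) {
  if (cfg$n_perm < 100) stop("n_perm must be at least 100")
  rg <- labels[labels$expression_class == "RG" & !is.na(labels$phase_h), ]
  amp_min <- stats::quantile(rg$amplitude, cfg$amplitude_quantile, names = FALSE)
  target <- rg$gene_id[rg$amplitude >= amp_min &
                         circular_phase_diff(rg$phase_h, phase_center) <= cfg$phase_halfwidth]
  if (length(pool) < length(target)) stop("pool smaller than target set")
  members <- csc_members(cscs, time_label, include_node)
  observed <- mean(vapply(members, function(m) sum(m %in% target), numeric(1)))
  # CSC x pool membership indicator; null means are one matrix product away
  M <- vapply(members, function(m) pool %in% m, logical(length(pool)))
  M <- matrix(as.numeric(M), nrow = length(pool))
  null <- with_seed(seed, {
    vapply(seq_len(cfg$n_perm), function(r) {
      z <- numeric(length(pool))
      z[sample(length(pool), length(target))] <- 1
      mean(crossprod(M, z))
    }, numeric(1))
  })
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (cfg$n_perm + 1),
       n_target = length(target), target = target)
}
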
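# Gene-level interaction graphs: construction, hop expansion from seed clock
# genes, core nodes, AM/PM network differencing, and import/export.

#' Build a gene interaction graph from gene pairs
#'
#' One vertex per gene, one undirected edge per unordered pair (duplicates
#' collapse with summed PET support). Vertex attributes: expression class,
#' expression breadth, gene length, and degree (distinct neighbors).
#'
#' @param pairs gene-pair data.frame (`gene_a, gene_b`, optional
#'   `pet_count`, `time_label`).
#' @param labels optional gene labels (adds `expression_class`).
#' @param breadth optional named breadth vector from [expression_breadth()].
#' @param genes optional gene models (adds `gene_length`).
#' @return an [igraph::igraph] object.
#' @export
build_graph <- function(pairs, labels = NULL, breadth = NULL, genes = NULL) {
  key <- ifelse(pairs$gene_a <= pairs$gene_b,
                paste(pairs$gene_a, pairs$gene_b, sep = "\r"),
                paste(pairs$gene_b, pairs$gene_a, sep = "\r"))
  pet <- if ("pet_count" %in% names(pairs)) pairs$pet_count else rep(1L, nrow(pairs))
  agg <- tapply(pet, key, sum)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  ed <- data.frame(from = parts[, 1], to = parts[, 2],
                   pet_count = as.integer(agg), stringsAsFactors = FALSE)
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  if (!is.null(labels)) {
    igraph::V(g)$expression_class <-
      labels$expression_class[match(igraph::V(g)$name, labels$gene_id)]
  }
  if (!is.null(breadth)) {
    igraph::V(g)$breadth <- unname(breadth[igraph::V(g)$name])
  }
  if (!is.null(genes)) {
    gi <- match(igraph::V(g)$name, genes$gene_id)
    igraph::V(g)$gene_length <- genes$end[gi] - genes$start[gi]
  }
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Expand a neighborhood one or two hops from seed genes
#'
#' Breadth-first expansion: the result contains every vertex within graph
#' distance `hops` of any seed, with all induced edges among the included
#' vertices (cross-links between neighbors are kept, not only tree edges).
#' Seeds absent from the graph are skipped with a warning; if no seed is
#' present the expansion fails.
#'
#' @param graph an igraph object with vertex names.
#' @param seeds character vector of seed gene ids.
#' @param hops 1 or 2.
#' @return the induced subgraph.
#' @export
hop_expand <- function(graph, seeds, hops) {
  stopifnot(length(hops) == 1, hops %in% c(1, 2))
  vn <- igraph::V(graph)$name
  present <- seeds %in% vn
  if (!any(present)) stop("no seed present in the graph")
  if (any(!present)) {
    warning("seed(s) absent from graph skipped: ",
            paste(seeds[!present], collapse = ", "))
  }
  # hand-rolled BFS so the expansion can be cross-checked against
  # shortest-path distances in tests
  frontier <- unique(seeds[present])
  reached <- frontier
  for (h in seq_len(hops)) {
    if (length(frontier) == 0) break
    nb <- unique(unlist(lapply(
      igraph::adjacent_vertices(graph, frontier),
      function(v) vn[as.integer(v)]
    ), use.names = FALSE))
    frontier <- setdiff(nb, reached)
    reached <- c(reached, frontier)
  }
  igraph::induced_subgraph(graph, reached)
}

#' Core nodes of an interaction graph
#'
#' Genes whose degree (distinct neighbors) reaches `core_min_degree`.
#'
#' @param graph an igraph object.
#' @param cfg a [circa_config()].
#' @return character vector of gene ids.
#' @export
core_nodes <- function(graph, cfg = circa_config()) {
  d <- igraph::degree(graph)
  names(d)[d >= cfg$core_min_degree]
}

edge_keys <- function(graph) {
  if (igraph::ecount(graph) == 0) return(character(0))
  el <- igraph::as_edgelist(graph)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
}

#' Difference two connectivity networks
#'
#' Set differences on vertex ids and unordered edges between the AM and PM
#' graphs, plus a degree-comparison table for the common nodes.
#'
#' @param graph_am,graph_pm igraph objects over the same gene universe.
#' @return list with `common_nodes`, `am_specific_nodes`, `pm_specific_nodes`,
#'   `common_edges`, `am_specific_edges`, `pm_specific_edges` (two-column
#'   data.frames), and `degree_table` for common nodes.
#' @export
diff_networks <- function(graph_am, graph_pm) {
  na <- igraph::V(graph_am)$name; np <- igraph::V(graph_pm)$name
  ea <- edge_keys(graph_am); ep <- edge_keys(graph_pm)
  unkey <- function(k) {
    if (length(k) == 0) return(data.frame(gene_a = character(0), gene_b = character(0)))
    parts <- do.call(rbind, strsplit(k, "\r", fixed = TRUE))
    data.frame(gene_a = parts[, 1], gene_b = parts[, 2], stringsAsFactors = FALSE)
  }
  common <- intersect(na, np)
  list(common_nodes = common,
       am_specific_nodes = setdiff(na, np),
       pm_specific_nodes = setdiff(np, na),
       common_edges = unkey(intersect(ea, ep)),
       am_specific_edges = unkey(setdiff(ea, ep)),
       pm_specific_edges = unkey(setdiff(ep, ea)),
       degree_table = data.frame(
         gene_id = common,
         degree_am = igraph::degree(graph_am, common),
         degree_pm = igraph::degree(graph_pm, common),
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Export / import an interaction graph
#'
#' `"edgelist"` writes a TSV of edges with attribute columns plus a
#' companion `<path>.nodes.tsv` with vertex attributes, which
#' [import_graph()] reads back into an attribute-identical graph.
#' `"graphml"` delegates to [igraph::write_graph()].
#'
#' @param graph an igraph object.
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  ed <- igraph::as_data_frame(graph, what = "edges")
  vt <- igraph::as_data_frame(graph, what = "vertices")
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(vt, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  ed <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  vt <- utils::read.table(paste0(path, ".nodes.tsv"), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vt)
}

#' Distinct partner regions of a query region
#'
#' Collects the opposite anchors of every loop touching the query region and
#' merges overlapping anchors into distinct genomic regions — the one-hop
#' partner-region count of a locus in the interaction table (e.g. a clock
#' gene's looping regions at one time point).
#'
#' @param loops loop data.frame.
#' @param chrom,start,end query region (0-based half-open).
#' @return a [GenomicRanges::GRanges] of merged partner regions.
#' @export
partner_regions <- function(loops, chrom, start, end) {
  q <- as_granges0(chrom, start, end)
  ga <- as_granges0(loops$chrom_a, loops$start_a, loops$end_a)
  gb <- as_granges0(loops$chrom_b, loops$start_b, loops$end_b)
  hit_a <- GenomicRanges::countOverlaps(ga, q, ignore.strand = TRUE) > 0
  hit_b <- GenomicRanges::countOverlaps(gb, q, ignore.strand = TRUE) > 0
  partners <- c(gb[hit_a], ga[hit_b & !hit_a])
  GenomicRanges::reduce(partners)
}
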
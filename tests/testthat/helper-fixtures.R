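# Small fixtures built in code, shared across test files.

# A hand-laid four-gene annotation on two chromosomes.
tiny_genes <- function() {
  data.frame(
    gene_id = c("geneA", "geneB", "geneC", "geneD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000, 5000, 20000, 2000),
    end = c(3000, 7000, 22000, 4000),
    strand = c("+", "-", "+", "+"),
    stringsAsFactors = FALSE
  )
}

# The canonical 12 sample labels (two days x six clock times).
all_time_labels <- function() {
  paste0("d", rep(1:2, each = 6), "_t", sprintf("%02d", rep(c(0, 4, 8, 12, 16, 20), 2)))
}

# Deterministic cosine time course at the canonical 12 samples.
cosine_trace <- function(mesor, amplitude, phase, period = 24) {
  t <- circaloop::times_from_labels(all_time_labels())
  mesor + amplitude * cos(2 * pi * (t - phase) / period)
}

# One loop row in internal format.
make_loop <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b,
                      pet = 10, fdr = 0.01, time_label = "t08") {
  data.frame(chrom_a = chrom_a, start_a = start_a, end_a = end_a,
             chrom_b = chrom_b, start_b = start_b, end_b = end_b,
             pet_count = pet, fdr = fdr, time_label = time_label,
             stringsAsFactors = FALSE)
}

# Gene labels for constructed pair/CSC tests.
make_labels <- function(ids, classes, phases = NULL, amplitudes = NULL) {
  data.frame(gene_id = ids, expression_class = classes,
             phase_h = phases %||% rep(NA_real_, length(ids)),
             amplitude = amplitudes %||% rep(NA_real_, length(ids)),
             mean_expr = 100, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small default-structure simulated dataset reused by slower tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- circaloop::sim_config(
        n_genes = 400, n_loops_per_time = 600,
        csc_design = list(n_am = 10, n_pm = 10, n_static = 10,
                          degree_min = 3, degree_max = 6))
      cache <<- circaloop::simulate_dataset(cfg, seed = 42)
    }
    cache
  }
})
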
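# Readers and writers for the on-disk formats. All genomic intervals are
# 0-based half-open internally (BED convention); 1-based inputs (GFF3, and
# optionally loop tables) are converted at this boundary only.

read_lines_nonempty <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path)
  keep <- !grepl("^\\s*$", x) & !startsWith(x, "#") & !startsWith(x, "track") &
    !startsWith(x, "browser")
  list(lines = x[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "[\t ]+")

num_or_stop <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    stop(sprintf("malformed %s at line %d: '%s'", what, lineno[which(is.na(v))[1]],
                 x[which(is.na(v))[1]]))
  }
  v
}

#' Read gene models from BED or GFF3
#'
#' Accepts BED6/BED12 (already 0-based half-open) or a GFF3 subset (records
#' with type `gene`; 1-based closed coordinates, converted on read). The
#' `gene_id` comes from BED column 4 or the GFF3 `ID=` attribute and must be
#' unique.
#'
#' @param path file path; format inferred from the extension (`.gff`,
#'   `.gff3` vs anything else = BED) unless `format` is given.
#' @param format `"auto"`, `"bed"`, or `"gff3"`.
#' @return data.frame with columns `gene_id, chrom, start, end, strand`
#'   (0-based half-open).
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  lf <- read_lines_nonempty(path)
  fields <- split_fields(lf$lines)
  if (format == "bed") {
    n <- vapply(fields, length, integer(1))
    if (any(n < 6)) {
      stop("malformed BED line ", lf$lineno[which(n < 6)[1]], ": fewer than 6 columns")
    }
    genes <- data.frame(
      gene_id = vapply(fields, `[`, "", 4),
      chrom = vapply(fields, `[`, "", 1),
      start = num_or_stop(vapply(fields, `[`, "", 2), "BED start", lf$lineno),
      end = num_or_stop(vapply(fields, `[`, "", 3), "BED end", lf$lineno),
      strand = vapply(fields, `[`, "", 6),
      stringsAsFactors = FALSE
    )
  } else {
    n <- vapply(fields, length, integer(1))
    if (any(n < 9)) {
      stop("malformed GFF3 line ", lf$lineno[which(n < 9)[1]], ": fewer than 9 columns")
    }
    type <- vapply(fields, `[`, "", 3)
    keep <- type == "gene"
    fields <- fields[keep]; lineno <- lf$lineno[keep]
    attrs <- vapply(fields, function(f) paste(f[9:length(f)], collapse = " "), "")
    ids <- sub(".*ID=([^;]+).*", "\\1", attrs)
    if (any(!grepl("ID=", attrs))) {
      stop("GFF3 gene record without ID attribute at line ", lineno[which(!grepl("ID=", attrs))[1]])
    }
    genes <- data.frame(
      gene_id = ids,
      chrom = vapply(fields, `[`, "", 1),
      start = num_or_stop(vapply(fields, `[`, "", 4), "GFF3 start", lineno) - 1,
      end = num_or_stop(vapply(fields, `[`, "", 5), "GFF3 end", lineno),
      strand = vapply(fields, `[`, "", 7),
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  }
  if (any(genes$start >= genes$end)) stop("gene with start >= end: ",
                                          genes$gene_id[genes$start >= genes$end][1])
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for gene ", genes$gene_id[!genes$strand %in% c("+", "-")][1])
  }
  rownames(genes) <- NULL
  genes
}

#' Write gene models as BED6
#' @param genes gene-model data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  out <- data.frame(genes$chrom, as.integer(genes$start), as.integer(genes$end),
                    genes$gene_id, 0L, genes$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a MACS2 narrowPeak file
#'
#' Ten columns; column 7 is the signal value and column 10 the summit offset
#' from `start` (`-1` meaning "no summit", resolved to the interval midpoint).
#'
#' @param path narrowPeak file.
#' @param time_label label attached to every peak (e.g. `"t08"`).
#' @return data.frame with `peak_id, chrom, start, end, summit, signal,
#'   time_label` (0-based; `summit` is an absolute position).
#' @export
read_peaks <- function(path, time_label) {
  lf <- read_lines_nonempty(path)
  fields <- split_fields(lf$lines)
  n <- vapply(fields, length, integer(1))
  if (any(n < 10)) {
    stop("malformed narrowPeak line ", lf$lineno[which(n < 10)[1]], ": fewer than 10 columns")
  }
  start <- num_or_stop(vapply(fields, `[`, "", 2), "peak start", lf$lineno)
  end <- num_or_stop(vapply(fields, `[`, "", 3), "peak end", lf$lineno)
  off <- num_or_stop(vapply(fields, `[`, "", 10), "summit offset", lf$lineno)
  if (any(off >= end - start)) {
    stop("summit offset beyond peak width at line ", lf$lineno[which(off >= end - start)[1]])
  }
  summit <- ifelse(off < 0, floor((start + end) / 2), start + off)
  peaks <- data.frame(
    peak_id = vapply(fields, `[`, "", 4),
    chrom = vapply(fields, `[`, "", 1),
    start = start, end = end, summit = summit,
    signal = num_or_stop(vapply(fields, `[`, "", 7), "signalValue", lf$lineno),
    time_label = time_label, stringsAsFactors = FALSE
  )
  if (any(!is.finite(peaks$signal))) stop("non-finite signal value in ", path)
  if (any(peaks$start > peaks$summit | peaks$summit >= peaks$end)) {
    stop("summit outside peak interval in ", path)
  }
  peaks
}

#' Write peaks as narrowPeak
#' @param peaks peak data.frame (`peak_id, chrom, start, end, summit, signal`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                    peaks$peak_id, 0L, ".", peaks$signal, -1, -1,
                    as.integer(peaks$summit - peaks$start))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read loops from BEDPE (+ PET count and FDR columns)
#'
#' Expects at least eight columns: the two anchors (`chrom,start,end` each),
#' then the supporting PET count and the interaction FDR. Anchors are put in
#' canonical order (`(chrom_a, start_a) <= (chrom_b, start_b)`) so overlap and
#' equality tests are order-insensitive.
#'
#' @param path BEDPE file.
#' @param time_label label attached to every loop.
#' @param one_based set `TRUE` if the table uses 1-based closed coordinates
#'   (converted on read); default `FALSE` (BEDPE convention).
#' @return data.frame with columns `chrom_a, start_a, end_a, chrom_b, start_b,
#'   end_b, pet_count, fdr, time_label`.
#' @export
read_loops <- function(path, time_label, one_based = FALSE) {
  lf <- read_lines_nonempty(path)
  fields <- split_fields(lf$lines)
  n <- vapply(fields, length, integer(1))
  if (any(n < 8)) {
    stop("malformed BEDPE line ", lf$lineno[which(n < 8)[1]], ": fewer than 8 columns")
  }
  col <- function(i, what) num_or_stop(vapply(fields, `[`, "", i), what, lf$lineno)
  loops <- data.frame(
    chrom_a = vapply(fields, `[`, "", 1),
    start_a = col(2, "start_a"), end_a = col(3, "end_a"),
    chrom_b = vapply(fields, `[`, "", 4),
    start_b = col(5, "start_b"), end_b = col(6, "end_b"),
    pet_count = as.integer(col(7, "pet_count")),
    fdr = col(8, "fdr"),
    time_label = time_label, stringsAsFactors = FALSE
  )
  if (one_based) {
    loops$start_a <- loops$start_a - 1
    loops$start_b <- loops$start_b - 1
  }
  validate_loops(loops)
  canonical_loops(loops)
}

validate_loops <- function(loops) {
  if (any(loops$start_a < 0 | loops$start_b < 0)) stop("negative loop coordinate")
  if (any(loops$fdr < 0 | loops$fdr > 1)) stop("loop fdr outside [0, 1]")
  if (any(loops$pet_count < 1)) stop("loop pet_count < 1")
  if (any(loops$start_a >= loops$end_a | loops$start_b >= loops$end_b)) {
    stop("loop anchor with start >= end")
  }
  invisible(loops)
}

# Canonical anchor order: (chrom_a, start_a) lexicographically first.
canonical_loops <- function(loops) {
  swap <- loops$chrom_a > loops$chrom_b |
    (loops$chrom_a == loops$chrom_b & loops$start_a > loops$start_b)
  if (any(swap)) {
    tmp <- loops[swap, c("chrom_a", "start_a", "end_a")]
    loops[swap, c("chrom_a", "start_a", "end_a")] <-
      loops[swap, c("chrom_b", "start_b", "end_b")]
    loops[swap, c("chrom_b", "start_b", "end_b")] <- tmp
  }
  rownames(loops) <- NULL
  loops
}

#' Write loops as BEDPE (+ PET count and FDR)
#' @param loops loop data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  out <- data.frame(loops$chrom_a, as.integer(loops$start_a), as.integer(loops$end_a),
                    loops$chrom_b, as.integer(loops$start_b), as.integer(loops$end_b),
                    loops$pet_count, loops$fdr)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a labeled TSV matrix
#'
#' First column = feature ids (must be unique), header row = sample labels.
#' Ragged rows and empty cells are rejected.
#'
#' @param path TSV file.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(unique(nf)) != 1) {
    stop("ragged TSV: line ", which(nf != nf[1])[1], " has ", nf[nf != nf[1]][1],
         " fields, expected ", nf[1])
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate row id: ", ids[duplicated(ids)][1])
  body <- df[, -1, drop = FALSE]
  if (any(body == "" | is.na(body))) stop("missing cell in matrix ", path)
  m <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(body), dimnames = list(NULL, colnames(body)))
  if (any(is.na(m))) stop("non-numeric cell in matrix ", path)
  rownames(m) <- ids
  m
}

#' Write a labeled matrix as TSV
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param id_col name for the id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
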
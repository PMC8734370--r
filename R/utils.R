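# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# The twelve canonical sample labels: two days x six clock times.
time_labels <- function() {
  paste0("d", rep(1:2, each = 6), "_t", sprintf("%02d", rep(c(0, 4, 8, 12, 16, 20), 2)))
}

# Six clock-time labels ("t00".."t20"), used for per-time-point peak files.
clock_labels <- function() {
  sprintf("t%02d", c(0, 4, 8, 12, 16, 20))
}

#' Parse clock times (hours) from sample labels
#'
#' Labels follow the fixed vocabulary `d{1,2}_t{00,04,08,12,16,20}` (or bare
#' `t{HH}`); both replicate days map to the same clock time mod 24.
#'
#' @param labels character vector of sample labels.
#' @return numeric vector of hours in `[0, 24)`.
#' @export
times_from_labels <- function(labels) {
  m <- regmatches(labels, regexpr("t[0-9]{2}$", labels))
  if (length(m) != length(labels)) {
    bad <- labels[!grepl("t[0-9]{2}$", labels)]
    stop("cannot parse clock time from sample label(s): ", paste(bad, collapse = ", "))
  }
  as.numeric(sub("^t", "", m)) %% 24
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); mu in radians.
# No circular-statistics package is relied on: the generator only needs draws.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# 0-based half-open intervals -> IRanges (1-based closed).
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# 0-based half-open intervals -> GRanges.
as_granges0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(seqnames = chrom, ranges = as_iranges0(start, end), strand = strand)
}

# Interval midpoint under the 0-based half-open convention.
midpoint0 <- function(start, end) (start + end) / 2

`%||%` <- function(a, b) if (is.null(a)) b else a
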
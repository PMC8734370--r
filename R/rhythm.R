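# Rhythm detection: row normalization, cosinor harmonic regression over a
# period grid, BH correction, and phase relationships between paired signals.

#' Row-normalize a diurnal matrix (Ei/M - 1)
#'
#' Each value is divided by the row mean over all time points and shifted by
#' -1, so every retained row has mean exactly zero. Rows whose mean is zero
#' (e.g. all-zero genes) cannot be normalized; they are dropped with a warning
#' and recorded in the `"excluded"` attribute.
#'
#' @param m numeric matrix (features x samples).
#' @return normalized matrix; attribute `excluded` holds dropped row ids.
#' @export
normalize_diurnal <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  M <- rowMeans(m)
  bad <- M == 0 | !is.finite(M)
  if (any(bad)) {
    warning(sum(bad), " row(s) with zero mean excluded from normalization")
  }
  out <- m[!bad, , drop = FALSE] / M[!bad] - 1
  attr(out, "excluded") <- rownames(m)[bad]
  out
}

#' Fit a single-component cosinor model
#'
#' Least-squares fit of `y = m + a*cos(2*pi*t/T) + b*sin(2*pi*t/T)`. The
#' amplitude is `sqrt(a^2 + b^2)` and the phase is the clock time of the
#' fitted peak, `(T/2pi) * atan2(b, a) mod T`, mapped into `[0, 24)`. The
#' p-value is an F-test of `(a, b) = (0, 0)` on `(2, n - 3)` degrees of
#' freedom; a constant series gives `F = 0`, `p = 1`.
#'
#' @param values numeric signal vector.
#' @param times sampling times in hours (clock time mod 24 for replicate days).
#' @param period trial period in hours.
#' @return list with `mesor, amplitude, phase_h, p_value, rsq`.
#' @examples
#' t <- rep(c(0, 4, 8, 12, 16, 20), 2)
#' y <- 3 + 2 * cos(2 * pi * (t - 8) / 24)
#' fit_cosinor(y, t, 24)$phase_h
#' @export
fit_cosinor <- function(values, times, period) {
  stopifnot(length(values) == length(times), period > 0)
  keep <- is.finite(values)
  values <- values[keep]; times <- times[keep]
  n <- length(values)
  if (n < 6) stop("fit_cosinor needs at least 6 samples")
  if (length(unique(times)) < 3) stop("singular cosinor design: too few distinct times")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  fit <- stats::lm.fit(X, values)
  co <- fit$coefficients
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((values - mean(values))^2)
  amp <- sqrt(co[2]^2 + co[3]^2)
  phase <- (period / (2 * pi)) * atan2(co[3], co[2]) %% (2 * pi)
  if (rss0 <= 0) {
    return(list(mesor = co[1], amplitude = 0, phase_h = 0, p_value = 1, rsq = 0))
  }
  Fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  p <- if (!is.finite(Fstat)) 0 else stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)
  list(mesor = unname(co[1]), amplitude = unname(amp),
       phase_h = unname(phase %% 24), p_value = p,
       rsq = 1 - rss1 / rss0)
}

#' Call rhythmic features by cosinor regression over a period grid
#'
#' For every row, cosinor models are fitted at each grid period between
#' `period_min` and `period_max` (step `period_step`); the best-R-squared
#' period is retained and its F-test p-value carried forward. Q-values are
#' Benjamini-Hochberg adjusted across rows and a feature is rhythmic when
#' `q < q_threshold`. Both replicate days are fitted jointly at clock time
#' mod 24. Rows with fewer than 6 finite values are skipped with a warning.
#'
#' @param m numeric matrix (features x 12 samples); raw or normalized — the
#'   F statistic is invariant to row location/scale.
#' @param cfg a [circa_config()].
#' @param times sampling hours; parsed from `colnames(m)` when `NULL`.
#' @return data.frame of rhythm calls: `feature_id, p_value, q_value,
#'   period_h, phase_h, amplitude, mesor, is_rhythmic`.
#' @export
detect_rhythms <- function(m, cfg = circa_config(), times = NULL) {
  stopifnot(is.matrix(m))
  if (is.null(times)) times <- times_from_labels(colnames(m))
  stopifnot(length(times) == ncol(m))
  ok <- rowSums(is.finite(m)) >= 6
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with fewer than 6 finite samples skipped")
    m <- m[ok, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no usable rows for rhythm detection")
  periods <- seq(cfg$period_min, cfg$period_max, by = cfg$period_step)
  n <- ncol(m)
  Yt <- t(m)                     # samples x features
  mu <- colMeans(Yt)
  rss0 <- colSums((Yt - rep(mu, each = n))^2)

  best_rss <- rep(Inf, ncol(Yt))
  best_T <- rep(periods[1], ncol(Yt))
  best_a <- best_b <- best_m <- numeric(ncol(Yt))
  for (T in periods) {
    w <- 2 * pi / T
    X <- cbind(1, cos(w * times), sin(w * times))
    B <- solve(crossprod(X), crossprod(X, Yt))   # 3 x features
    rss1 <- colSums((Yt - X %*% B)^2)
    upd <- rss1 < best_rss - 1e-12
    if (any(upd)) {
      best_rss[upd] <- rss1[upd]
      best_T[upd] <- T
      best_m[upd] <- B[1, upd]; best_a[upd] <- B[2, upd]; best_b[upd] <- B[3, upd]
    }
  }
  const <- rss0 <= 0
  Fstat <- ((rss0 - best_rss) / 2) / (pmax(best_rss, .Machine$double.xmin) / (n - 3))
  p <- stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)
  p[const] <- 1
  amp <- sqrt(best_a^2 + best_b^2); amp[const] <- 0
  phase <- ((best_T / (2 * pi)) * (atan2(best_b, best_a) %% (2 * pi))) %% 24
  phase[const] <- 0
  q <- stats::p.adjust(p, method = "BH")
  data.frame(
    feature_id = rownames(m), p_value = p, q_value = q,
    period_h = best_T, phase_h = phase, amplitude = amp, mesor = best_m,
    is_rhythmic = q < cfg$q_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Circular phase difference
#'
#' Shortest distance on the 24 h clock: `min(|a - b|, 24 - |a - b|)`,
#' symmetric and bounded in `[0, 12]`.
#'
#' @param phase_a,phase_b phases in hours (vectors recycle).
#' @return hours in `[0, 12]`.
#' @examples circular_phase_diff(23, 1)  # 2
#' @export
circular_phase_diff <- function(phase_a, phase_b) {
  d <- abs(phase_a %% 24 - phase_b %% 24)
  pmin(d, 24 - d)
}

#' Mean signed phase lag between paired rhythmic features
#'
#' For each pair where both members are called rhythmic, the signed lag is
#' `(phase_b - phase_a) mod 24`; only pairs where b genuinely lags a (lag in
#' `(0, 12]`) are retained, and the mean retained lag is returned. In the
#' occupancy-vs-expression use, `calls_a` is occupancy and `calls_b`
#' expression, so the result is the average time by which transcript rhythms
#' trail polymerase recruitment.
#'
#' @param calls_a,calls_b rhythm-call data.frames from [detect_rhythms()].
#' @param pairing data.frame with columns `feature_a`, `feature_b`.
#' @return list with `mean_lag_h`, `n_pairs`, and the retained `lags`.
#' @export
mean_phase_lag <- function(calls_a, calls_b, pairing) {
  a <- calls_a[match(pairing$feature_a, calls_a$feature_id), ]
  b <- calls_b[match(pairing$feature_b, calls_b$feature_id), ]
  both <- !is.na(a$feature_id) & !is.na(b$feature_id) & a$is_rhythmic & b$is_rhythmic
  lag <- (b$phase_h[both] - a$phase_h[both]) %% 24
  lag <- lag[lag > 0 & lag <= 12]
  if (length(lag) == 0) stop("no lagging pairs")
  list(mean_lag_h = mean(lag), n_pairs = length(lag), lags = lag)
}

#' Pearson correlation between paired signal and expression series
#'
#' Per-pair Pearson correlation over the shared time points, plus an overall
#' correlation of the concatenated per-series standardized values. Pairs with
#' a zero-variance member are skipped with a warning.
#'
#' @param series_a,series_b numeric matrices (features x samples) with
#'   feature rownames.
#' @param pairing data.frame with columns `feature_a`, `feature_b`.
#' @return list with `per_pair` (data.frame `feature_a, feature_b, pcc`) and
#'   `overall`.
#' @export
signal_expression_correlation <- function(series_a, series_b, pairing) {
  ia <- match(pairing$feature_a, rownames(series_a))
  ib <- match(pairing$feature_b, rownames(series_b))
  if (any(is.na(ia)) || any(is.na(ib))) stop("pairing references unknown features")
  va <- apply(series_a[ia, , drop = FALSE], 1, stats::sd)
  vb <- apply(series_b[ib, , drop = FALSE], 1, stats::sd)
  ok <- va > 0 & vb > 0
  if (any(!ok)) warning(sum(!ok), " pair(s) with a zero-variance series skipped")
  ia <- ia[ok]; ib <- ib[ok]
  pcc <- vapply(seq_along(ia), function(k) {
    stats::cor(series_a[ia[k], ], series_b[ib[k], ])
  }, numeric(1))
  za <- t(scale(t(series_a[ia, , drop = FALSE])))
  zb <- t(scale(t(series_b[ib, , drop = FALSE])))
  list(
    per_pair = data.frame(feature_a = pairing$feature_a[ok],
                          feature_b = pairing$feature_b[ok],
                          pcc = pcc, stringsAsFactors = FALSE),
    overall = stats::cor(as.vector(t(za)), as.vector(t(zb)))
  )
}
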
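#' Log-uniformly spaced sequence
#'
#' `n` points between `from` and `to` with constant ratio between
#' neighbours; collapses to `from` when `n == 1`.
#'
#' @param from,to positive endpoints.
#' @param n number of points (>= 1).
#' @return numeric vector of length `n`.
#' @keywords internal
#' @noRd
logspace <- function(from, to, n) {
  stopifnot(from > 0, to > 0, n >= 1)
  if (n == 1) return(from)
  exp(seq(log(from), log(to), length.out = n))
}

# stop() with sprintf-style formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# round-half-up; base round() uses banker's rounding on .5 ties
round_half_up <- function(x) floor(x + 0.5)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Otsu threshold of a numeric vector
#'
#' Maximises between-class variance on a fixed-bin histogram. Used for the
#' default vessel-mask threshold policy where no fixed cutoff is supplied.
#'
#' @param x numeric vector (typically positive vesselness values).
#' @param n_bins histogram resolution.
#' @return scalar threshold on the scale of `x`.
#' @keywords internal
#' @noRd
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("otsu_threshold: no finite values")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(n_bins, 1L + floor((x - lo) / (hi - lo) * n_bins)), n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# reflective ("symmetric") 1-D padding indices for length n, pad r
reflect_idx <- function(n, r) {
  if (r == 0) return(seq_len(n))
  left <- pmin(n, rev(seq_len(r)))
  right <- pmax(1L, n - seq_len(r) + 1L)
  c(left, seq_len(n), right)
}

# binary 6-neighbourhood dilation of a logical 3-D array
dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- if (by > 0) c(1L, seq_len(n - 1L)) else c(seq_len(n - 1L) + 1L, n)
    idx[[ax]] <- src
    do.call(`[`, c(list(m), idx))
  }
  for (ax in 1:3) {
    out <- out | shift(mask, ax, 1L) | shift(mask, ax, -1L)
  }
  out
}
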
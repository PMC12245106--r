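# Internal numeric helpers shared across the imaging modules. These are the
# small 3D primitives (separable filters, flood-fill labelling, Otsu) that the
# high-content pipeline needs; all operate on plain numeric arrays.

abort_input <- function(msg) stop(msg, call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort_input(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort_input(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

# Shift an array along one axis, padding with `fill`.
shift_array <- function(a, axis, by, fill) {
  if (by == 0L) return(a)
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- seq_len(d[axis]) - by
  keep <- src >= 1L & src <= d[axis]
  out <- array(fill, dim = d)
  idx_to <- idx; idx_to[[axis]] <- which(keep)
  idx_from <- idx; idx_from[[axis]] <- src[keep]
  out <- do.call(`[<-`, c(list(out), idx_to, list(do.call(`[`, c(list(a), idx_from, list(drop = FALSE))))))
  out
}

# Separable Gaussian smoothing of a 3D array (reflectionless: renormalised
# truncated kernel via constant padding with edge replication is avoided by
# normalising shifted weights against shifted ones-mask).
gaussian_smooth3d <- function(a, sigma) {
  if (all(sigma <= 0)) return(a)
  sigma <- rep(sigma, length.out = 3L)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(2.5 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim = dim(a))
    norm <- array(0, dim = dim(a))
    ones <- array(1, dim = dim(a))
    for (k in seq_along(w)) {
      by <- k - r - 1L
      acc <- acc + w[k] * shift_array(a, axis, by, 0)
      norm <- norm + w[k] * shift_array(ones, axis, by, 0)
    }
    a <- acc / norm
  }
  a
}

# Separable box minimum filter (erosion with a cube of half-width r voxels).
min_filter3d <- function(a, r) {
  r <- rep(as.integer(r), length.out = 3L)
  for (axis in 1:3) {
    if (r[axis] <= 0L) next
    out <- a
    for (by in c(-(seq_len(r[axis])), seq_len(r[axis]))) {
      out <- pmin(out, shift_array(a, axis, by, Inf))
    }
    a <- out
  }
  a
}

# Label the connected component (6-connectivity) of `mask` containing `seed`
# (a length-3 voxel index). Returns a logical array of the same shape.
flood_component <- function(mask, seed) {
  d <- dim(mask)
  lin <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  comp <- logical(length(mask))
  seed_lin <- lin(seed[1], seed[2], seed[3])
  if (!mask[seed_lin]) return(array(FALSE, dim = d))
  frontier <- seed_lin
  comp[frontier] <- TRUE
  strides <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -(d[1] * d[2]))
  nvox <- length(mask)
  # guard x-edges so the +/-1 strides do not wrap across rows
  xi <- ((seq_len(nvox) - 1L) %% d[1]) + 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (s in strides) {
      cand <- frontier + s
      ok <- cand >= 1L & cand <= nvox
      if (s == 1L) ok <- ok & xi[frontier] < d[1]
      if (s == -1L) ok <- ok & xi[frontier] > 1L
      cand <- cand[ok]
      cand <- cand[mask[cand] & !comp[cand]]
      if (length(cand)) {
        comp[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- unique(nxt)
  }
  array(comp, dim = d)
}

# Largest 6-connected component of a logical array.
largest_component <- function(mask) {
  remaining <- mask
  best <- NULL
  best_n <- 0L
  d <- dim(mask)
  while (any(remaining)) {
    seed_lin <- which(remaining)[1]
    k <- (seed_lin - 1L) %/% (d[1] * d[2]) + 1L
    rem <- (seed_lin - 1L) %% (d[1] * d[2])
    j <- rem %/% d[1] + 1L
    i <- rem %% d[1] + 1L
    comp <- flood_component(remaining, c(i, j, k))
    n <- sum(comp)
    if (n > best_n) {
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  if (is.null(best)) array(FALSE, dim = d) else best
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based threshold maximising between-class variance, computed on
#' 256 equal-width bins over the data range. Used as the default threshold
#' for the live/dead channels, where no fixed instrument value exists.
#'
#' @param x Numeric vector or array of intensities.
#' @param levels Number of histogram bins (default 256).
#' @return The threshold value (a scalar on the intensity scale).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) abort_input("`x` has no finite values")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Resolve a threshold spec: "otsu" or a fixed numeric value.
resolve_threshold <- function(values, method) {
  if (is.numeric(method)) return(method)
  if (identical(method, "otsu")) return(otsu_threshold(values))
  abort_input("`threshold_method` must be \"otsu\" or a numeric value")
}

# Derive a stream of sub-seeds from one integer seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
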
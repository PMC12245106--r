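# Stain separation of RGB histology sections (optical-density unmixing) and
# the two-channel correlation analysis used to quantify ECM abundance in
# trichrome-stained spheroid sections.

#' Stain vectors for optical-density unmixing
#'
#' Rows are unit optical-density direction vectors in RGB space. The default
#' pair is the package's aniline-blue / acid-fuchsin set for Masson's
#' trichrome (collagenous ECM vs cytoplasm); supply your own matrix for
#' other protocols — results on real slides depend on the vectors chosen.
#'
#' @param m A k x 3 numeric matrix (k = 2 or 3) of OD directions; rows are
#'   normalised to unit length.
#' @param names Optional stain names (rownames used when present).
#' @return A unit-row matrix of class `stain_vectors`.
#' @export
stain_vectors <- function(m = NULL, names = NULL) {
  if (is.null(m)) {
    m <- rbind(
      `aniline-blue` = c(0.80, 0.56, 0.22),
      `acid-fuchsin` = c(0.10, 0.74, 0.67)
    )
  }
  m <- as.matrix(m)
  if (ncol(m) != 3L || nrow(m) < 2L) abort_input("stain matrix must be k x 3, k >= 2")
  if (!is.null(names)) rownames(m) <- names
  if (is.null(rownames(m))) rownames(m) <- paste0("stain", seq_len(nrow(m)))
  m <- m / sqrt(rowSums(m^2))
  g <- m %*% t(m)
  if (abs(det(g)) < 1e-8) abort_input("stain vectors are (near-)collinear")
  structure(m, class = c("stain_vectors", "matrix"))
}

#' Separate stains by optical-density unmixing
#'
#' Converts each pixel to optical density, `OD = -log((I + eps) / white)`,
#' and projects it onto the stain basis by least squares (the normal
#' equations of the k x 3 stain matrix); concentrations are clipped at 0.
#'
#' @param rgb An h x w x 3 array, values in \[0, 1\] or \[0, 255\].
#' @param vectors A [stain_vectors()] matrix.
#' @param white Optional length-3 white point; defaults to the per-channel
#'   image maximum.
#' @param eps Offset avoiding log(0) (default 1/255 on the \[0, 1\] scale).
#' @return An h x w x k array of stain concentrations, k-th slice named by
#'   stain.
#' @export
stain_separate <- function(rgb, vectors = stain_vectors(), white = NULL,
                           eps = 1 / 255) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    abort_input("`rgb` must be an h x w x 3 array")
  }
  if (max(rgb) > 1) rgb <- rgb / 255
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  px <- matrix(rgb, ncol = 3L)
  if (is.null(white)) white <- pmax(apply(px, 2, max), eps)
  od <- -log(sweep(px + eps, 2, white + eps, `/`))
  m <- unclass(vectors)
  conc <- od %*% t(m) %*% solve(m %*% t(m))
  conc[conc < 0] <- 0
  out <- array(conc, dim = c(h, w, nrow(m)))
  dimnames(out) <- list(NULL, NULL, rownames(m))
  out
}

# Forward render of stain concentrations back to RGB (Beer-Lambert); used to
# verify unmixing round-trips.
render_stains <- function(conc, vectors = stain_vectors(), white = c(1, 1, 1)) {
  m <- unclass(vectors)
  h <- dim(conc)[1]; w <- dim(conc)[2]
  od <- matrix(conc, ncol = nrow(m)) %*% m
  px <- sweep(exp(-od), 2, white, `*`)
  array(px, dim = c(h, w, 3L))
}

#' Pearson correlation between two image channels
#'
#' @param ch1,ch2 Numeric vectors/matrices of equal length.
#' @param mask Optional logical mask selecting the pixels to use.
#' @return Pearson's R in \[-1, 1\]; `NA` with a warning when either channel
#'   has zero variance.
#' @export
channel_pearson <- function(ch1, ch2, mask = NULL) {
  ch1 <- as.numeric(ch1); ch2 <- as.numeric(ch2)
  if (length(ch1) != length(ch2)) abort_input("channel lengths differ")
  if (!is.null(mask)) {
    ch1 <- ch1[as.logical(mask)]
    ch2 <- ch2[as.logical(mask)]
  }
  if (length(ch1) < 2L) abort_input("need >= 2 pixels after masking")
  if (var(ch1) == 0 || var(ch2) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(ch1, ch2)
}

#' Joint (2D) histogram of two channels
#'
#' @param ch1,ch2 Numeric vectors/matrices of equal length.
#' @param bins Number of bins per axis (>= 2).
#' @param mask Optional logical mask.
#' @return A list of class `joint_histogram`: `counts` (bins x bins matrix,
#'   summing to the number of masked pixels), `x_breaks`, `y_breaks`.
#' @export
joint_histogram <- function(ch1, ch2, bins = 64L, mask = NULL) {
  if (bins < 2L) abort_input("`bins` must be >= 2")
  ch1 <- as.numeric(ch1); ch2 <- as.numeric(ch2)
  if (length(ch1) != length(ch2)) abort_input("channel lengths differ")
  if (!is.null(mask)) {
    ch1 <- ch1[as.logical(mask)]
    ch2 <- ch2[as.logical(mask)]
  }
  xb <- seq(min(ch1), max(ch1), length.out = bins + 1L)
  yb <- seq(min(ch2), max(ch2), length.out = bins + 1L)
  ix <- findInterval(ch1, xb, rightmost.closed = TRUE)
  iy <- findInterval(ch2, yb, rightmost.closed = TRUE)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, x_breaks = xb, y_breaks = yb),
            class = "joint_histogram")
}

#' @rdname joint_histogram
#' @param object A `joint_histogram`.
#' @param ... Unused.
#' @export
autoplot.joint_histogram <- function(object, ...) {
  bins <- nrow(object$counts)
  xm <- (object$x_breaks[-1] + object$x_breaks[-(bins + 1L)]) / 2
  ym <- (object$y_breaks[-1] + object$y_breaks[-(bins + 1L)]) / 2
  d <- tibble(
    x = rep(xm, times = bins),
    y = rep(ym, each = bins),
    count = as.vector(object$counts)
  )
  ggplot2::ggplot(filter(d, .data$count > 0),
                  ggplot2::aes(.data$x, .data$y, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "channel 1", y = "channel 2", fill = "pixels") +
    ggplot2::theme_minimal()
}
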
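#' Z-scored sliding windows of a circular reference barcode
#'
#' Builds the `x_max` by `m` matrix whose row `x` is the reference window of
#' length `m` starting at pixel `x` (wrapping around the circle), centered
#' and scaled to unit Euclidean norm. With windows in this form the Pearson
#' correlation of a contig against every window is a single matrix-vector
#' product, which is also how the random-barcode null is scored cheaply.
#' Zero-variance windows become all-zero rows (their correlation is defined
#' as 0) and are flagged in the `"degenerate"` attribute.
#'
#' @param reference a circular [barcode()].
#' @param m window length in pixels (1 < m <= n_px).
#' @return numeric matrix with attribute `degenerate` (logical row flags).
#' @export
reference_windows <- function(reference, m) {
  stopifnot(inherits(reference, "cb_barcode"), reference$circular)
  x_max <- reference$n_px
  if (m > x_max) stop("window longer than the reference")
  if (m < 2L) stop("windows need at least 2 pixels")
  v <- reference$values
  idx <- outer(seq_len(x_max) - 1L, seq_len(m) - 1L, `+`) %% x_max + 1L
  W <- matrix(v[idx], nrow = x_max, ncol = m)
  W <- W - rowMeans(W)
  nrm <- sqrt(rowSums(W * W))
  degen <- nrm < 1e-12
  nrm[degen] <- 1
  W <- W / nrm
  W[degen, ] <- 0
  attr(W, "degenerate") <- degen
  W
}

# Center and scale to unit norm; zero-variance vectors map to all zeros.
unitize <- function(v) {
  v <- v - mean(v)
  n <- sqrt(sum(v * v))
  if (n < 1e-12) return(list(v = v * 0, degenerate = TRUE))
  list(v = v / n, degenerate = FALSE)
}

#' Sliding Pearson match scores of a contig against the reference
#'
#' Slides the (linear) contig barcode along the circular reference and
#' computes a Pearson correlation at every integer pixel offset, in both
#' orientations: entries `1..x_max` are forward starts, entries
#' `x_max+1..2*x_max` are the same starts with the contig reversed
#' ("flipped"). Windows wrap around the circular reference. Degenerate
#' zero-variance windows or contigs score 0 (with a warning for the contig
#' case).
#'
#' @param contig a [barcode()] (linear fragment).
#' @param reference a circular [barcode()] on the same bp-per-pixel scale.
#' @param W optional precomputed [reference_windows()] matrix for this
#'   contig length (an optimization for repeated calls; it is checked for
#'   size only).
#' @return object of class `cb_matchtable`: list with `contig_id`, `scores`
#'   (length `2 * x_max`, each in \[-1, 1\]), `contig_len_px`, `x_max`.
#' @export
sliding_pearson <- function(contig, reference, W = NULL) {
  stopifnot(inherits(contig, "cb_barcode"), inherits(reference, "cb_barcode"))
  if (!reference$circular) stop("the reference barcode must be circular")
  if (!isTRUE(all.equal(contig$bp_per_px, reference$bp_per_px)))
    stop("contig and reference are on different bp-per-pixel scales")
  m <- contig$n_px
  if (m > reference$n_px) stop("contig barcode longer than the reference")
  if (is.null(W)) W <- reference_windows(reference, m)
  stopifnot(nrow(W) == reference$n_px, ncol(W) == m)
  cz <- unitize(contig$values)
  if (cz$degenerate)
    warning("zero-variance contig barcode; all match scores set to 0")
  fwd <- as.numeric(W %*% cz$v)
  rev_ <- as.numeric(W %*% rev(cz$v))
  scores <- pmin(pmax(c(fwd, rev_), -1), 1)
  structure(list(contig_id = if (is.null(contig$id)) "contig" else contig$id,
                 scores = scores, contig_len_px = m,
                 x_max = reference$n_px),
            class = "cb_matchtable")
}

#' @export
print.cb_matchtable <- function(x, ...) {
  bm <- best_match(x)
  cat(sprintf(
    "<cb_matchtable> %s: %d px contig vs %d px reference; max C = %.4f at x = %d (%s)\n",
    x$contig_id, x$contig_len_px, x$x_max, bm$c_hat, bm$x_star,
    bm$orientation))
  invisible(x)
}

#' Best match of a contig
#'
#' The maximum entry of a match table; ties are broken deterministically by
#' the smallest position, forward before flipped.
#'
#' @param table a `cb_matchtable` from [sliding_pearson()].
#' @return list with `contig_id`, `c_hat` (the maximum score), `x_star`
#'   (1-based start pixel) and `orientation` (`"forward"`/`"flipped"`).
#' @export
best_match <- function(table) {
  stopifnot(inherits(table, "cb_matchtable"))
  i <- which.max(table$scores)   # first maximum: smallest x, forward first
  x_max <- table$x_max
  list(contig_id = table$contig_id,
       c_hat = table$scores[i],
       x_star = if (i <= x_max) i else i - x_max,
       orientation = if (i <= x_max) "forward" else "flipped")
}

#' Export a match table as TSV
#'
#' Columns: contig_id, x (start pixel), orientation, score.
#'
#' @param table a `cb_matchtable`.
#' @param path output file.
#' @export
write_matchtable <- function(table, path) {
  x_max <- table$x_max
  df <- data.frame(contig_id = table$contig_id,
                   x = rep(seq_len(x_max), 2L),
                   orientation = rep(c("forward", "flipped"),
                                     each = x_max),
                   score = table$scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
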
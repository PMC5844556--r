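#' Lag-1 autocorrelation of a barcode
#'
#' Pixels along an optical barcode are correlated (chiefly by the PSF); the
#' random-barcode null must match that correlation or p-values would be far
#' too optimistic. This returns the lag-1 autocorrelation of the
#' mean-removed barcode, clipped to \[0, 0.999\].
#'
#' @param contig a [barcode()] with at least 3 pixels.
#' @return scalar in \[0, 0.999\].
#' @export
estimate_autocorrelation <- function(contig) {
  v <- if (inherits(contig, "cb_barcode")) contig$values else as.numeric(contig)
  n <- length(v)
  if (n < 3L) stop("need at least 3 pixels to estimate autocorrelation")
  s <- v - mean(v)
  den <- sum(s * s)
  if (den < 1e-24) stop("zero-variance barcode")
  r1 <- sum(s[-n] * s[-1L]) / den
  min(max(r1, 0), 0.999)
}

#' Generate autocorrelation-matched random barcodes
#'
#' Stationary Gaussian random barcodes with the requested lag-1
#' autocorrelation, each column z-normalized. Used to build the null
#' distribution of the maximum match score for a given contig length. Two
#' constructions are available behind the same interface: `"ar1"` (default)
#' is a first-order autoregression, whose autocorrelation decays
#' exponentially with lag; `"kernel"` is white noise filtered with the
#' Gaussian kernel whose width reproduces the requested lag-1 value, giving
#' the Gaussian-shaped autocorrelation that PSF-blurred barcodes actually
#' have (the pipeline uses this one).
#'
#' @param length_px barcode length in pixels.
#' @param corr_param lag-1 autocorrelation in \[0, 1).
#' @param R number of barcodes.
#' @param seed integer seed (the draw is reproducible given the seed).
#' @param method `"ar1"` or `"kernel"`.
#' @return numeric matrix, `length_px` rows by `R` columns.
#' @export
generate_random_barcodes <- function(length_px, corr_param, R,
                                     seed = NULL,
                                     method = c("ar1", "kernel")) {
  stopifnot(R >= 1, corr_param >= 0, corr_param < 1, length_px >= 2)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (method == "ar1" || corr_param == 0) {
    eps <- matrix(rnorm(length_px * R), length_px, R)
    x <- eps
    if (corr_param > 0) {
      a <- sqrt(1 - corr_param^2)
      for (i in 2:length_px)
        x[i, ] <- corr_param * x[i - 1L, ] + a * eps[i, ]
    }
  } else {
    # Gaussian-filtered white noise: ACF(k) = exp(-k^2 / (4 sigma^2)),
    # so sigma is chosen from the requested lag-1 autocorrelation.
    sig <- sqrt(-1 / (4 * log(corr_param)))
    r <- ceiling(4 * sig)
    k <- dnorm(-r:r, sd = sig)
    k <- k / sum(k)
    eps <- matrix(rnorm((length_px + 2L * r) * R), length_px + 2L * r, R)
    x <- apply(eps, 2L, function(col)
      stats::filter(col, k, sides = 2)[(r + 1L):(r + length_px)])
    x <- matrix(x, length_px, R)
  }
  x <- sweep(x, 2L, colMeans(x))
  sdv <- sqrt(colSums(x * x) / (length_px - 1L))
  sweep(x, 2L, sdv, `/`)
}

# Max match score over both orientations for each column of a barcode
# matrix, against precomputed reference windows W.
max_scores_against <- function(W, X) {
  Xc <- sweep(X, 2L, colMeans(X))
  nrm <- sqrt(colSums(Xc * Xc))
  nrm[nrm < 1e-12] <- 1
  Xc <- sweep(Xc, 2L, nrm, `/`)
  s1 <- W %*% Xc
  s2 <- W %*% Xc[rev(seq_len(nrow(Xc))), , drop = FALSE]
  pmin(pmax(apply(s1, 2L, max), apply(s2, 2L, max)), 1)
}

# Null CDF of a single Pearson correlation with nu effective samples:
# (c+1)/2 ~ Beta(a, a) with a = (nu-2)/2, i.e. density ~ (1-c^2)^((nu-4)/2).
log_G <- function(c, nu) {
  a <- (nu - 2) / 2
  log1p(-pbeta((c + 1) / 2, a, a, lower.tail = FALSE))
}

log_g <- function(c, nu) {
  a <- (nu - 2) / 2
  dbeta((c + 1) / 2, a, a, log = TRUE) - log(2)
}

#' Fit the parametric null density of the maximum match score
#'
#' Two parametric descriptions of the `R` observed null maxima are fitted
#' by maximum likelihood:
#'
#' * the CDF power `F(c) = G(c; nu_eff)^n_eff`, where `G` is the null CDF
#'   of a single Pearson correlation for `nu_eff` effective samples and
#'   `n_eff` is the effective number of independent comparisons (both
#'   "effective" because pixels within a window, and overlapping windows,
#'   are correlated), plus a Gumbel baseline for comparison; and
#' * a generalized extreme-value (GEV) density on the Fisher-transformed
#'   maxima `z = atanh(c)` — the classical limit law for maxima of smooth
#'   correlated Gaussian fields, whose (typically negative) shape parameter
#'   captures the sharp upper edge that the CDF-power family overshoots.
#'
#' The CDF-power parameters are reported for diagnostics and
#' length-dependence studies; p-values ([score_to_pvalue()]) use the GEV
#' tail, which calibrates markedly better in the decision region
#' (p of order `p_thresh`), falling back to the CDF-power form if the GEV
#' fit fails.
#'
#' @param max_scores numeric vector of maximum scores from random barcodes,
#'   each in (-1, 1).
#' @param n_comparisons hint for initializing `n_eff` (e.g. `2 * x_max`).
#' @param contig_len_px,corr_param,r_used metadata recorded in the fit.
#' @return object of class `cb_nullfit` with fields `nu_eff`, `n_eff`,
#'   `fit_loglik`, `gumbel_loc`, `gumbel_scale`, `gumbel_loglik`,
#'   `better_fit`, `gev` (loc/scale/shape/loglik or `NULL`),
#'   `pvalue_model` (`"gev"` or `"cdf_power"`), plus the metadata.
#' @export
fit_null <- function(max_scores, n_comparisons = NULL,
                     contig_len_px = NA_integer_, corr_param = NA_real_,
                     r_used = length(max_scores)) {
  c_ <- as.numeric(max_scores)
  if (length(c_) < 10L) stop("too few max scores to fit a null")
  if (sd(c_) < 1e-12) stop("degenerate max scores (all equal)")
  c_ <- pmin(pmax(c_, -1 + 1e-9), 1 - 1e-9)
  if (is.null(n_comparisons)) n_comparisons <- 100

  nll <- function(theta) {
    nu <- 3 + exp(theta[1L])
    ne <- exp(theta[2L])
    lG <- log_G(c_, nu)
    -sum(log(ne) + (ne - 1) * lG + log_g(c_, nu))
  }
  starts <- expand.grid(nu = c(6, 25, 100),
                        ne = unique(pmax(c(n_comparisons,
                                           n_comparisons / 8), 2)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(log(starts$nu[i] - 3), log(starts$ne[i])), nll,
            method = "L-BFGS-B",
            lower = c(log(0.2), 0), upper = c(log(20000), log(1e8))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("maximum-likelihood fit of the null density failed")

  # Gumbel baseline
  b0 <- sd(c_) * sqrt(6) / pi
  gnll <- function(th) {
    b <- exp(th[2L])
    z <- (c_ - th[1L]) / b
    sum(log(b) + z + exp(-z))
  }
  gfit <- tryCatch(optim(c(mean(c_) - 0.5772157 * b0, log(b0)), gnll),
                   error = function(e) NULL)

  # GEV on Fisher-transformed maxima; used for the p-value tail
  z_ <- atanh(c_)
  zb0 <- sd(z_) * sqrt(6) / pi
  gevnll <- function(th) {
    b <- exp(th[2L])
    t <- 1 + th[3L] * (z_ - th[1L]) / b
    if (any(t <= 0)) return(1e10)
    if (abs(th[3L]) < 1e-8) {
      zz <- (z_ - th[1L]) / b
      return(sum(log(b) + zz + exp(-zz)))
    }
    sum(log(b) + (1 + 1 / th[3L]) * log(t) + t^(-1 / th[3L]))
  }
  gev <- NULL
  gbest <- NULL
  for (xi0 in c(-0.15, -0.05, 0.05)) {
    gf <- tryCatch(
      optim(c(mean(z_) - 0.5772157 * zb0, log(zb0), xi0), gevnll),
      error = function(e) NULL)
    if (!is.null(gf) && gf$value < 1e9 &&
        (is.null(gbest) || gf$value < gbest$value)) gbest <- gf
  }
  if (!is.null(gbest) && abs(gbest$par[3L]) < 1)
    gev <- list(loc = gbest$par[1L], scale = exp(gbest$par[2L]),
                shape = gbest$par[3L], loglik = -gbest$value)

  structure(list(contig_len_px = as.integer(contig_len_px),
                 corr_param = corr_param,
                 nu_eff = 3 + exp(best$par[1L]),
                 n_eff = exp(best$par[2L]),
                 fit_loglik = -best$value,
                 gumbel_loc = if (is.null(gfit)) NA_real_ else gfit$par[1L],
                 gumbel_scale = if (is.null(gfit)) NA_real_ else
                   exp(gfit$par[2L]),
                 gumbel_loglik = if (is.null(gfit)) -Inf else -gfit$value,
                 better_fit = if (is.null(gfit) ||
                                  -best$value >= -gfit$value) "cdf_power"
                              else "gumbel",
                 gev = gev,
                 pvalue_model = if (is.null(gev)) "cdf_power" else "gev",
                 r_used = as.integer(r_used)),
            class = "cb_nullfit")
}

#' @export
print.cb_nullfit <- function(x, ...) {
  cat(sprintf(
    "<cb_nullfit> len = %s px, corr = %s: nu_eff = %.2f, n_eff = %.1f (logLik %.1f; %s fits better)\n",
    x$contig_len_px, format(x$corr_param, digits = 3), x$nu_eff, x$n_eff,
    x$fit_loglik, x$better_fit))
  invisible(x)
}

# Fitted CDF of the maximum score under the model used for p-values.
null_cdf <- function(c, fit) 1 - score_to_pvalue(c, fit)

#' Quantile of the fitted max-score null
#'
#' @param p probability in \[0, 1\].
#' @param fit a `cb_nullfit`.
#' @return score c with `F(c) = p` under the model used for p-values.
#' @export
qnull_max <- function(p, fit) {
  if (identical(fit$pvalue_model, "gev")) {
    g <- fit$gev
    z <- if (abs(g$shape) < 1e-8) g$loc - g$scale * log(-log(p)) else
      g$loc + g$scale / g$shape * ((-log(p))^(-g$shape) - 1)
    tanh(z)
  } else {
    a <- (fit$nu_eff - 2) / 2
    2 * qbeta(p^(1 / fit$n_eff), a, a) - 1
  }
}

#' Convert a match score to a p-value
#'
#' `p = 1 - F(c)` under the fitted max-score null, evaluated through the
#' closed form of the fitted tail (no numerical quadrature): the GEV
#' survival function on `atanh(c)` when that fit is available, otherwise
#' the CDF power `-expm1(n_eff * log G)`. Values are floored at `1e-15` so
#' the Fisher transform `-2 log p` stays finite. Vectorized over `c`.
#'
#' @param c score(s) in \[-1, 1\].
#' @param fit a `cb_nullfit`.
#' @return p-value(s) in \[0, 1\], monotone non-increasing in `c`.
#' @export
score_to_pvalue <- function(c, fit) {
  stopifnot(inherits(fit, "cb_nullfit"))
  c <- pmin(pmax(as.numeric(c), -1), 1)
  if (identical(fit$pvalue_model, "gev")) {
    g <- fit$gev
    z <- atanh(pmin(pmax(c, -1 + 1e-15), 1 - 1e-15))
    if (abs(g$shape) < 1e-8) {
      p <- -expm1(-exp(-(z - g$loc) / g$scale))
    } else {
      t <- pmax(1 + g$shape * (z - g$loc) / g$scale, 0)
      p <- -expm1(-t^(-1 / g$shape))
    }
  } else {
    p <- -expm1(fit$n_eff * log_G(c, fit$nu_eff))
  }
  p <- pmin(pmax(p, 1e-15), 1)
  p[c >= 1] <- 0
  p[c <= -1] <- 1
  p
}

#' Partition contigs by the length threshold
#'
#' Optical resolution is set by the PSF width, so barcodes need to be
#' several PSF widths long to carry spatial information; the default
#' threshold is 12 sigma (about 12 kbp at sigma = 1 kbp). Contigs at least
#' `l_thresh_bp` long are kept.
#'
#' @param contigs list of [dna_sequence()] records.
#' @param l_thresh_bp length threshold in bp (>= 0; 0 keeps everything).
#' @return list with elements `kept` and `discarded`.
#' @export
length_filter <- function(contigs, l_thresh_bp) {
  stopifnot(l_thresh_bp >= 0)
  if (!length(contigs)) return(list(kept = list(), discarded = list()))
  lens <- vapply(contigs, seq_length, 0L)
  list(kept = contigs[lens >= l_thresh_bp],
       discarded = contigs[lens < l_thresh_bp])
}

#' Fit the null for one contig length against a reference
#'
#' Runs the full step-3 protocol: estimate the contig's lag-1
#' autocorrelation, generate `R` matched random barcodes, score each against
#' the reference over all positions and both orientations, keep the maxima,
#' and fit the parametric density.
#'
#' @param contig a contig [barcode()].
#' @param reference the circular reference [barcode()].
#' @param R number of random barcodes (default 1000).
#' @param seed integer seed for the random barcodes.
#' @param W optional precomputed [reference_windows()] for this length.
#' @param method random-barcode construction, see
#'   [generate_random_barcodes()]; the pipeline default is `"kernel"`,
#'   matching the Gaussian-shaped autocorrelation of PSF-blurred barcodes.
#' @return a `cb_nullfit`.
#' @export
null_fit_for <- function(contig, reference, R = 1000L, seed = NULL,
                         W = NULL, method = "kernel") {
  rho <- estimate_autocorrelation(contig)
  m <- contig$n_px
  if (is.null(W)) W <- reference_windows(reference, m)
  X <- generate_random_barcodes(m, rho, R, seed = seed, method = method)
  mx <- max_scores_against(W, X)
  fit_null(mx, n_comparisons = 2 * reference$n_px, contig_len_px = m,
           corr_param = rho, r_used = R)
}

#' Null-fit cache
#'
#' Fits are cached by contig length (pixels) and lag-1 autocorrelation
#' rounded to 2 decimals, so contigs of similar statistics share one fit.
#' The cache can be serialized to JSON and restored.
#'
#' @return `new_null_cache()` returns an empty cache (an environment).
#' @export
new_null_cache <- function() new.env(parent = emptyenv())

null_cache_key <- function(length_px, corr_param)
  sprintf("L%d_r%.2f", as.integer(length_px), corr_param)

cache_get_or_fit <- function(cache, length_px, corr_param, fitter) {
  key <- null_cache_key(length_px, corr_param)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  fit <- fitter(key)
  if (!is.null(cache)) cache[[key]] <- fit
  fit
}

#' @param cache a cache from `new_null_cache()`.
#' @param path JSON file.
#' @rdname new_null_cache
#' @export
null_cache_to_json <- function(cache, path) {
  keys <- ls(cache)
  obj <- lapply(setNames(keys, keys), function(k) unclass(cache[[k]]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname new_null_cache
#' @export
null_cache_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cache <- new_null_cache()
  for (k in names(obj)) {
    fit <- obj[[k]]
    fit$contig_len_px <- as.integer(fit$contig_len_px)
    cache[[k]] <- structure(fit, class = "cb_nullfit")
  }
  cache
}
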
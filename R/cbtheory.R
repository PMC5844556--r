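#' Optical DNA barcode container
#'
#' A 1-D pixel intensity vector with the physical metadata needed to compare
#' barcodes: the pixel scale (bp per pixel), the point-spread-function width
#' used to blur the underlying binding profile, and circularity. Both
#' theoretical contig barcodes and (pseudo-)experimental reference barcodes
#' use this container.
#'
#' @param values numeric vector of pixel intensities (arbitrary fluorescence
#'   units; may be z-normalized).
#' @param bp_per_px basepairs per pixel (> 0).
#' @param psf_sigma_bp PSF standard deviation in bp (>= 0).
#' @param circular logical.
#' @param id optional identifier.
#' @return object of class `cb_barcode` with fields `values`, `bp_per_px`,
#'   `psf_sigma_bp`, `circular`, `n_px`, `id`.
#' @export
barcode <- function(values, bp_per_px, psf_sigma_bp, circular = FALSE,
                    id = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a barcode needs at least one pixel")
  if (!is.finite(bp_per_px) || bp_per_px <= 0) stop("bp_per_px must be > 0")
  if (!is.finite(psf_sigma_bp) || psf_sigma_bp < 0)
    stop("psf_sigma_bp must be >= 0")
  structure(list(values = values, bp_per_px = bp_per_px,
                 psf_sigma_bp = psf_sigma_bp, circular = isTRUE(circular),
                 n_px = length(values), id = id),
            class = "cb_barcode")
}

#' @export
print.cb_barcode <- function(x, ...) {
  cat(sprintf("<cb_barcode>%s %d px, %g bp/px, PSF sigma %g bp, %s\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              x$n_px, x$bp_per_px, x$psf_sigma_bp,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

# Sequence-derived lattice inputs that stay fixed while free
# concentrations are iterated: per-start binding constants for both
# species (with illegal linear starts zeroed).
lattice_sites <- function(seq, params) {
  L <- seq_length(seq)
  foot <- c(params$footprint_yoyo, params$footprint_netropsin)
  if (!seq$circular && L < max(foot))
    stop("linear sequence shorter than the largest ligand footprint (",
         max(foot), " bp)")
  KY <- rep(params$K_yoyo, L)
  if (!seq$circular && params$footprint_yoyo > 1L)
    KY[(L - params$footprint_yoyo + 2L):L] <- 0
  list(L = L, foot = foot, KY = KY,
       KN = netropsin_site_constants(seq, params),
       circular = seq$circular)
}

lattice_stats_sites <- function(sites, c_free_yoyo, c_free_netropsin) {
  res <- lattice_occupancy_cpp(sites$L, sites$foot,
                               list(sites$KY * c_free_yoyo,
                                    sites$KN * c_free_netropsin),
                               sites$circular)
  list(pstart_yoyo = res$pstart[[1]], pstart_netropsin = res$pstart[[2]],
       logZ = res$logZ, L = sites$L)
}

# Per-start ligand placement probabilities and log partition function for a
# sequence under given free concentrations. Species 1 = YOYO, 2 = netropsin.
lattice_stats <- function(seq, params, c_free_yoyo, c_free_netropsin) {
  lattice_stats_sites(lattice_sites(seq, params), c_free_yoyo,
                      c_free_netropsin)
}

# Rolling sum of per-start probabilities over the ligand footprint: the
# probability that basepair j is covered by a ligand starting in
# (j - f + 1) .. j.
coverage_from_starts <- function(pstart, f, circular) {
  L <- length(pstart)
  if (f == 1L) return(pstart)
  ps <- if (circular) c(pstart[(L - f + 2L):L], pstart) else
    c(numeric(f - 1L), pstart)
  cs <- cumsum(ps)
  cs[seq.int(f, length.out = L)] - c(0, cs[seq_len(L - 1L)])
}

#' Solve for free ligand concentrations
#'
#' The equilibrium occupancies depend on the *free* (unbound) ligand
#' concentrations, which are themselves depleted by binding. This solves the
#' two-ligand mass balance `c_total = c_free + n_bound(c_free) * conc_dna`
#' self-consistently, where `n_bound` is the expected number of bound
#' ligands per basepair on the given sequence at the current free
#' concentrations. An adaptively damped fixed-point iteration is used
#' (relative tolerance `tol`, at most `max_iter` iterations); failure to
#' converge is an error reporting the residuals.
#'
#' @param params [ligand_params()].
#' @param seq [dna_sequence()].
#' @param tol relative mass-balance tolerance.
#' @param max_iter iteration cap.
#' @return named numeric: `c(yoyo = ..., netropsin = ...)` in uM.
#' @export
free_concentrations <- function(params, seq, tol = 1e-9, max_iter = 200L) {
  free_concentrations_sites(params, lattice_sites(seq, params), tol,
                            max_iter)
}

free_concentrations_sites <- function(params, sites, tol = 1e-9,
                                      max_iter = 200L) {
  ctot <- c(yoyo = params$conc_yoyo_total,
            netropsin = params$conc_netropsin_total)
  if (params$conc_dna == 0 ||
      (params$K_yoyo == 0 && all(params$netropsin_constants == 0)))
    return(ctot)
  scale <- pmax(ctot, .Machine$double.eps)
  bound <- function(cf) {
    st <- lattice_stats_sites(sites, cf[1], cf[2])
    c(sum(st$pstart_yoyo), sum(st$pstart_netropsin)) / st$L *
      params$conc_dna
  }
  cf <- ctot
  damp <- 1
  res <- Inf
  for (it in seq_len(max_iter)) {
    tgt <- pmax(ctot - bound(cf), 0)
    new_res <- max(abs(tgt - cf) / scale)
    if (new_res <= tol) return(setNames(tgt, names(ctot)))
    # halve the step whenever the residual fails to shrink (the undamped
    # map can 2-cycle when its slope is below -1); never re-enlarge, so
    # oscillating regimes settle
    if (new_res >= res) damp <- damp / 2
    cf <- cf + damp * (tgt - cf)
    res <- new_res
  }
  stop(sprintf(paste0("free-concentration iteration did not converge in %d ",
                      "steps (relative residual %.3g, tolerance %.3g)"),
               max_iter, res, tol))
}

#' Per-basepair YOYO-1 binding probability
#'
#' Computes, for every basepair, the probability that it is covered by a
#' bound YOYO-1 molecule, under grand-canonical equilibrium of two competing
#' hard-core ligands (fluorescent YOYO-1 with a uniform binding constant;
#' netropsin with a sequence-dependent 4-mer constant) on the basepair
#' lattice. Circular sequences use periodic boundary conditions; linear
#' sequences use free ends. This per-bp probability vector is the raw signal
#' that, once blurred by the PSF and sampled to pixels, becomes the barcode.
#'
#' @param seq [dna_sequence()]; for linear sequences the length must be at
#'   least the largest footprint.
#' @param params [ligand_params()].
#' @param c_free_yoyo,c_free_netropsin free concentrations in uM, normally
#'   from [free_concentrations()].
#' @return numeric vector of probabilities in \[0, 1\], one per basepair.
#' @export
yoyo_binding_profile <- function(seq, params, c_free_yoyo,
                                 c_free_netropsin) {
  st <- lattice_stats(seq, params, c_free_yoyo, c_free_netropsin)
  p <- coverage_from_starts(st$pstart_yoyo, params$footprint_yoyo,
                            seq$circular)
  pmin(pmax(p, 0), 1)
}

# Session cache of kernel FFTs, keyed by (padded length, sigma); cleared
# when it grows past a few dozen entries.
.psf_cache <- new.env(parent = emptyenv())

# FFT convolution of x with a Gaussian kernel (radius 4 sigma), either
# wrap-around (circular) or with edge-renormalization (linear): near a free
# end the kernel mass falling off the molecule is excluded and the
# remaining mass renormalized to 1. Linear signals are zero-padded to a
# fast composite FFT length; the edge denominator has a closed form from
# the kernel's cumulative sums, so one forward and one inverse transform
# suffice per call.
gaussian_smooth <- function(x, sigma, circular) {
  if (sigma == 0) return(x)
  L <- length(x)
  r <- ceiling(4 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  if (circular) {
    kc <- numeric(L)
    idx <- mod1((-r:r) + 1L, L)
    for (i in seq_along(k)) kc[idx[i]] <- kc[idx[i]] + k[i]
    Re(fft(fft(x) * fft(kc), inverse = TRUE)) / L
  } else {
    nf <- stats::nextn(L + 2L * r, c(2L, 3L))
    key <- sprintf("%d_%.6g", nf, sigma)
    if (is.null(.psf_cache[[key]])) {
      if (length(ls(.psf_cache)) > 32L)
        rm(list = ls(.psf_cache), envir = .psf_cache)
      kp <- numeric(nf)
      kp[mod1((-r:r) + 1L, nf)] <- k
      .psf_cache[[key]] <- fft(kp)
    }
    xp <- c(x, numeric(nf - L))
    num <- Re(fft(fft(xp) * .psf_cache[[key]], inverse = TRUE))[seq_len(L)] / nf
    i <- seq_len(L)
    cs <- c(0, cumsum(k))              # prefix sums over offsets -r..r
    den <- cs[pmin(r, L - i) + r + 2L] - cs[pmax(-r, 1L - i) + r + 1L]
    num / den
  }
}

#' Blur a binding profile with the optical point spread function
#'
#' Discrete Gaussian convolution of the per-bp binding probability with a
#' kernel of standard deviation `sigma_bp`. Circular profiles use
#' wrap-around convolution (which conserves the mean exactly); linear
#' profiles renormalize the kernel at the edges so the kernel mass in use
#' always sums to 1.
#'
#' @param profile numeric per-bp vector.
#' @param sigma_bp Gaussian standard deviation in bp; 0 is the identity.
#' @param circular logical.
#' @return smoothed per-bp numeric vector.
#' @export
apply_psf <- function(profile, sigma_bp, circular = FALSE) {
  stopifnot(is.numeric(profile), sigma_bp >= 0)
  gaussian_smooth(as.numeric(profile), sigma_bp, isTRUE(circular))
}

#' Downsample a per-bp signal to pixel resolution
#'
#' @param smoothed per-bp numeric vector.
#' @param bp_per_px basepairs per pixel (>= 1). The number of pixels is
#'   `round(length / bp_per_px)` (an error if that is < 1).
#' @param method `"interp"` (default) linearly interpolates the bp-resolution
#'   signal at pixel centers; `"block"` averages the basepairs falling in
#'   each pixel.
#' @param circular logical; circular signals interpolate across the origin.
#' @param psf_sigma_bp PSF width recorded in the output metadata.
#' @param id identifier recorded in the output.
#' @return a [barcode()].
#' @export
to_pixel_resolution <- function(smoothed, bp_per_px,
                                method = c("interp", "block"),
                                circular = FALSE, psf_sigma_bp = 0,
                                id = NULL) {
  method <- match.arg(method)
  stopifnot(bp_per_px >= 1)
  L <- length(smoothed)
  n_px <- round(L / bp_per_px)
  if (n_px < 1) stop("signal shorter than one pixel at ", bp_per_px,
                     " bp/px")
  if (bp_per_px == 1 && n_px == L) {
    vals <- as.numeric(smoothed)
  } else if (method == "block") {
    bnd <- floor(seq_len(n_px) * L / n_px)
    lo <- c(1L, head(bnd, -1L) + 1L)
    vals <- vapply(seq_len(n_px),
                   function(j) mean(smoothed[lo[j]:bnd[j]]), 0)
  } else {
    px_size <- L / n_px
    centers <- (seq_len(n_px) - 0.5) * px_size
    xs <- seq_len(L) - 0.5
    if (circular) {
      xs <- c(xs[L] - L, xs, xs[1] + L)
      ys <- c(smoothed[L], smoothed, smoothed[1])
    } else ys <- smoothed
    vals <- approx(xs, ys, xout = centers, rule = 2)$y
  }
  barcode(vals, bp_per_px = bp_per_px, psf_sigma_bp = psf_sigma_bp,
          circular = circular, id = id)
}

#' Convert a DNA sequence into a theoretical competitive-binding barcode
#'
#' The full theory pipeline for one sequence: solve the free ligand
#' concentrations on this sequence, compute the per-bp YOYO-1 binding
#' probability by the lattice equilibrium, blur with the PSF, and sample
#' down to pixel resolution. Deterministic.
#'
#' @param seq [dna_sequence()].
#' @param params [ligand_params()].
#' @param sigma_bp PSF standard deviation in bp (default 1000, about the
#'   width of the optical point spread function).
#' @param bp_per_px pixel scale in bp (default 500).
#' @param method downsampling method, see [to_pixel_resolution()].
#' @return a [barcode()] at pixel resolution.
#' @export
sequence_to_barcode <- function(seq, params = ligand_params(),
                                sigma_bp = 1000, bp_per_px = 500,
                                method = "interp") {
  sites <- lattice_sites(seq, params)
  cf <- free_concentrations_sites(params, sites)
  st <- lattice_stats_sites(sites, cf[["yoyo"]], cf[["netropsin"]])
  prof <- pmin(pmax(coverage_from_starts(st$pstart_yoyo,
                                         params$footprint_yoyo,
                                         seq$circular), 0), 1)
  sm <- apply_psf(prof, sigma_bp, seq$circular)
  to_pixel_resolution(sm, bp_per_px, method = method,
                      circular = seq$circular, psf_sigma_bp = sigma_bp,
                      id = seq$id)
}

#' Write / read a barcode as TSV
#'
#' Plain-text format: `#`-prefixed header lines naming `bp_per_px`,
#' `psf_sigma_bp` and `circular`, then one intensity per line.
#'
#' @param bc a [barcode()].
#' @param path file path.
#' @return `write_barcode` returns `path` invisibly; `read_barcode` a
#'   [barcode()].
#' @export
write_barcode <- function(bc, path) {
  stopifnot(inherits(bc, "cb_barcode"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bp_per_px: %.10g", bc$bp_per_px),
               sprintf("# psf_sigma_bp: %.10g", bc$psf_sigma_bp),
               sprintf("# circular: %s", bc$circular),
               if (!is.null(bc$id)) sprintf("# id: %s", bc$id)), con)
  writeLines(sprintf("%.12g", bc$values), con)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(".*:", "", m[1]))
  }
  vals <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  barcode(vals,
          bp_per_px = as.numeric(get("bp_per_px")),
          psf_sigma_bp = as.numeric(get("psf_sigma_bp", "0")),
          circular = identical(get("circular", "FALSE"), "TRUE"),
          id = {
            id <- get("id", NA)
            if (is.na(id)) NULL else id
          })
}
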
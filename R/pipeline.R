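#' Scaffolding configuration
#'
#' Collects every tunable of the pipeline with the method's default values:
#' significance threshold `p_thresh = 0.01` (at most 1 percent
#' misallocations are accepted), `R = 1000` random barcodes per null fit,
#' PSF width `sigma_bp = 1000`, length threshold `l_thresh_bp = 12 *
#' sigma_bp` (barcodes shorter than a dozen PSF widths carry too little
#' spatial information), and pixel scale `bp_per_px = 500`.
#'
#' @param p_thresh p-value threshold in (0, 1).
#' @param sigma_bp PSF standard deviation, bp.
#' @param l_thresh_bp length threshold, bp; `NULL` means `12 * sigma_bp`.
#' @param bp_per_px pixel scale, bp.
#' @param R random barcodes per null fit.
#' @param seed master seed; all stochastic components derive substreams
#'   from it.
#' @param tol_px tolerance (pixels, circular distance) for calling a
#'   placement "correct" against a truth table.
#' @param max_mask_bits auction working-set guard, see
#'   [solve_auction_exact()].
#' @param ligands a [ligand_params()].
#' @param downsample `"interp"` or `"block"`, see [to_pixel_resolution()].
#' @param noise_sd,noise_corr_px synthetic-mode noise settings passed to
#'   [pseudo_experimental_barcode()] by the calibration drivers.
#' @return object of class `scaffold_config`.
#' @export
scaffold_config <- function(p_thresh = 0.01, sigma_bp = 1000,
                            l_thresh_bp = NULL, bp_per_px = 500,
                            R = 1000L, seed = 1L, tol_px = 5L,
                            max_mask_bits = 20L,
                            ligands = ligand_params(),
                            downsample = "interp",
                            noise_sd = 0.3, noise_corr_px = NULL) {
  stopifnot(p_thresh > 0, p_thresh < 1, sigma_bp >= 0, bp_per_px >= 1,
            R >= 1, tol_px >= 0)
  if (is.null(l_thresh_bp)) l_thresh_bp <- 12 * sigma_bp
  structure(list(p_thresh = p_thresh, sigma_bp = sigma_bp,
                 l_thresh_bp = l_thresh_bp, bp_per_px = bp_per_px,
                 R = as.integer(R), seed = as.integer(seed),
                 tol_px = as.integer(tol_px),
                 max_mask_bits = as.integer(max_mask_bits),
                 ligands = ligands, downsample = downsample,
                 noise_sd = noise_sd, noise_corr_px = noise_corr_px),
            class = "scaffold_config")
}

#' @export
print.scaffold_config <- function(x, ...) {
  cat(sprintf(paste0("<scaffold_config> p_thresh = %g, sigma = %g bp, ",
                     "l_thresh = %g bp, %g bp/px, R = %d, seed = %d\n"),
              x$p_thresh, x$sigma_bp, x$l_thresh_bp, x$bp_per_px, x$R,
              x$seed))
  invisible(x)
}

# One contig through steps 1-3: theory barcode, sliding scores, null fit
# (cached by length and rounded autocorrelation), p-values.
contig_steps123 <- function(contig, reference, config, null_cache, W_cache) {
  bc <- sequence_to_barcode(contig, config$ligands,
                            sigma_bp = config$sigma_bp,
                            bp_per_px = config$bp_per_px,
                            method = config$downsample)
  m <- bc$n_px
  if (m > reference$n_px)
    stop("contig '", contig$id, "' is longer than the reference barcode")
  Wk <- as.character(m)
  if (is.null(W_cache[[Wk]]))
    W_cache[[Wk]] <- reference_windows(reference, m)
  W <- W_cache[[Wk]]
  # The sample lag-1 estimate is biased low on short smooth series; the
  # optics guarantee at least the PSF-implied pixel correlation, so the
  # estimate is floored there (otherwise short-contig nulls are too rough
  # and their p-values anti-conservative).
  rho_psf <- exp(-(config$bp_per_px / config$sigma_bp)^2 / 4)
  rho <- round(max(estimate_autocorrelation(bc), rho_psf), 2)
  fit <- cache_get_or_fit(null_cache, m, rho, function(key) {
    X <- generate_random_barcodes(m, rho, config$R,
                                  seed = derive_seed(config$seed, key),
                                  method = "kernel")
    fit_null(max_scores_against(W, X), n_comparisons = 2 * reference$n_px,
             contig_len_px = m, corr_param = rho, r_used = config$R)
  })
  mt <- sliding_pearson(bc, reference, W = W)
  pv <- score_to_pvalue(mt$scores, fit)
  list(barcode = bc, match = mt,
       pvals = structure(list(contig_id = mt$contig_id, pvals = pv,
                              contig_len_px = m, x_max = reference$n_px),
                         class = "cb_pvaltable"),
       fit = fit, best = best_match(mt), p_min = min(pv))
}

#' Run the full contig-scaffolding pipeline
#'
#' Length filter, theory barcodes, sliding Pearson match scores, calibrated
#' p-values, placement bids, and non-overlapping placement by the exact
#' auction (or, with `method = "independent"`, each contig independently at
#' its best position subject only to the p-value threshold, as used in
#' per-contig calibration studies). Deterministic for a fixed config seed.
#'
#' @param contigs list of [dna_sequence()] records, a `cb_cutplan`, or a
#'   path to a FASTA file.
#' @param reference a circular [barcode()] or path to a barcode TSV.
#' @param config a [scaffold_config()].
#' @param truth optional truth table (data.frame with `contig_id`,
#'   `start_px`, `orientation`); taken from the cut plan if one is given.
#' @param null_cache optional shared [new_null_cache()] (must belong to this
#'   reference); speeds up repeated runs against one reference.
#' @param method `"auction"` (default) or `"independent"`.
#' @return object of class `scaffold_report`: fields `placements`,
#'   `total_score`, `occupied`, `filling_fraction`, `per_contig`
#'   (one row per input contig), `ratios` (when truth is available),
#'   `method`, `x_max`, `config`.
#' @export
run_scaffold <- function(contigs, reference, config = scaffold_config(),
                         truth = NULL, null_cache = NULL,
                         method = c("auction", "independent")) {
  method <- match.arg(method)
  if (inherits(contigs, "cb_cutplan")) {
    if (is.null(truth)) truth <- contigs$truth
    contigs <- contigs$contigs
  }
  if (is.character(contigs)) contigs <- read_contigs(contigs)
  if (inherits(contigs, "cb_sequence")) contigs <- list(contigs)
  if (is.character(reference)) reference <- read_barcode(reference)
  stopifnot(inherits(reference, "cb_barcode"), reference$circular)
  if (is.null(null_cache)) null_cache <- new_null_cache()
  W_cache <- new.env(parent = emptyenv())
  x_max <- reference$n_px

  filt <- length_filter(contigs, config$l_thresh_bp)
  ids_all <- vapply(contigs, `[[`, "", "id")
  lens_all <- vapply(contigs, seq_length, 0L)
  kept_ids <- vapply(filt$kept, `[[`, "", "id")

  res <- lapply(filt$kept, contig_steps123, reference = reference,
                config = config, null_cache = null_cache,
                W_cache = W_cache)
  names(res) <- kept_ids
  ptabs <- lapply(res, `[[`, "pvals")
  bids <- build_bids(ptabs, p_thresh = config$p_thresh)

  if (method == "auction") {
    sol <- solve_auction_exact(bids, x_max, circular = TRUE,
                               max_mask_bits = config$max_mask_bits)
  } else {
    rows <- integer(0)
    for (id in kept_ids) {
      r <- res[[id]]
      if (r$p_min < config$p_thresh) {
        cand <- which(bids$bidder == id &
                        bids$x_start == r$best$x_star &
                        bids$orientation == r$best$orientation)
        rows <- c(rows, cand[1L])
      }
    }
    occupied <- logical(x_max)
    for (r in rows)
      occupied[bid_pixels(bids$x_start[r], bids$x_end[r], x_max)] <- TRUE
    placements <- bids[rows, c("bidder", "x_start", "x_end", "length_px",
                               "orientation", "p_value", "score",
                               "wrapped")]
    rownames(placements) <- NULL
    sol <- structure(list(placements = placements,
                          total_score = sum(bids$score[rows]),
                          occupied = occupied, x_max = x_max),
                     class = "cb_placement")
  }

  n_all <- length(ids_all)
  pc <- data.frame(contig_id = ids_all, length_bp = lens_all,
                   length_px = rep(NA_integer_, n_all),
                   kept = ids_all %in% kept_ids,
                   c_hat = rep(NA_real_, n_all),
                   x_star = rep(NA_integer_, n_all),
                   orientation = rep(NA_character_, n_all),
                   p_min = rep(NA_real_, n_all),
                   placed = rep(FALSE, n_all),
                   placed_x = rep(NA_integer_, n_all),
                   placed_orientation = rep(NA_character_, n_all),
                   stringsAsFactors = FALSE)
  for (id in kept_ids) {
    i <- match(id, pc$contig_id)
    r <- res[[id]]
    pc$length_px[i] <- r$barcode$n_px
    pc$c_hat[i] <- r$best$c_hat
    pc$x_star[i] <- r$best$x_star
    pc$orientation[i] <- r$best$orientation
    pc$p_min[i] <- r$p_min
  }
  if (nrow(sol$placements)) {
    j <- match(sol$placements$bidder, pc$contig_id)
    pc$placed[j] <- TRUE
    pc$placed_x[j] <- sol$placements$x_start
    pc$placed_orientation[j] <- sol$placements$orientation
  }

  report <- structure(list(placements = sol$placements,
                           total_score = sol$total_score,
                           occupied = sol$occupied,
                           filling_fraction = mean(sol$occupied),
                           per_contig = pc, method = method,
                           x_max = x_max, truth = truth, config = config),
                      class = "scaffold_report")
  if (!is.null(truth))
    report$ratios <- correct_placement_ratio(report, truth,
                                             tol_px = config$tol_px)
  report
}

#' @export
print.scaffold_report <- function(x, ...) {
  pc <- x$per_contig
  cat(sprintf(paste0("<scaffold_report> %d contigs (%d pass the length ",
                     "filter), %d placed by %s; total score %.2f, filling ",
                     "fraction %.3f\n"),
              nrow(pc), sum(pc$kept), nrow(x$placements), x$method,
              x$total_score, x$filling_fraction))
  if (!is.null(x$ratios))
    cat(sprintf("  correct placements: %d / %d placed (%.1f%%)\n",
                x$ratios$n_correct, x$ratios$n_placed,
                100 * x$ratios$correct_over_placed))
  invisible(x)
}

#' @export
summary.scaffold_report <- function(object, ...) {
  print(object)
  if (nrow(object$placements)) {
    cat("\nPlacements:\n")
    print(object$placements)
  }
  invisible(object)
}

circular_distance <- function(a, b, n) {
  d <- abs(a - b) %% n
  pmin(d, n - d)
}

#' Filling fraction of a placement
#'
#' Number of occupied reference pixels divided by the total number of
#' pixels.
#'
#' @param solution a `cb_placement` or `scaffold_report`.
#' @param x_max reference length in pixels (taken from the object if
#'   missing).
#' @return fraction in \[0, 1\].
#' @export
filling_fraction <- function(solution, x_max = solution$x_max) {
  sum(solution$occupied) / x_max
}

#' Correct-placement ratios against a truth table
#'
#' A placed contig is "correct" when its orientation matches the truth and
#' its start pixel is within `tol_px` of the true start (circular
#' distance). Because the natural denominator is ambiguous, all three are
#' reported: correct over all contigs, over contigs passing the length
#' filter, and over placed contigs.
#'
#' @param report a `scaffold_report`.
#' @param truth data.frame with `contig_id`, `start_px`, `orientation`.
#' @param tol_px pixel tolerance (default 5).
#' @return list with `n_correct`, `n_placed`, `n_kept`, `n_all`,
#'   `correct_over_all`, `correct_over_kept`, `correct_over_placed`, and
#'   the logical `correct` flags aligned with `report$placements`.
#' @export
correct_placement_ratio <- function(report, truth = report$truth,
                                    tol_px = 5L) {
  if (is.null(truth)) stop("no truth table available")
  pl <- report$placements
  j <- match(pl$bidder, truth$contig_id)
  if (anyNA(j))
    stop("truth table is missing placed contig(s): ",
         paste(pl$bidder[is.na(j)], collapse = ", "))
  correct <- logical(nrow(pl))
  if (nrow(pl)) {
    d <- circular_distance(pl$x_start, truth$start_px[j], report$x_max)
    correct <- !is.na(truth$start_px[j]) & d <= tol_px &
      pl$orientation == truth$orientation[j]
  }
  n_placed <- nrow(pl)
  n_kept <- sum(report$per_contig$kept)
  n_all <- nrow(report$per_contig)
  list(n_correct = sum(correct), n_placed = n_placed, n_kept = n_kept,
       n_all = n_all,
       correct_over_all = if (n_all) sum(correct) / n_all else 0,
       correct_over_kept = if (n_kept) sum(correct) / n_kept else 0,
       correct_over_placed = if (n_placed) sum(correct) / n_placed else 0,
       correct = correct)
}

#' Export placements as JSON and/or BED-like TSV
#'
#' The TSV uses 1-based inclusive reference coordinates; intervals that
#' wrap around the circular origin are split into two rows flagged
#' `wrapped = TRUE`.
#'
#' @param report a `scaffold_report`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @export
write_placements <- function(report, json_path = NULL, tsv_path = NULL) {
  pl <- report$placements
  if (!is.null(json_path)) {
    obj <- list(placements = pl[, c("bidder", "x_start", "x_end",
                                    "orientation", "p_value", "score")],
                total_score = report$total_score,
                filling_fraction = report$filling_fraction,
                x_max = report$x_max)
    names(obj$placements)[1L] <- "contig_id"
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(tsv_path)) {
    rows <- list()
    for (i in seq_len(nrow(pl))) {
      if (pl$wrapped[i]) {
        rows[[length(rows) + 1L]] <-
          data.frame(contig_id = pl$bidder[i], start = pl$x_start[i],
                     end = report$x_max, orientation = pl$orientation[i],
                     p_value = pl$p_value[i], score = pl$score[i],
                     wrapped = TRUE)
        rows[[length(rows) + 1L]] <-
          data.frame(contig_id = pl$bidder[i], start = 1L,
                     end = pl$x_end[i], orientation = pl$orientation[i],
                     p_value = pl$p_value[i], score = pl$score[i],
                     wrapped = TRUE)
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(contig_id = pl$bidder[i], start = pl$x_start[i],
                     end = pl$x_end[i], orientation = pl$orientation[i],
                     p_value = pl$p_value[i], score = pl$score[i],
                     wrapped = FALSE)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(contig_id = character(0), start = integer(0),
                 end = integer(0), orientation = character(0),
                 p_value = numeric(0), score = numeric(0),
                 wrapped = logical(0))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
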
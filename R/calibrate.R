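#' Misallocation calibration on independently placed contigs
#'
#' Emulates the per-contig p-value validation protocol: cut fixed-length
#' contigs at uniformly random positions (and random orientation) from a
#' synthetic circular genome, build a pseudo-experimental reference barcode
#' for the same genome, and place each contig independently at its
#' best-scoring position subject only to the p-value threshold (no
#' auction). At `p_thresh = 0.01` the fraction of placements landing away
#' from the truth should be about 1 percent.
#'
#' @param genome_len_bp synthetic genome length (default 138 kbp).
#' @param contig_lens_bp contig lengths to draw (default 20/30/40 kbp).
#' @param n_per_len contigs per length (default 250).
#' @param config a [scaffold_config()]; the master seed, noise settings,
#'   optics and thresholds all come from here.
#' @param verbose print progress.
#' @return list with `per_length` (data.frame: length_bp, n, n_placed,
#'   n_misallocated), `n_placed`, `n_misallocated`,
#'   `misallocation_fraction` (among placements), `placed_fraction`.
#' @export
calibrate_misallocation <- function(genome_len_bp = 138000,
                                    contig_lens_bp = c(20000, 30000, 40000),
                                    n_per_len = 250L,
                                    config = scaffold_config(),
                                    verbose = FALSE) {
  seed <- config$seed
  genome <- random_genome(genome_len_bp, circular = TRUE,
                          seed = derive_seed(seed, "cal1-genome"),
                          id = "calib_genome")
  ref <- pseudo_experimental_barcode(genome, config$ligands,
                                     sigma_bp = config$sigma_bp,
                                     bp_per_px = config$bp_per_px,
                                     noise_sd = config$noise_sd,
                                     noise_corr_px = config$noise_corr_px,
                                     seed = derive_seed(seed, "cal1-noise"))
  cache <- new_null_cache()
  W_cache <- new.env(parent = emptyenv())
  doubled <- paste0(genome$bases, genome$bases)
  per <- list()
  for (len in contig_lens_bp) {
    set.seed(derive_seed(seed, paste0("cal1-cuts-", len)))
    starts <- sample.int(genome_len_bp, n_per_len, replace = TRUE)
    orients <- sample(c("forward", "flipped"), n_per_len, replace = TRUE)
    n_placed <- 0L
    n_mis <- 0L
    for (i in seq_len(n_per_len)) {
      sq <- dna_sequence(substr(doubled, starts[i], starts[i] + len - 1L),
                         id = sprintf("c%d_%d", len, i))
      if (orients[i] == "flipped") sq <- reverse_complement(sq)
      r <- contig_steps123(sq, ref, config, cache, W_cache)
      if (r$p_min < config$p_thresh) {
        n_placed <- n_placed + 1L
        true_px <- floor((starts[i] - 1L) / config$bp_per_px) + 1L
        ok <- r$best$orientation == orients[i] &&
          circular_distance(r$best$x_star, true_px, ref$n_px) <=
          config$tol_px
        if (!ok) n_mis <- n_mis + 1L
      }
    }
    if (verbose)
      message(sprintf("length %d bp: %d placed, %d misallocated", len,
                      n_placed, n_mis))
    per[[length(per) + 1L]] <- data.frame(length_bp = len, n = n_per_len,
                                          n_placed = n_placed,
                                          n_misallocated = n_mis)
  }
  per <- do.call(rbind, per)
  list(per_length = per, n_placed = sum(per$n_placed),
       n_misallocated = sum(per$n_misallocated),
       misallocation_fraction = if (sum(per$n_placed))
         sum(per$n_misallocated) / sum(per$n_placed) else 0,
       placed_fraction = sum(per$n_placed) / sum(per$n))
}

#' Pure-sample scaffolding calibration
#'
#' Emulates the pure-plasmid simulation study: cut one synthetic circular
#' genome with truncated-exponential spacing at several mean contig sizes,
#' run the full pipeline (auction included) against the genome's
#' pseudo-experimental barcode, and pool the correct-placement statistics
#' across replicates. The correct/placed ratio should sit near
#' `1 - p_thresh`, i.e. about 99 percent.
#'
#' @param genome_len_bp synthetic genome length (default 220 kbp).
#' @param mean_lens_bp mean contig sizes (default 10/24.5/40/80 kbp).
#' @param n_reps replicates per mean.
#' @param config a [scaffold_config()].
#' @param verbose print progress.
#' @return list with `per_mean` (data.frame: mean_len_bp, n_placed,
#'   n_correct, mean_filling), pooled `n_placed`, `n_correct`,
#'   `correct_over_placed`.
#' @export
calibrate_pure_scaffold <- function(genome_len_bp = 220000,
                                    mean_lens_bp = c(10000, 24500, 40000,
                                                     80000),
                                    n_reps = 30L,
                                    config = scaffold_config(),
                                    verbose = FALSE) {
  seed <- config$seed
  genome <- random_genome(genome_len_bp, circular = TRUE,
                          seed = derive_seed(seed, "cal2-genome"),
                          id = "pure_genome")
  ref <- pseudo_experimental_barcode(genome, config$ligands,
                                     sigma_bp = config$sigma_bp,
                                     bp_per_px = config$bp_per_px,
                                     noise_sd = config$noise_sd,
                                     noise_corr_px = config$noise_corr_px,
                                     seed = derive_seed(seed, "cal2-noise"))
  cache <- new_null_cache()
  per <- list()
  for (mu in mean_lens_bp) {
    np <- 0L; nc <- 0L; ff <- numeric(n_reps)
    for (rep in seq_len(n_reps)) {
      cp <- cut_contigs(genome, mu,
                        seed = derive_seed(seed,
                                           sprintf("cal2-%g-%d", mu, rep)),
                        bp_per_px = config$bp_per_px)
      rpt <- run_scaffold(cp, ref, config, null_cache = cache)
      np <- np + rpt$ratios$n_placed
      nc <- nc + rpt$ratios$n_correct
      ff[rep] <- rpt$filling_fraction
    }
    if (verbose)
      message(sprintf("mean %g bp: %d/%d correct, mean filling %.2f", mu,
                      nc, np, mean(ff)))
    per[[length(per) + 1L]] <- data.frame(mean_len_bp = mu, n_placed = np,
                                          n_correct = nc,
                                          mean_filling = mean(ff))
  }
  per <- do.call(rbind, per)
  list(per_mean = per, n_placed = sum(per$n_placed),
       n_correct = sum(per$n_correct),
       correct_over_placed = if (sum(per$n_placed))
         sum(per$n_correct) / sum(per$n_placed) else 0)
}

#' Foreign-contig rejection calibration
#'
#' Cuts contigs from a large unrelated genome and attempts to place each
#' independently on the plasmid stand-in reference (steps 1-3 only). Since
#' no foreign contig truly belongs, the fraction that passes the p-value
#' threshold measures the calibration of the null directly and should sit
#' near `p_thresh`.
#'
#' @param plasmid_len_bp plasmid stand-in length (default 220 kbp).
#' @param foreign_len_bp unrelated genome length (default 2 Mbp).
#' @param mean_lens_bp mean contig sizes for the cutting law.
#' @param n_reps_per_mean replicates per mean.
#' @param config a [scaffold_config()].
#' @param verbose print progress.
#' @return list with `per_rep` (data.frame: mean_len_bp, rep, n_kept,
#'   n_placed), pooled `n_kept`, `n_placed`, `placed_fraction`.
#' @export
calibrate_foreign_rejection <- function(plasmid_len_bp = 220000,
                                        foreign_len_bp = 2e6,
                                        mean_lens_bp = c(10000, 24500,
                                                         45000),
                                        n_reps_per_mean = 10L,
                                        config = scaffold_config(),
                                        verbose = FALSE) {
  seed <- config$seed
  plasmid <- random_genome(plasmid_len_bp, circular = TRUE,
                           seed = derive_seed(seed, "cal3-plasmid"),
                           id = "plasmid")
  ref <- pseudo_experimental_barcode(plasmid, config$ligands,
                                     sigma_bp = config$sigma_bp,
                                     bp_per_px = config$bp_per_px,
                                     noise_sd = config$noise_sd,
                                     noise_corr_px = config$noise_corr_px,
                                     seed = derive_seed(seed, "cal3-noise"))
  foreign <- random_genome(foreign_len_bp, circular = TRUE,
                           seed = derive_seed(seed, "cal3-foreign"),
                           id = "foreign")
  cache <- new_null_cache()
  W_cache <- new.env(parent = emptyenv())
  per <- list()
  for (mu in mean_lens_bp) {
    for (rep in seq_len(n_reps_per_mean)) {
      cp <- cut_contigs(foreign, mu,
                        seed = derive_seed(seed,
                                           sprintf("cal3-%g-%d", mu, rep)),
                        bp_per_px = config$bp_per_px,
                        provenance = "foreign")
      keep <- length_filter(cp$contigs, config$l_thresh_bp)$kept
      # foreign contigs can exceed the plasmid reference; those cannot bid
      keep <- keep[vapply(keep, seq_length, 0L) <=
                     plasmid_len_bp]
      n_placed <- 0L
      for (sq in keep) {
        r <- contig_steps123(sq, ref, config, cache, W_cache)
        if (r$p_min < config$p_thresh) n_placed <- n_placed + 1L
      }
      if (verbose)
        message(sprintf("mean %g bp rep %d: %d/%d placed", mu, rep,
                        n_placed, length(keep)))
      per[[length(per) + 1L]] <- data.frame(mean_len_bp = mu, rep = rep,
                                            n_kept = length(keep),
                                            n_placed = n_placed)
    }
  }
  per <- do.call(rbind, per)
  list(per_rep = per, n_kept = sum(per$n_kept),
       n_placed = sum(per$n_placed),
       placed_fraction = if (sum(per$n_kept))
         sum(per$n_placed) / sum(per$n_kept) else 0)
}
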
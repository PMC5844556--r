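#' Generate a random genome sequence
#'
#' I.i.d. bases with the requested GC content; a seeded stand-in for a
#' plasmid or chromosomal sequence in simulation studies.
#'
#' @param length_bp genome length in bp.
#' @param gc_content probability of G or C per base, in \[0, 1\].
#' @param circular logical (default TRUE: plasmids).
#' @param seed integer seed.
#' @param id record id.
#' @return a [dna_sequence()].
#' @export
random_genome <- function(length_bp, gc_content = 0.5, circular = TRUE,
                          seed = NULL, id = "genome") {
  stopifnot(length_bp >= 1, gc_content >= 0, gc_content <= 1)
  if (!is.null(seed)) set.seed(seed)
  draw <- sample.int(4L, length_bp, replace = TRUE,
                     prob = c((1 - gc_content) / 2, (1 - gc_content) / 2,
                              gc_content / 2, gc_content / 2))
  dna_sequence(intToUtf8(utf8ToInt("ATGC")[draw]), id = id,
               circular = circular)
}

# Exponential of mean mu truncated (censored) at cap: draws larger than
# the cap become the cap, leaving a point mass there — a fragment can be
# the whole molecule but never longer.
rtrunc_exp <- function(n, mu, cap) {
  pmin(-mu * log(runif(n)), cap)
}

#' Cut a genome into contigs with truncated-exponential spacing
#'
#' Emulates shotgun-assembly contig sets: successive inter-cut distances are
#' drawn from an exponential distribution of the given mean, truncated at
#' the genome length (contigs cannot be longer than the sequence itself).
#' Circular genomes get a uniformly random origin cut first. The resulting
#' contigs tile the genome exactly; each contig's orientation is randomized
#' (flipped contigs are stored reverse-complemented) and the truth table
#' records the original coordinates, start pixel and orientation.
#'
#' @param genome a [dna_sequence()].
#' @param mean_len_bp mean of the (untruncated) exponential, bp; the
#'   default 24.5 kbp is the scale of contig sizes in short-read
#'   assemblies of plasmid-bearing isolates.
#' @param seed integer seed.
#' @param bp_per_px pixel scale used to fill the `start_px` truth column.
#' @param provenance label stored in the truth table (e.g. `"plasmid"`).
#' @return object of class `cb_cutplan`: list with `genome_id`,
#'   `cut_positions` (bp), `contigs` (list of linear [dna_sequence()]) and
#'   `truth` (data.frame: contig_id, start_bp, end_bp, length_bp, start_px,
#'   orientation, provenance).
#' @export
cut_contigs <- function(genome, mean_len_bp = 24500, seed = NULL,
                        bp_per_px = 500, provenance = "plasmid") {
  stopifnot(inherits(genome, "cb_sequence"), mean_len_bp > 0)
  if (!is.null(seed)) set.seed(seed)
  L <- seq_length(genome)
  origin <- if (genome$circular) sample.int(L, 1L) else 0L
  rot <- if (origin > 0L)
    paste0(substr(genome$bases, origin + 1L, L),
           substr(genome$bases, 1L, origin))
  else genome$bases

  lens <- integer(0)
  total <- 0L
  while (total < L) {
    l <- max(1L, round(rtrunc_exp(1L, mean_len_bp, L)))
    if (total + l > L) l <- L - total
    lens <- c(lens, l)
    total <- total + l
  }
  starts_rot <- cumsum(c(0L, head(lens, -1L)))
  orient <- sample(c("forward", "flipped"), length(lens), replace = TRUE)
  start_bp <- mod1(origin + starts_rot + 1L, L)

  contigs <- vector("list", length(lens))
  truth <- data.frame(
    contig_id = sprintf("%s_c%03d", genome$id, seq_along(lens)),
    start_bp = start_bp,
    end_bp = mod1(origin + starts_rot + lens, L),
    length_bp = lens,
    start_px = as.integer(floor((start_bp - 1L) / bp_per_px)) + 1L,
    orientation = orient,
    provenance = provenance,
    stringsAsFactors = FALSE)
  for (i in seq_along(lens)) {
    b <- substr(rot, starts_rot[i] + 1L, starts_rot[i] + lens[i])
    sq <- dna_sequence(b, id = truth$contig_id[i], circular = FALSE)
    if (orient[i] == "flipped") sq <- reverse_complement(sq)
    contigs[[i]] <- sq
  }
  structure(list(genome_id = genome$id,
                 cut_positions = truth$start_bp,
                 contigs = contigs, truth = truth),
            class = "cb_cutplan")
}

#' @export
print.cb_cutplan <- function(x, ...) {
  cat(sprintf("<cb_cutplan> %s: %d contigs, lengths %d - %d bp\n",
              x$genome_id, length(x$contigs), min(x$truth$length_bp),
              max(x$truth$length_bp)))
  invisible(x)
}

#' Pseudo-experimental reference barcode
#'
#' Stand-in for a consensus barcode averaged from single-molecule
#' experiments: the theoretical barcode of the genome plus additive
#' stationary correlated Gaussian noise, z-normalized. The noise standard
#' deviation is in units of the z-normalized theory barcode; its lag-1
#' autocorrelation defaults to the value a white noise field acquires after
#' passing the same optical PSF, `exp(-(bp_per_px / sigma_bp)^2 / 4)`.
#'
#' @param genome a circular [dna_sequence()].
#' @param ligand_params a [ligand_params()].
#' @param sigma_bp,bp_per_px optics, as in [sequence_to_barcode()].
#' @param noise_sd noise standard deviation (0 gives the pure, z-normalized
#'   theory barcode).
#' @param noise_corr_px lag-1 autocorrelation of the noise in pixels;
#'   `NULL` uses the PSF-matched default above.
#' @param seed integer seed for the noise draw.
#' @return a circular [barcode()].
#' @export
pseudo_experimental_barcode <- function(genome,
                                        ligand_params = cbscaffold::ligand_params(),
                                        sigma_bp = 1000, bp_per_px = 500,
                                        noise_sd = 0.3,
                                        noise_corr_px = NULL, seed = NULL) {
  stopifnot(noise_sd >= 0)
  th <- sequence_to_barcode(genome, ligand_params, sigma_bp = sigma_bp,
                            bp_per_px = bp_per_px)
  v <- znorm(th$values)
  if (noise_sd > 0) {
    if (is.null(noise_corr_px))
      noise_corr_px <- exp(-(bp_per_px / sigma_bp)^2 / 4)
    noise <- generate_random_barcodes(th$n_px, noise_corr_px, 1L,
                                      seed = seed)[, 1L]
    v <- v + noise_sd * noise
  }
  barcode(znorm(v), bp_per_px = bp_per_px, psf_sigma_bp = sigma_bp,
          circular = TRUE, id = paste0(genome$id, "_pseudoexp"))
}

#' Mixed plasmid / chromosomal contig sample
#'
#' Cuts both a plasmid genome and a (much longer) unrelated "foreign"
#' genome with the same truncated-exponential law and pools the contigs,
#' keeping provenance labels so downstream placement can be scored for
#' foreign-contig rejection.
#'
#' @param plasmid_genome,foreign_genome [dna_sequence()] records.
#' @param mean_len_bp mean contig length, bp.
#' @param seed integer seed.
#' @param bp_per_px pixel scale for truth coordinates (plasmid only;
#'   foreign contigs get `start_px = NA`).
#' @return list with `contigs` (pooled list) and `truth` (row-bound truth
#'   table with `provenance` in `{"plasmid", "foreign"}`).
#' @export
mixed_sample <- function(plasmid_genome, foreign_genome,
                         mean_len_bp = 24500, seed = NULL,
                         bp_per_px = 500) {
  if (!is.null(seed)) set.seed(seed)
  cp <- cut_contigs(plasmid_genome, mean_len_bp, seed = NULL,
                    bp_per_px = bp_per_px, provenance = "plasmid")
  cf <- cut_contigs(foreign_genome, mean_len_bp, seed = NULL,
                    bp_per_px = bp_per_px, provenance = "foreign")
  cf$truth$start_px <- NA_integer_
  list(contigs = c(cp$contigs, cf$contigs),
       truth = rbind(cp$truth, cf$truth))
}

#' Write a truth table as TSV
#'
#' @param truth a truth data.frame (from [cut_contigs()] or
#'   [mixed_sample()]).
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
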
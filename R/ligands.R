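#' Ligand parameters for competitive-binding barcode theory
#'
#' Bundles everything the equilibrium model needs: the YOYO-1 binding
#' constant, the netropsin 4-mer binding-constant table, ligand footprints,
#' and the total concentrations of both ligands and of DNA basepairs.
#' Netropsin is AT-specific and non-fluorescent; where it outcompetes the
#' YOYO-1 dye the barcode is dark.
#'
#' The netropsin table is strand-symmetrized on construction: a 4-mer and
#' its reverse complement are assigned the mean of whatever values the input
#' lists for the pair (a bound ligand cannot distinguish strands). After
#' symmetrization the table must cover all 256 4-mers.
#'
#' @param netropsin_constants named numeric vector, names are 4-mers over
#'   ACGT, values are binding constants in 1/uM. Defaults to the bundled
#'   synthetic table (see [default_binding_constants()]).
#' @param K_yoyo YOYO-1 binding constant, 1/uM.
#' @param footprint_yoyo,footprint_netropsin ligand footprints in bp.
#' @param conc_yoyo_total,conc_netropsin_total total ligand concentrations, uM.
#' @param conc_dna total DNA concentration, uM basepairs.
#' @return object of class `cb_ligand_params`.
#' @export
ligand_params <- function(netropsin_constants = default_binding_constants(),
                          K_yoyo = 26,
                          footprint_yoyo = 4L, footprint_netropsin = 4L,
                          conc_yoyo_total = 0.5, conc_netropsin_total = 6,
                          conc_dna = 0.4) {
  stopifnot(K_yoyo >= 0, conc_yoyo_total >= 0, conc_netropsin_total >= 0,
            conc_dna >= 0, footprint_yoyo >= 1, footprint_netropsin >= 1)
  tab <- symmetrize_constants(netropsin_constants)
  structure(list(K_yoyo = K_yoyo,
                 netropsin_constants = tab,
                 footprint_yoyo = as.integer(footprint_yoyo),
                 footprint_netropsin = as.integer(footprint_netropsin),
                 conc_yoyo_total = conc_yoyo_total,
                 conc_netropsin_total = conc_netropsin_total,
                 conc_dna = conc_dna),
            class = "cb_ligand_params")
}

#' @export
print.cb_ligand_params <- function(x, ...) {
  cat(sprintf(paste0("<cb_ligand_params> K_yoyo = %g /uM, ",
                     "c_tot(YOYO) = %g uM, c_tot(netropsin) = %g uM, ",
                     "c(DNA) = %g uM bp\n"),
              x$K_yoyo, x$conc_yoyo_total, x$conc_netropsin_total,
              x$conc_dna))
  cat(sprintf("  netropsin table: %d 4-mers, range %.3g - %.3g /uM\n",
              length(x$netropsin_constants), min(x$netropsin_constants),
              max(x$netropsin_constants)))
  invisible(x)
}

all_kmers <- function(k = 4L) {
  b <- c("A", "C", "G", "T")
  do.call(paste0, rev(expand.grid(rep(list(b), k), stringsAsFactors = FALSE)))
}

symmetrize_constants <- function(tab) {
  if (is.null(names(tab)) || any(names(tab) == ""))
    stop("netropsin constants must be a named vector (names = 4-mers)")
  names(tab) <- toupper(names(tab))
  k <- unique(nchar(names(tab)))
  if (length(k) != 1L)
    stop("all netropsin table entries must have the same k-mer size")
  if (any(tab < 0)) stop("binding constants must be >= 0")
  kmers <- all_kmers(k)
  rc <- vapply(kmers, revcomp_bases, "")
  out <- setNames(rep(NA_real_, length(kmers)), kmers)
  for (i in seq_along(kmers)) {
    v <- tab[c(kmers[i], rc[i])]
    v <- v[!is.na(v)]
    if (length(v)) out[i] <- mean(v)
  }
  if (anyNA(out))
    stop("netropsin table does not cover all ", length(kmers), " ", k,
         "-mers after strand symmetrization; first missing: ",
         kmers[which(is.na(out))[1]])
  out
}

#' Read a ligand binding-constant table
#'
#' Plain-text dialect: one `4MER<TAB>constant` per line, `#` starts a
#' comment, blank lines ignored. Constants are in 1/uM.
#'
#' @param path file to read.
#' @return named numeric vector (not yet strand-symmetrized; that happens in
#'   [ligand_params()]).
#' @export
read_binding_constants <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed line in ", path, ": '", lines[bad][1], "'")
  vals <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(vals)) stop("non-numeric binding constant in ", path)
  setNames(vals, toupper(vapply(parts, `[[`, "", 1L)))
}

#' Bundled synthetic netropsin binding-constant table
#'
#' The package ships a synthetic default table
#' (`extdata/netropsin_constants_synthetic.tsv`) with AT-content-graded
#' constants: log-K increases linearly with the number of A/T bases in the
#' 4-mer, from 0.5/uM for all-GC to 150/uM for all-AT, reflecting
#' netropsin's strong preference for AT tracts. It is a documented
#' stand-in; replace it with a measured table via
#' [read_binding_constants()] for real analyses.
#'
#' @return named numeric vector of 256 constants, 1/uM.
#' @export
default_binding_constants <- function() {
  path <- system.file("extdata", "netropsin_constants_synthetic.tsv",
                      package = "cbscaffold", mustWork = TRUE)
  read_binding_constants(path)
}

# Per-position netropsin constants along a sequence: entry i is the
# table value for the 4-mer starting at basepair i (wrapping if circular).
# For linear sequences the trailing footprint-1 entries are set to 0; they
# correspond to no legal ligand start.
netropsin_site_constants <- function(seq, params) {
  tab <- params$netropsin_constants
  tabv <- unname(tab)  # symmetrize_constants emits canonical A<C<G<T order
  v <- base_codes(seq$bases) - 1L
  L <- length(v)
  k <- nchar(names(tab)[1L])
  if (!seq$circular && L < k)
    return(numeric(L))
  vx <- if (seq$circular) c(v, v[seq_len(k - 1L)]) else v
  idx <- rep(0, if (seq$circular) L else L - k + 1L)
  for (j in seq_len(k))
    idx <- idx * 4 + vx[seq_along(idx) + j - 1L]
  out <- numeric(L)
  out[seq_along(idx)] <- unname(tabv[idx + 1L])
  out
}
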
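#' DNA sequence record
#'
#' Light-weight container for a DNA sequence: the unit that is cut into
#' contigs and converted into theoretical barcodes. Only the unambiguous
#' alphabet ACGT is accepted; ambiguity codes are rejected by default or,
#' optionally, resolved by seeded uniform resampling from the compatible
#' bases (see [read_contigs()]).
#'
#' @param bases character scalar over A/C/G/T (case-insensitive).
#' @param id record identifier.
#' @param circular is the molecule circular (plasmid/genome) rather than a
#'   linear fragment?
#' @return an object of class `cb_sequence`: a list with fields `id`,
#'   `bases`, `circular`.
#' @export
dna_sequence <- function(bases, id = "seq", circular = FALSE) {
  bases <- toupper(as.character(bases))
  if (length(bases) != 1L || nchar(bases) < 1L)
    stop("'bases' must be a single non-empty string")
  if (grepl("[^ACGT]", bases))
    stop("sequence '", id, "' contains characters outside ACGT")
  structure(list(id = as.character(id), bases = bases,
                 circular = isTRUE(circular)),
            class = "cb_sequence")
}

#' @export
print.cb_sequence <- function(x, ...) {
  cat(sprintf("<cb_sequence> %s: %d bp, %s\n", x$id, nchar(x$bases),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

seq_length <- function(seq) nchar(seq$bases)

# Reverse complement of a plain ACGT string.
revcomp_bases <- function(bases) {
  chartr("ACGT", "TGCA",
         intToUtf8(rev(utf8ToInt(bases))))
}

reverse_complement <- function(seq) {
  out <- seq
  out$bases <- revcomp_bases(seq$bases)
  out
}

IUPAC_CHOICES <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

#' Read contig sequences from a FASTA file
#'
#' @param path FASTA file (multi-record; record ids preserved).
#' @param circular logical, recycled over records.
#' @param ambiguity `"reject"` (default) errors on non-ACGT bases;
#'   `"sample"` replaces each ambiguity code by a base drawn uniformly from
#'   its compatible set, reproducibly from `seed`.
#' @param seed integer seed used only when `ambiguity = "sample"`.
#' @return list of [dna_sequence()] records.
#' @export
read_contigs <- function(path, circular = FALSE,
                         ambiguity = c("reject", "sample"), seed = 1L) {
  ambiguity <- match.arg(ambiguity)
  set <- Biostrings::readDNAStringSet(path)
  circular <- rep_len(circular, length(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    b <- toupper(as.character(set[[i]]))
    if (grepl("[^ACGT]", b)) {
      if (ambiguity == "reject")
        stop("record '", names(set)[i], "' contains non-ACGT characters; ",
             "use ambiguity = \"sample\" to resolve them")
      ch <- strsplit(b, "", fixed = TRUE)[[1]]
      bad <- which(!ch %in% c("A", "C", "G", "T"))
      set.seed(derive_seed(seed, names(set)[i]))
      for (j in bad) {
        opts <- IUPAC_CHOICES[[ch[j]]]
        if (is.null(opts)) stop("unknown base '", ch[j], "'")
        ch[j] <- opts[sample.int(length(opts), 1L)]
      }
      b <- paste(ch, collapse = "")
    }
    out[[i]] <- dna_sequence(b, id = names(set)[i], circular = circular[i])
  }
  out
}

#' Write sequence records to FASTA
#'
#' @param seqs a `cb_sequence` or list of them.
#' @param path output file.
#' @export
write_contigs <- function(seqs, path) {
  if (inherits(seqs, "cb_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "bases"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Integer codes 1..4 for A,C,G,T; errors on anything else.
base_codes <- function(bases) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  v <- code[utf8ToInt(bases)]
  if (any(v == 0L)) stop("sequence contains characters outside ACGT")
  v
}
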
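#' @name seq-utils
#' @title Small nucleotide sequence utilities
#' @description Internal helpers shared by the simulators and the HSP
#'   aligner: 2-bit-style integer encoding, reverse complement, random
#'   sequence generation, FASTA IO via Biostrings.
#' @keywords internal
NULL

BASES <- c("A", "C", "G", "T")

# A=0 C=1 G=2 T=3, any other IUPAC character (N, R, Y, S, W, ...) => 4.
# The aligner treats 4 as "never seed, always mismatch".
.encode_dna <- function(seq) {
  x <- utf8ToInt(toupper(seq))
  out <- rep.int(4L, length(x))
  out[x == 65L] <- 0L # A
  out[x == 67L] <- 1L # C
  out[x == 71L] <- 2L # G
  out[x == 84L] <- 3L # T
  out
}

.revcomp <- function(seq) {
  chartr("ACGTacgtRYKMrykm", "TGCAtgcaYRMKyrmk",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Read a genome from FASTA, concatenating multi-record files
#'
#' Multiple records (e.g. a chromosome plus plasmids) are concatenated into a
#' single [genome_record()] so whole-genome statistics and pairwise distances
#' operate on the full replicon set.
#'
#' @param path path to a (possibly multi-record) FASTA file
#' @param id optional identifier; defaults to the first record's name
#' @return a `genome_record`
#' @export
read_genome_fasta <- function(path, id = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  seq <- paste(vapply(seq_along(set), function(i) as.character(set[[i]]), ""),
               collapse = "")
  if (is.null(id)) id <- sub("\\s.*$", "", names(set)[1])
  genome_record(id, seq)
}

#' Write one or more genome records to FASTA
#'
#' @param genomes a `genome_record` or list of them
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a genome record
#'
#' A named nucleotide sequence with its length; the basic currency of the
#' distance and statistics modules.
#'
#' @param id replicon or genome identifier
#' @param seq nucleotide sequence (character scalar, IUPAC alphabet)
#' @param topology optional topology tag (e.g. "circular")
#' @return an object of class `genome_record` with fields `id`, `seq`,
#'   `length`, `topology`
#' @export
genome_record <- function(id, seq, topology = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  structure(list(id = id, seq = toupper(seq), length = nchar(seq),
                 topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp\n", x$id,
              format(x$length, big.mark = ",")))
  invisible(x)
}
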
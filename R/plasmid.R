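#' Plasmid sequence with an annotated gene region
#'
#' Container for a plasmid (or any template) sequence held as the
#' non-template strand in 5'->3' orientation, together with the inclusive
#' gene region \[b, e\] (1-based internal coordinates) on which all k-mer
#' analysis and prediction operate.
#'
#' @param name Identifier (matched against the BED `chrom` column).
#' @param seq Nucleotide string over A/C/G/T (ambiguity codes rejected).
#' @param gene_start,gene_end Inclusive 1-based bounds of the gene region;
#'   defaults to the whole sequence.
#' @return An object of class `plasmid_sequence`: a list with elements
#'   `name`, `seq`, `gene_start`, `gene_end`.
#' @examples
#' plasmid_sequence("p", "ACGTACGTACGT", 2, 11)
#' @export
plasmid_sequence <- function(name, seq, gene_start = 1L, gene_end = nchar(seq)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- stringr::str_locate(seq, "[^ACGT]")[1, "start"]
  if (!is.na(bad)) {
    stop("sequence for '", name, "' contains non-ACGT character '",
         substr(seq, bad, bad), "' at position ", bad, call. = FALSE)
  }
  gene_start <- as.integer(gene_start)
  gene_end <- as.integer(gene_end)
  if (!(gene_start >= 1L && gene_start < gene_end && gene_end <= nchar(seq))) {
    stop("gene region must satisfy 1 <= b < e <= length(seq)", call. = FALSE)
  }
  structure(
    list(name = name, seq = seq, gene_start = gene_start, gene_end = gene_end),
    class = "plasmid_sequence"
  )
}

#' @export
print.plasmid_sequence <- function(x, ...) {
  cat("<plasmid_sequence> ", x$name, ": ", nchar(x$seq), " nt, gene region [",
      x$gene_start, ", ", x$gene_end, "] (",
      x$gene_end - x$gene_start + 1L, " nt)\n", sep = "")
  invisible(x)
}

#' Read a plasmid sequence from FASTA
#'
#' Sequence files for SMRF-seq plasmids are distributed as the template
#' strand 5'->3'; the grammar operates on the non-template strand. With
#' `strand = "template"` the record is reverse-complemented on read so the
#' stored sequence is always non-template 5'->3'.
#'
#' @param path FASTA file (single- or multi-record).
#' @param record Record name or index to load (default first).
#' @param strand Orientation of the sequence *in the file*.
#' @param gene_start,gene_end Gene region in coordinates of the stored
#'   (non-template) sequence; defaults to the whole record.
#' @return A [plasmid_sequence()].
#' @export
read_plasmid_fasta <- function(path, record = 1L,
                               strand = c("non_template", "template"),
                               gene_start = NULL, gene_end = NULL) {
  strand <- match.arg(strand)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (is.character(record)) {
    idx <- match(record, names(set))
    if (is.na(idx)) stop("FASTA record '", record, "' not found in ", path,
                         call. = FALSE)
  } else {
    idx <- as.integer(record)
    if (idx < 1L || idx > length(set)) stop("FASTA record index out of range",
                                            call. = FALSE)
  }
  x <- set[[idx]]
  if (strand == "template") x <- Biostrings::reverseComplement(x)
  nm <- sub("\\s.*$", "", names(set)[idx])
  seq <- as.character(x)
  plasmid_sequence(nm, seq,
                   gene_start %||% 1L,
                   gene_end %||% nchar(seq))
}

#' Write a plasmid sequence to FASTA (non-template strand as stored)
#' @param plasmid A [plasmid_sequence()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_plasmid_fasta <- function(plasmid, path) {
  x <- Biostrings::DNAStringSet(plasmid$seq)
  names(x) <- plasmid$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# All-4^k named vector of overlapping k-mer occurrence counts m_s over the
# gene region [b, e] of the non-template strand.
gene_kmer_counts <- function(plasmid, k) {
  gene <- substr(plasmid$seq, plasmid$gene_start, plasmid$gene_end)
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(gene), width = k)
}
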
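#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that keeps only the first
#' whitespace-delimited token of each header as the sequence name.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return a `DNAStringSet`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) iso_abort(paste0("no such file: ", path), "io")
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences 5'->3' (reverse-complemented on the minus
#' strand) and returns an uppercase character string.
#'
#' @inheritParams coords
#' @param genome a named `DNAStringSet` (see [read_genome()]) or a named
#'   character vector of chromosome sequences.
#' @export
spliced_sequence <- function(models, transcript_id, genome) {
  t <- tx_row(models, transcript_id)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!(t$chrom %in% names(genome))) {
    iso_abort(paste0("chromosome not in genome: ", t$chrom), "lookup")
  }
  ex <- tx_exons(models, transcript_id)
  chrom_seq <- as.character(genome[[t$chrom]])
  if (max(ex$end) > nchar(chrom_seq)) {
    iso_abort(paste0("exon beyond end of chromosome ", t$chrom), "lookup")
  }
  s <- paste0(substring(chrom_seq, ex$start + 1L, ex$end), collapse = "")
  if (t$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  toupper(s)
}
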
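## Six-frame translation with coordinate maps.  Stops are retained as '*'
## (pseudogene evidence must survive to the curation stage) and codons
## containing N translate to 'X'.

.translate_nt <- function(nt) {
  n <- nchar(nt)
  n <- n - n %% 3L
  if (n < 3L) return("")
  as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE)))
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames are keyed `"+0"`, `"+1"`, `"+2"` (plus strand offsets) and
#' `"-0"`, `"-1"`, `"-2"` (offsets on the reverse complement).  Each entry
#' carries the information needed to map any peptide position back to
#' 1-based inclusive genomic coordinates via [frame_codon_locus()].
#'
#' @param seq A nucleotide sequence (character scalar over `ACGTN`).
#' @return A named list of six entries, each `list(strand, frame, peptide)`.
#' @export
translate_six_frames <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  rc <- if (L) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  } else {
    ""
  }
  out <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") seq else rc
    for (f in 0:2) {
      pep <- if (L > f) .translate_nt(substr(src, f + 1L, L)) else ""
      out[[paste0(strand, f)]] <- list(strand = strand, frame = f,
                                       peptide = pep)
    }
  }
  out
}

#' Map peptide positions in a translation frame back to coordinates
#'
#' Returns the 1-based inclusive nucleotide span, on the original (plus
#' strand) coordinate system, of the codons encoding peptide positions
#' `p_start..p_end` of the given frame.
#'
#' @param strand `"+"` or `"-"`.
#' @param frame Frame offset 0, 1 or 2.
#' @param p_start,p_end Peptide positions (1-based).
#' @param seq_len Length of the translated nucleotide sequence.
#' @return `c(start, end)` in original coordinates.
#' @export
frame_codon_locus <- function(strand, frame, p_start, p_end, seq_len) {
  stopifnot(p_start >= 1L, p_end >= p_start)
  nt1 <- frame + 3L * (p_start - 1L) + 1L
  nt2 <- frame + 3L * p_end
  if (strand == "+") {
    c(nt1, nt2)
  } else {
    c(seq_len - nt2 + 1L, seq_len - nt1 + 1L)
  }
}

.revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}
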
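## Readers/writers for external formats and the 1-based inclusive coordinate
## model shared by every module.  All coordinates in this package are 1-based
## and inclusive, matching GFF3 and the family-table location strings.

#' Read a FASTA file
#'
#' Identifiers are truncated at the first whitespace and must be unique;
#' sequences are uppercased.  In nucleotide mode `U` is normalized to `T`.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"`, `"protein"`, or `"auto"` (guess from residue content).
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  stopifnot(file.exists(path))
  if (file.size(path) == 0L ||
      !any(startsWith(trimws(readLines(path, n = 50L)), ">"))) {
    warning("empty FASTA file: ", path)
    return(if (type == "protein") Biostrings::AAStringSet()
           else Biostrings::DNAStringSet())
  }
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  if (type == "auto") {
    letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    nuc <- c("A", "C", "G", "T", "U", "N", "-")
    type <- if (all(letters_used %in% nuc)) "dna" else "protein"
  }
  if (type == "dna") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    out <- Biostrings::DNAStringSet(seqs)
  } else {
    out <- Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x A named `XStringSet` or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    x <- Biostrings::BStringSet(x)
  }
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Parse a family-table location string into a genomic locus
#'
#' Accepts the dialects used in the curated family table:
#' `chrom:start.end`, `chrom:start-end`, with optional spaces around the
#' separator (e.g. `"Bd2:14220256.14222873"`, `"Bd2: 52664751 - 52666466"`).
#' Coordinates are 1-based inclusive.  The table records no strand, so
#' strand defaults to `"+"`.  Reversed coordinates (end < start, a known
#' misprint class) are normalized to (min, max) with a warning.
#'
#' @param text A location string.
#' @return A one-row data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
parse_locus_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^\\s*([A-Za-z0-9_.]+)\\s*:\\s*([0-9]+)\\s*[.-]\\s*([0-9]+)\\s*$", text))[[1]]
  if (length(m) != 4L) {
    stop("malformed locus string: '", text, "'")
  }
  start <- as.numeric(m[3L])
  end <- as.numeric(m[4L])
  if (start < 1) stop("malformed locus string (start < 1): '", text, "'")
  if (end < start) {
    warning("reversed coordinates in '", text, "'; normalizing to (min, max)")
    tmp <- start
    start <- end
    end <- tmp
  }
  data.frame(chrom = m[2L], start = start, end = end, strand = "+",
             stringsAsFactors = FALSE)
}

#' Extract a genomic region, optionally with flanking sequence
#'
#' Returns the sequence of `[start - flank, end + flank]` clipped to the
#' chromosome bounds; minus-strand loci are reverse complemented.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param chrom,start,end,strand Locus (1-based inclusive).
#' @param flank Extra basepairs on each side (clipped, never padded).
#' @return A character scalar.
#' @export
extract_region <- function(genome, chrom, start, end, strand = "+", flank = 0) {
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: ", chrom)
  }
  stopifnot(start >= 1, end >= start, strand %in% c("+", "-"), flank >= 0)
  L <- length(genome[[chrom]])
  s <- max(1, start - flank)
  e <- min(L, end + flank)
  seg <- Biostrings::subseq(genome[[chrom]], s, e)
  if (strand == "-") {
    seg <- Biostrings::reverseComplement(seg)
  }
  as.character(seg)
}

## ---- GFF3 gene models -------------------------------------------------

#' Read gene models from GFF3
#'
#' Builds one gene model per `mRNA` feature; its `CDS` children become exons
#' sorted in transcription order (descending genomic start on the minus
#' strand).  Phase is taken from GFF column 8.  `CDS` features without a
#' parent are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of gene models; each is a list with elements
#'   `model_id`, `chrom`, `start`, `end`, `strand` and `exons` (a data.frame
#'   with `start`, `end`, `phase` in transcription order).
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  is_mrna <- as.character(gr$type) %in% c("mRNA", "transcript")
  is_cds <- as.character(gr$type) == "CDS"
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p)) as.character(p[[1L]]) else NA_character_
  }, character(1L))
  orphan <- is_cds & is.na(parents)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without a parent skipped")
  }
  models <- list()
  for (i in which(is_mrna)) {
    id <- as.character(gr$ID[i])
    kids <- which(is_cds & !is.na(parents) & parents == id)
    if (!length(kids)) next
    ex <- data.frame(
      start = GenomicRanges::start(gr)[kids],
      end = GenomicRanges::end(gr)[kids],
      phase = as.integer(as.character(gr$phase[kids])),
      stringsAsFactors = FALSE
    )
    strand <- as.character(GenomicRanges::strand(gr)[i])
    ex <- ex[order(ex$start, decreasing = (strand == "-")), , drop = FALSE]
    rownames(ex) <- NULL
    models[[id]] <- list(
      model_id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      start = GenomicRanges::start(gr)[i],
      end = GenomicRanges::end(gr)[i],
      strand = strand,
      exons = ex
    )
  }
  models
}

#' Write gene models to GFF3
#'
#' Emits a `gene`/`mRNA`/`CDS` hierarchy compatible with [read_gff3()].
#'
#' @param models A list of gene models as returned by [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    gid <- paste0(m$model_id, ".gene")
    lines <- c(lines,
      paste(m$chrom, "wrkyminer", "gene", m$start, m$end, ".", m$strand, ".",
            paste0("ID=", gid), sep = "\t"),
      paste(m$chrom, "wrkyminer", "mRNA", m$start, m$end, ".", m$strand, ".",
            paste0("ID=", m$model_id, ";Parent=", gid), sep = "\t"))
    for (k in seq_len(nrow(m$exons))) {
      lines <- c(lines,
        paste(m$chrom, "wrkyminer", "CDS",
              m$exons$start[k], m$exons$end[k], ".", m$strand,
              m$exons$phase[k],
              paste0("ID=", m$model_id, ".cds", k, ";Parent=", m$model_id),
              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Translate the spliced CDS of a gene model
#'
#' Exons are concatenated in transcription order, the phase of the first
#' exon is applied, and the result is translated with stops retained as
#' `*` (a trailing stop is dropped).
#'
#' @param model A gene model (see [read_gff3()]).
#' @param genome A named [Biostrings::DNAStringSet].
#' @return The predicted protein as a character scalar.
#' @export
model_protein <- function(model, genome) {
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  segs <- vapply(seq_len(nrow(ex)), function(k) {
    extract_region(genome, model$chrom, ex$start[k], ex$end[k], "+")
  }, character(1L))
  cds <- paste(segs, collapse = "")
  if (model$strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  ph <- model$exons$phase[1L]
  if (is.na(ph)) ph <- 0L
  if (ph > 0L) cds <- substr(cds, ph + 1L, nchar(cds))
  prot <- .translate_nt(cds)
  sub("\\*$", "", prot)
}
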
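# Shared fixtures and independent oracles used across the suite.

# random background chromosome as a DNAStringSet
random_genome <- function(len, name = "chrT", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    name))
}

# implant a nucleotide sequence into a background chromosome at `pos`
# (1-based position of the first implanted base); minus strand implants the
# reverse complement
implant <- function(genome, nt, pos, strand = "+") {
  chrom <- names(genome)[1L]
  s <- as.character(genome[[chrom]])
  if (strand == "-") {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  }
  stopifnot(pos >= 1L, pos + nchar(nt) - 1L <= nchar(s))
  substr(s, pos, pos + nchar(nt) - 1L) <- nt
  out <- Biostrings::DNAStringSet(setNames(s, chrom))
  out
}

# naive reverse translation with one fixed codon per residue (test-local,
# independent of the generator's sampled codons)
fixed_revtrans <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  tab <- vapply(split(names(gc), unname(gc)), `[`, character(1L), 1L)
  paste(tab[strsplit(pep, "")[[1L]]], collapse = "")
}

# least-squares branch lengths of a fixed topology against a distance
# matrix; returns the residual sum of squares.  Used to enumerate all
# topologies as a brute-force oracle for NJ.
ls_residual <- function(tree, D) {
  n <- length(tree$tip.label)
  pairs <- t(combn(n, 2L))
  E <- nrow(tree$edge)
  A <- matrix(0, nrow(pairs), E)
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]
    j <- pairs[r, 2L]
    np <- ape::nodepath(tree, i, j)
    for (k in seq_len(length(np) - 1L)) {
      e <- which((tree$edge[, 1L] == np[k] & tree$edge[, 2L] == np[k + 1L]) |
                   (tree$edge[, 2L] == np[k] & tree$edge[, 1L] == np[k + 1L]))
      A[r, e] <- 1
    }
    d[r] <- D[tree$tip.label[i], tree$tip.label[j]]
  }
  fit <- qr.coef(qr(A), d)
  fit[is.na(fit)] <- 0
  sum((A %*% fit - d)^2)
}

# an alignment of k clean pairs: members of a pair are nearly identical,
# different pairs are unrelated
clean_pair_alignment <- function(k = 4L, ncol = 60L, seed = 5L) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  # a conserved backbone shared by every clade keeps all pairwise
  # p-distances strictly below saturation, as in real domain alignments
  backbone <- strsplit("WRKYGQKCHH", "")[[1L]]
  rows <- character(0)
  for (p in seq_len(k)) {
    proto <- c(backbone, sample(aa, ncol - length(backbone), replace = TRUE))
    for (m in 1:2) {
      v <- proto
      flip <- sample(seq(length(backbone) + 1L, ncol), 1L)
      v[flip] <- sample(setdiff(aa, v[flip]), 1L)
      rows[paste0("t", p, m)] <- paste(v, collapse = "")
    }
  }
  rows
}

# move a gene model's predicted start codon by `delta` bp (transcription
# sense: positive = further upstream), preserving frame
shift_model_start <- function(model, delta) {
  stopifnot(delta %% 3 == 0)
  if (model$strand == "+") {
    model$exons$start[1L] <- model$exons$start[1L] - delta
    model$start <- min(model$start, model$exons$start[1L])
  } else {
    model$exons$end[1L] <- model$exons$end[1L] + delta
    model$end <- max(model$end, model$exons$end[1L])
  }
  model
}
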
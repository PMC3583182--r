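## Subfamily assignment, pseudogene flagging and gene-model auditing -
## the machine-checkable form of the family's manual-curation rules.
##
## Classification cascade: two complete domains -> I; C2HC finger -> III;
## IIab intron + C2H2 -> {IIa, IIb}; PR intron + C2H2 -> {IIc, IId, IIe}.
## The groups sharing intron class and finger type are split by tree
## placement when available, else by nearest labeled reference domain
## (reported as ambiguous).

#' Pair Group I N- and C-terminal domains into loci
#'
#' Two same-strand domains within `pair_max_gap` bp, where the domain
#' upstream in transcription order is intronless (the N-terminal domain)
#' and the downstream one carries the PR intron (the C-terminal domain),
#' form one two-domain locus.  An intronless complete domain followed by an
#' incomplete fragment is also paired (truncated C-domain: a pseudogene
#' candidate).  All other hits become one-domain loci.
#'
#' @param hits A merged hit data.frame from [scan_genome()].
#' @param config A [scan_config()].
#' @return A data.frame of loci: `locus_name`, footprint coordinates,
#'   `n_domains`, `complete`, and per-domain columns `d1_*`/`d2_*` (d1 is
#'   the 5'-most domain in transcription order).  Scalar convenience
#'   columns `intron_class`, `finger_type`, `finger_extension`, `peptide`
#'   describe the classification-bearing domain.
#' @export
pair_group1_domains <- function(hits, config = scan_config()) {
  dom_cols <- c("start", "end", "strand", "exon1_start", "exon1_end",
                "exon2_start", "exon2_end", "intron_class", "peptide",
                "heptapeptide", "finger_type", "finger_extension",
                "complete", "stop_broken", "frame", "score")
  loci <- list()
  if (nrow(hits)) {
    hits <- hits[order(hits$chrom, hits$start), , drop = FALSE]
    used <- rep(FALSE, nrow(hits))
    for (i in seq_len(nrow(hits))) {
      if (used[i]) next
      j <- if (i < nrow(hits)) i + 1L else NA_integer_
      pair <- FALSE
      if (!is.na(j) && !used[j] &&
          hits$chrom[j] == hits$chrom[i] &&
          hits$strand[j] == hits$strand[i] &&
          hits$start[j] - hits$end[i] <= config$pair_max_gap) {
        # transcription order: left hit is 5' on '+', 3' on '-'
        up <- if (hits$strand[i] == "+") i else j
        dn <- if (hits$strand[i] == "+") j else i
        n_ok <- hits$complete[up] && hits$intron_class[up] == "NONE"
        c_ok <- (hits$complete[dn] && hits$intron_class[dn] == "PR") ||
          !hits$complete[dn]
        pair <- n_ok && c_ok
      }
      if (pair) {
        up <- if (hits$strand[i] == "+") i else j
        dn <- if (hits$strand[i] == "+") j else i
        row <- list(chrom = hits$chrom[i],
                    start = min(hits$start[c(i, j)]),
                    end = max(hits$end[c(i, j)]),
                    strand = hits$strand[i], n_domains = 2L,
                    complete = hits$complete[up] && hits$complete[dn])
        for (k in dom_cols) {
          row[[paste0("d1_", k)]] <- hits[[k]][up]
          row[[paste0("d2_", k)]] <- hits[[k]][dn]
        }
        cls <- dn  # the C-terminal (intron-bearing) domain is informative
        used[c(i, j)] <- TRUE
      } else {
        row <- list(chrom = hits$chrom[i], start = hits$start[i],
                    end = hits$end[i], strand = hits$strand[i],
                    n_domains = 1L, complete = hits$complete[i])
        for (k in dom_cols) {
          row[[paste0("d1_", k)]] <- hits[[k]][i]
          row[[paste0("d2_", k)]] <- hits[[k]][i][NA]
        }
        cls <- i
        used[i] <- TRUE
      }
      row$intron_class <- hits$intron_class[cls]
      row$finger_type <- hits$finger_type[cls]
      row$finger_extension <- hits$finger_extension[cls]
      row$peptide <- hits$peptide[cls]
      row$score <- hits$score[cls]
      loci[[length(loci) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  if (!length(loci)) {
    base <- data.frame(locus_name = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), n_domains = integer(0),
                       complete = logical(0), stringsAsFactors = FALSE)
    eh <- .empty_hits()
    for (p in c("d1_", "d2_")) for (k in dom_cols) base[[paste0(p, k)]] <- eh[[k]]
    base$intron_class <- character(0)
    base$finger_type <- character(0)
    base$finger_extension <- integer(0)
    base$peptide <- character(0)
    base$score <- numeric(0)
    return(base)
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(locus_name = sprintf("locus_%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.ref_label <- function(ref_names) sub("[._].*$", "", ref_names)

.nearest_reference <- function(peptide, references, labels, config) {
  mat <- .substitution_matrix(config)
  sc <- Biostrings::pairwiseAlignment(
    pattern = references, subject = peptide, type = "local",
    substitutionMatrix = mat, gapOpening = config$gap_opening,
    gapExtension = config$gap_extension, scoreOnly = TRUE)
  labels[which.max(sc)]
}

#' Assign WRKY subfamilies to loci
#'
#' Applies the structural decision cascade, then resolves the
#' structure-degenerate groups ({IIa, IIb} and {IIc, IId, IIe}) by tree
#' placement when supplied, else by nearest labeled reference domain
#' (confidence `"ambiguous"`).  Loci without a complete domain are
#' `UNASSIGNED`.
#'
#' @param loci Output of [pair_group1_domains()].
#' @param references Optional named [Biostrings::AAStringSet] of reference
#'   domains; names start with the subfamily label (e.g. `"IIc"`,
#'   `"IIc.BdWRKY2"`).
#' @param placements Optional named character vector mapping `locus_name`
#'   to a clade label from a phylogenetic placement
#'   (see [placements_from_tree()]).
#' @param config A [scan_config()].
#' @return `loci` with added columns `subfamily`, `evidence`
#'   (comma-separated), `confidence` (`rule`, `tree-confirmed`,
#'   `ambiguous`).
#' @export
assign_subfamily <- function(loci, references = NULL, placements = NULL,
                             config = scan_config()) {
  if (!is.null(references)) references <- .as_queries(references)
  labels <- if (!is.null(references)) .ref_label(names(references))
  sub <- ev <- conf <- character(nrow(loci))
  resolve <- function(i, candidates, base_ev) {
    pl <- if (!is.null(placements)) placements[loci$locus_name[i]] else NA
    if (!is.na(pl) && pl %in% candidates) {
      list(sub = unname(pl), ev = c(base_ev, "TREE_CLADE"),
           conf = "tree-confirmed")
    } else if (!is.null(references) && any(labels %in% candidates)) {
      keep <- labels %in% candidates
      list(sub = .nearest_reference(loci$peptide[i], references[keep],
                                    labels[keep], config),
           ev = base_ev, conf = "ambiguous")
    } else {
      list(sub = "UNASSIGNED", ev = base_ev, conf = "ambiguous")
    }
  }
  for (i in seq_len(nrow(loci))) {
    if (!loci$complete[i]) {
      sub[i] <- "UNASSIGNED"
      ev[i] <- ""
      conf[i] <- "rule"
      next
    }
    if (loci$n_domains[i] == 2L) {
      sub[i] <- "I"
      e <- c("TWO_DOMAINS",
             if (loci$intron_class[i] == "PR") "INTRON_PR")
      pl <- if (!is.null(placements)) placements[loci$locus_name[i]] else NA
      if (!is.na(pl) && identical(unname(pl), "I")) {
        e <- c(e, "TREE_CLADE")
        conf[i] <- "tree-confirmed"
      } else {
        conf[i] <- "rule"
      }
      ev[i] <- paste(e, collapse = ",")
      next
    }
    if (loci$finger_type[i] == "C2HC") {
      sub[i] <- "III"
      e <- c("FINGER_C2HC", if (loci$intron_class[i] == "PR") "INTRON_PR")
      conf[i] <- "rule"
      ev[i] <- paste(e, collapse = ",")
      next
    }
    base <- c("FINGER_C2H2",
              switch(loci$intron_class[i], PR = "INTRON_PR",
                     IIab = "INTRON_IIAB", NULL))
    cands <- switch(loci$intron_class[i],
                    IIab = c("IIa", "IIb"),
                    PR = c("IIc", "IId", "IIe"),
                    c("I", "IIa", "IIb", "IIc", "IId", "IIe"))
    r <- resolve(i, cands, base)
    sub[i] <- r$sub
    ev[i] <- paste(r$ev, collapse = ",")
    conf[i] <- r$conf
  }
  loci$subfamily <- sub
  loci$evidence <- ev
  loci$confidence <- conf
  loci
}

# search for a complete zinc finger downstream of the domain's first half,
# in all three reading frames - frameshift evidence.  Stops are not
# truncated: a frameshifted finger reads correctly in its own frame even
# when codons upstream of the shift are garbled.  Only consulted when the
# defect is not already explained by in-frame stops.
.downstream_finger <- function(genome, chrom, from, to, strand, config,
                               window = 1500L) {
  L <- length(genome[[chrom]])
  if (strand == "+") {
    s <- max(1L, from)
    e <- min(L, from + window)
  } else {
    e <- min(L, to)
    s <- max(1L, to - window)
  }
  if (s > e) return(FALSE)
  oriented <- extract_region(genome, chrom, s, e, strand)
  for (f in 0:2) {
    pep <- .translate_nt(substr(oriented, f + 1L, nchar(oriented)))
    if (nchar(pep) >= 30L &&
        !is.null(.find_finger(pep, 1L, config, to = nchar(pep)))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Collect pseudogene evidence for scanned loci
#'
#' Evidence classes: `PARTIAL_DOMAIN` (no complete domain reconstructable),
#' `INTERNAL_STOP` (`*` inside the best domain reading), `FRAMESHIFT`
#' (domain halves complete only in different frames with no sanctioned
#' intron), `ADJACENT_TRANSPOSON` (a supplied repeat annotation overlaps
#' within 2 kb; never set when no annotation is given).  Complete loci
#' receive an empty evidence set.
#'
#' @param loci Output of [pair_group1_domains()].
#' @param genome A named [Biostrings::DNAStringSet].
#' @param repeats Optional repeat annotation data.frame
#'   (`chrom`, `start`, `end`).
#' @param config A [scan_config()].
#' @return `loci` with added columns `pseudogene` (logical) and
#'   `pseudogene_evidence` (comma-separated).
#' @export
flag_pseudogene <- function(loci, genome, repeats = NULL,
                            config = scan_config()) {
  genome <- .as_genome(genome)
  evs <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (loci$complete[i]) next
    ev <- "PARTIAL_DOMAIN"
    # the incomplete domain of the locus (d2 when a complete N-domain was
    # paired with a truncated partner, else d1)
    d <- if (loci$n_domains[i] == 2L && !isTRUE(loci$d2_complete[i])) {
      "d2_"
    } else {
      "d1_"
    }
    if (isTRUE(loci[[paste0(d, "stop_broken")]][i])) {
      ev <- c(ev, "INTERNAL_STOP")
    } else if (.downstream_finger(
        genome, loci$chrom[i], loci[[paste0(d, "exon1_start")]][i],
        loci[[paste0(d, "exon1_end")]][i],
        loci$strand[i], config)) {
      ev <- c(ev, "FRAMESHIFT")
    }
    if (!is.null(repeats) && nrow(repeats)) {
      near <- repeats$chrom == loci$chrom[i] &
        repeats$start <= loci$end[i] + 2000L &
        repeats$end >= loci$start[i] - 2000L
      if (any(near)) ev <- c(ev, "ADJACENT_TRANSPOSON")
    }
    evs[i] <- paste(ev, collapse = ",")
  }
  loci$pseudogene <- nzchar(evs)
  loci$pseudogene_evidence <- evs
  loci
}

#' Audit gene models against domain evidence
#'
#' For each locus: no overlapping model means `missing`; an overlapping
#' model whose spliced CDS translation contains every complete domain
#' peptide of the locus is a `match` regardless of start-codon differences
#' (shifted ATG predictions are tolerated by construction), or `short` when
#' that protein is shorter than `min_protein_len`; an overlapping model
#' whose CDS does not encode a complete domain that the genome supports is
#' `mispredicted`.  Loci without a complete domain cannot contradict a
#' model and audit as `match` when covered.
#'
#' @param loci Output of [pair_group1_domains()] (optionally passed through
#'   [flag_pseudogene()]).
#' @param models Gene models from [read_gff3()].
#' @param genome A named [Biostrings::DNAStringSet].
#' @param config A [scan_config()].
#' @return A data.frame of audit reports: `locus_name`, coordinates,
#'   `model_id` (`NA` when missing), `status`
#'   (`match`/`mispredicted`/`missing`/`short`), `pseudogene`,
#'   `pseudogene_evidence`.
#' @export
audit_gene_models <- function(loci, models, genome, config = scan_config()) {
  genome <- .as_genome(genome)
  n <- nrow(loci)
  status <- character(n)
  model_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cand <- Filter(function(m) {
      m$chrom == loci$chrom[i] &&
        m$start <= loci$end[i] && m$end >= loci$start[i]
    }, models)
    if (!length(cand)) {
      status[i] <- "missing"
      next
    }
    need <- character(0)
    if (isTRUE(loci$d1_complete[i])) need <- c(need, loci$d1_peptide[i])
    if (loci$n_domains[i] == 2L && isTRUE(loci$d2_complete[i])) {
      need <- c(need, loci$d2_peptide[i])
    }
    if (!length(need)) {
      # incomplete locus: an overlapping model is not contradicted
      status[i] <- "match"
      model_id[i] <- cand[[1L]]$model_id
      next
    }
    found <- FALSE
    for (m in cand) {
      prot <- model_protein(m, genome)
      if (all(vapply(need, function(p) grepl(p, prot, fixed = TRUE),
                     logical(1L)))) {
        found <- TRUE
        model_id[i] <- m$model_id
        plen <- nchar(gsub("*", "", prot, fixed = TRUE))
        status[i] <- if (plen < config$min_protein_len) "short" else "match"
        break
      }
    }
    if (!found) {
      status[i] <- "mispredicted"
      model_id[i] <- cand[[1L]]$model_id
    }
  }
  data.frame(
    locus_name = loci$locus_name, chrom = loci$chrom, start = loci$start,
    end = loci$end, strand = loci$strand, model_id = model_id,
    status = status,
    subfamily = loci$subfamily %||% rep("UNASSIGNED", n),
    pseudogene = loci$pseudogene %||% rep(FALSE, n),
    pseudogene_evidence = loci$pseudogene_evidence %||% rep("", n),
    stringsAsFactors = FALSE)
}

#' Summarize a family table or audit output
#'
#' Works on curated family records (see [read_family_table()]) or audit
#' reports (see [audit_gene_models()]).  `n_flagged` counts mispredicted
#' plus missing records (disjoint by construction).
#'
#' @param records A data.frame of family records or audit reports.
#' @return A list of class `wrky_family_summary`: `total`, `per_subfamily`,
#'   `n_mispredicted`, `n_missing`, `n_flagged`, `n_pseudogenes`, `n_short`.
#' @export
summarize_family <- function(records) {
  if ("model_status" %in% names(records)) {
    st <- records$model_status
    mis <- sum(st == "incorrect")
    abs_ <- sum(st == "absent")
    sho <- sum(st == "short")
  } else if ("status" %in% names(records)) {
    st <- records$status
    mis <- sum(st == "mispredicted")
    abs_ <- sum(st == "missing")
    sho <- sum(st == "short")
  } else {
    stop("records must carry a 'model_status' or 'status' column")
  }
  sub <- if ("subfamily" %in% names(records)) records$subfamily else
    character(0)
  per <- vapply(.SUBFAMILIES, function(s) sum(sub == s), integer(1L))
  structure(list(
    total = nrow(records),
    per_subfamily = per,
    n_mispredicted = mis,
    n_missing = abs_,
    n_flagged = mis + abs_,
    n_pseudogenes = sum(records$pseudogene %||% logical(0)),
    n_short = sho
  ), class = "wrky_family_summary")
}

#' @export
print.wrky_family_summary <- function(x, ...) {
  cat("WRKY family summary\n")
  cat("  total loci:        ", x$total, "\n")
  cat("  per subfamily:     ",
      paste(sprintf("%s=%d", names(x$per_subfamily), x$per_subfamily),
            collapse = " "), "\n")
  cat("  mispredicted:      ", x$n_mispredicted, "\n")
  cat("  missing model:     ", x$n_missing, "\n")
  cat("  flagged (either):  ", x$n_flagged, "\n")
  cat("  pseudogenes:       ", x$n_pseudogenes, "\n")
  cat("  short models:      ", x$n_short, "\n")
  invisible(x)
}
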
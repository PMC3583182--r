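## Exhaustive, splice-aware discovery of WRKY-domain-encoding loci.
## Strategy (recall-first, mirroring a permissive translated search):
##   1. seed_search: Smith-Waterman of every query against all six reading
##      frames of every chromosome, permissive threshold, nothing filtered
##      for completeness;
##   2. reconstruct_spliced_domain: around each seed, complete the domain
##      either within one frame or by splicing a GT..AG intron at one of the
##      two sanctioned positions (immediately after the invariant PR
##      dipeptide, or five residues after the second cysteine of a C-X5-C);
##   3. merge_hits: pool and de-duplicate overlapping footprints.

.as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  genome
}

.as_queries <- function(queries) {
  if (is.character(queries)) queries <- Biostrings::AAStringSet(queries)
  stopifnot(is(queries, "AAStringSet"))
  if (length(queries) == 0L) stop("empty query set")
  stopifnot(!is.null(names(queries)), all(nzchar(names(queries))))
  queries
}

.empty_seeds <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0),
             query_id = character(0), score = numeric(0),
             aligned_peptide = character(0), stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0),
             exon1_start = integer(0), exon1_end = integer(0),
             exon2_start = integer(0), exon2_end = integer(0),
             intron_class = character(0), peptide = character(0),
             heptapeptide = character(0), finger_type = character(0),
             finger_extension = integer(0), complete = logical(0),
             stop_broken = logical(0), score = numeric(0),
             query_id = character(0), stringsAsFactors = FALSE)
}

.self_score <- function(q, mat) {
  ch <- strsplit(q, "")[[1]]
  sum(mat[cbind(ch, ch)])
}

#' Seed a translated search of the genome with protein queries
#'
#' Local (Smith-Waterman) alignment of each query against all six reading
#' frames of each chromosome, windowed for scale.  Every alignment scoring
#' at least the configured permissive threshold is reported; seeds are not
#' filtered for domain completeness at this stage.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or named character).
#' @param queries A named [Biostrings::AAStringSet] of representative WRKY
#'   domains, one or more per subfamily.
#' @param config A [scan_config()].
#' @return A data.frame of seeds: `chrom`, `start`, `end`, `strand`,
#'   `frame`, `query_id`, `score`, `aligned_peptide`.
#' @export
seed_search <- function(genome, queries, config = scan_config()) {
  genome <- .as_genome(genome)
  queries <- .as_queries(queries)
  mat <- .substitution_matrix(config)
  qchr <- as.character(queries)
  thr <- vapply(qchr, function(q) {
    config$min_seed_score %||% (config$min_seed_score_frac * .self_score(q, mat))
  }, numeric(1L))
  rows <- list()
  for (chrom in names(genome)) {
    seqchar <- as.character(genome[[chrom]])
    L <- nchar(seqchar)
    frames <- translate_six_frames(seqchar)
    for (fr in frames) {
      pep <- fr$peptide
      np <- nchar(pep)
      if (np < 10L) next
      step <- config$window_aa - config$window_overlap
      wstarts <- seq(1L, max(1L, np - config$window_overlap), by = step)
      wins <- Biostrings::AAStringSet(substring(
        pep, wstarts, pmin(wstarts + config$window_aa - 1L, np)))
      for (qi in seq_along(queries)) {
        sc <- Biostrings::pairwiseAlignment(
          pattern = wins, subject = queries[[qi]], type = "local",
          substitutionMatrix = mat, gapOpening = config$gap_opening,
          gapExtension = config$gap_extension, scoreOnly = TRUE)
        sel <- which(sc >= thr[qi])
        if (!length(sel)) next
        aln <- Biostrings::pairwiseAlignment(
          pattern = wins[sel], subject = queries[[qi]], type = "local",
          substitutionMatrix = mat, gapOpening = config$gap_opening,
          gapExtension = config$gap_extension)
        p1 <- wstarts[sel] + Biostrings::start(Biostrings::pattern(aln)) - 1L
        p2 <- wstarts[sel] + Biostrings::end(Biostrings::pattern(aln)) - 1L
        apep <- gsub("-", "", as.character(Biostrings::pattern(aln)),
                     fixed = TRUE)
        for (k in seq_along(sel)) {
          loc <- frame_codon_locus(fr$strand, fr$frame, p1[k], p2[k], L)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = loc[1L], end = loc[2L],
            strand = fr$strand, frame = fr$frame,
            query_id = names(queries)[qi], score = sc[sel[k]],
            aligned_peptide = apep[k], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(.empty_seeds())
  seeds <- do.call(rbind, rows)
  # window overlap can report one alignment twice
  seeds <- seeds[!duplicated(seeds[c("chrom", "start", "end", "strand",
                                     "query_id")]), , drop = FALSE]
  seeds <- seeds[order(seeds$chrom, seeds$start, seeds$strand,
                       -seeds$score, seeds$query_id), , drop = FALSE]
  rownames(seeds) <- NULL
  seeds
}

# acceptor positions a such that W[a-1..a] == "AG" and the implied intron
# [dnt, a] is within configured length bounds
.acceptor_positions <- function(W, dnt, config) {
  lo <- dnt + config$min_intron_len - 1L
  hi <- min(nchar(W), dnt + config$max_intron_len - 1L)
  if (lo > hi) return(integer(0))
  region <- substr(W, lo - 1L, hi)  # include one char before for AG spanning
  p <- gregexpr("AG", region, fixed = TRUE)[[1L]]
  if (p[1L] == -1L) return(integer(0))
  a <- (lo - 2L) + as.integer(p) + 1L
  a[a >= lo & a <= hi]
}

#' Reconstruct a (possibly intron-split) WRKY domain around a seed
#'
#' Attempts to complete the domain within a single reading frame; failing
#' that, searches for a canonical `GT..AG` intron at exactly the two
#' sanctioned positions - immediately after the invariant `PR` codons, or
#' at the codon boundary five residues after the second cysteine of a
#' `C-X5-C` - such that the spliced translation completes the domain.  The
#' splice yielding the highest-scoring complete domain wins.  If nothing
#' completes, the best-scoring incomplete reading is returned (candidate
#' pseudogene) rather than silently dropped.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param seed One seed (a one-row data.frame from [seed_search()]).
#' @param queries The query set used for seeding (for candidate scoring).
#' @param config A [scan_config()].
#' @return A one-row data.frame in the hit schema (see [scan_genome()]).
#' @export
reconstruct_spliced_domain <- function(genome, seed, queries,
                                       config = scan_config()) {
  genome <- .as_genome(genome)
  queries <- .as_queries(queries)
  mat <- .substitution_matrix(config)
  seed <- as.list(seed)
  chrom_seq <- as.character(genome[[seed$chrom]])
  L <- nchar(chrom_seq)
  ws <- max(1L, seed$start - config$max_intron_len - 400L)
  we <- min(L, seed$end + config$max_intron_len + 400L)
  W <- substr(chrom_seq, ws, we)
  if (seed$strand == "-") W <- .revcomp(W)
  n <- nchar(W)
  to_local <- function(g) if (seed$strand == "+") g - ws + 1L else we - g + 1L
  to_genomic <- function(l) if (seed$strand == "+") ws + l - 1L else we - l + 1L
  seed_local <- sort(c(to_local(seed$start), to_local(seed$end)))
  query <- as.character(queries[[seed$query_id]])

  # all three frame translations, computed once; spliced peptides are read
  # straight out of them (the acceptor fixes the downstream frame)
  P3 <- vapply(0:2, function(f) .translate_nt(substr(W, f + 1L, n)),
               character(1L))
  pep_from <- function(nt_start, n_res) {
    f2 <- (nt_start - 1L) %% 3L
    idx <- (nt_start - 1L - f2) / 3L + 1L
    substr(P3[f2 + 1L], idx, idx + n_res - 1L)
  }
  complete_cands <- list()
  incomplete_cands <- list()
  add <- function(complete, intron_class, peptide, heptapeptide, finger_type,
                  finger_extension, e1, e2, frame, ilen,
                  stop_broken = FALSE) {
    cand <- list(
      complete = complete, intron_class = intron_class, peptide = peptide,
      heptapeptide = heptapeptide, finger_type = finger_type,
      finger_extension = finger_extension, e1 = e1, e2 = e2, frame = frame,
      ilen = ilen, stop_broken = stop_broken)
    if (complete) {
      complete_cands[[length(complete_cands) + 1L]] <<- cand
    } else {
      incomplete_cands[[length(incomplete_cands) + 1L]] <<- cand
    }
  }
  # does the reading complete a finger once in-frame stops are ignored?
  # (then the stop is the only defect: INTERNAL_STOP pseudogene evidence)
  stops_only_defect <- function(reading) {
    if (!grepl("*", reading, fixed = TRUE)) return(FALSE)
    !is.null(.find_finger(gsub("*", "O", reading, fixed = TRUE), 8L, config))
  }

  for (f in 0:2) {
    P <- P3[f + 1L]
    if (!nzchar(P)) next
    hep <- .find_hepta(P, config)
    for (i in seq_len(nrow(hep))) {
      h <- hep$pos[i]
      hnt <- f + 3L * (h - 1L) + 1L
      # the heptapeptide may sit up to one intron upstream of a finger-side
      # seed, but never downstream of the seed footprint
      if (hnt < seed_local[1L] - config$max_intron_len - 60L ||
          hnt > seed_local[2L] + 60L) next
      rest <- substr(P, h, min(nchar(P), h + 220L))
      stop_at <- regexpr("*", rest, fixed = TRUE)
      eff <- if (stop_at > 0L) substr(rest, 1L, stop_at - 1L) else rest
      fng <- if (nchar(eff) >= 8L) .find_finger(eff, 8L, config) else NULL
      if (!is.null(fng)) {
        # domain completes without any intron
        add(TRUE, "NONE", substr(rest, 1L, fng$end), hep$variant[i],
            fng$type, fng$extension,
            c(hnt, f + 3L * (h + fng$end - 1L)), NULL, f, 0L)
        next
      }
      # single-frame probe reading (candidate pseudogene evidence)
      add(FALSE, "NONE", substr(rest, 1L, 76L), hep$variant[i],
          "INCOMPLETE", 0L,
          c(hnt, min(n, f + 3L * (h + min(nchar(rest), 76L) - 1L))),
          NULL, f, 0L, stop_broken = stops_only_defect(rest))
      # sanctioned splice positions: collect donor anchors within exon1
      anchors <- list()
      ne <- nchar(eff)
      if (ne >= 9L) {
        for (k in 8L:min(ne - 1L, 7L + config$pr_search_window)) {
          if (substr(eff, k, k + 1L) == "PR") {
            anchors[[length(anchors) + 1L]] <-
              list(class = "PR", last_res = h + k)  # the R of PR
          }
        }
        for (k in 8L:min(ne - 11L, 7L + config$hepta_finger_gap)) {
          if (substr(eff, k, k) == "C" && substr(eff, k + 6L, k + 6L) == "C") {
            anchors[[length(anchors) + 1L]] <-
              list(class = "IIab", last_res = h + k - 1L + 11L)
          }
        }
      }
      for (an in anchors) {
        exon1_pep <- substr(P, h, an$last_res)
        if (grepl("*", exon1_pep, fixed = TRUE)) next
        dnt <- f + 3L * an$last_res + 1L
        if (dnt + 1L > n || substr(W, dnt, dnt + 1L) != "GT") next
        for (a in .acceptor_positions(W, dnt, config)) {
          if (a + 3L > n) next
          pep2 <- pep_from(a + 1L, 64L)
          if (!nzchar(pep2)) next
          full <- paste0(exon1_pep, pep2)
          stop_at2 <- regexpr("*", full, fixed = TRUE)
          eff2 <- if (stop_at2 > 0L) substr(full, 1L, stop_at2 - 1L) else full
          fng2 <- if (nchar(eff2) >= 8L) .find_finger(eff2, 8L, config) else NULL
          if (!is.null(fng2) && fng2$end > nchar(exon1_pep)) {
            n2 <- fng2$end - nchar(exon1_pep)
            add(TRUE, an$class, substr(full, 1L, fng2$end), hep$variant[i],
                fng2$type, fng2$extension,
                c(hnt, dnt - 1L), c(a + 1L, a + 3L * n2), f,
                a - dnt + 1L)
          } else {
            # retain the spliced reading as pseudogene evidence (e.g. an
            # in-frame stop inside the finger)
            n2p <- min(nchar(pep2), 44L)
            add(FALSE, an$class, substr(full, 1L,
                                        nchar(exon1_pep) + n2p),
                hep$variant[i], "INCOMPLETE", 0L,
                c(hnt, dnt - 1L), c(a + 1L, a + 3L * n2p), f,
                a - dnt + 1L, stop_broken = stops_only_defect(full))
          }
        }
      }
    }
  }

  # a structural completion must also look like the query: chance splices
  # onto random acceptors can satisfy the finger grammar but align poorly
  score_of <- function(cands) {
    peps <- vapply(cands, `[[`, character(1L), "peptide")
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(peps), subject = query,
      type = "local", substitutionMatrix = mat,
      gapOpening = config$gap_opening, gapExtension = config$gap_extension,
      scoreOnly = TRUE)
  }
  guard <- config$min_complete_score_frac * .self_score(query, mat)
  all_cands <- c(complete_cands, incomplete_cands)
  if (!length(all_cands)) {
    # no heptapeptide near the seed: report the raw seed as an incomplete
    # fragment (e.g. a finger-only pseudogene remnant)
    return(data.frame(
      chrom = seed$chrom, start = seed$start, end = seed$end,
      strand = seed$strand, frame = seed$frame,
      exon1_start = seed$start, exon1_end = seed$end,
      exon2_start = NA_integer_, exon2_end = NA_integer_,
      intron_class = "NONE", peptide = seed$aligned_peptide,
      heptapeptide = NA_character_, finger_type = "INCOMPLETE",
      finger_extension = 0L, complete = FALSE, stop_broken = FALSE,
      score = seed$score, query_id = seed$query_id,
      stringsAsFactors = FALSE))
  }

  # choose the best reading independently for each heptapeptide anchor
  # (frame + position): a window can hold several domains, and a spurious
  # long-range splice from one gene must not shadow its neighbor
  sc_all <- score_of(all_cands)
  keys <- vapply(all_cands, function(x) paste0(x$frame, ":", x$e1[1L]),
                 character(1L))
  rows <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    cands <- all_cands[idx]
    scores <- sc_all[idx]
    comp <- vapply(cands, `[[`, logical(1L), "complete")
    ilen <- vapply(cands, `[[`, numeric(1L), "ilen")
    baseline <- if (any(!comp & ilen == 0)) {
      max(scores[!comp & ilen == 0])
    } else {
      0
    }
    ok <- comp & scores >= guard &
      (ilen == 0 | scores >= baseline + config$min_splice_gain)
    if (!any(ok) && any(!comp)) {
      # no trustworthy completion: demote any chance completions and keep
      # the best incomplete reading as pseudogene evidence
      keep <- !comp
      cands <- cands[keep]
      scores <- scores[keep]
    } else if (!any(ok)) {
      cands <- lapply(cands, function(x) {
        x$complete <- FALSE
        x$finger_type <- "INCOMPLETE"
        x
      })
    } else {
      cands <- cands[ok]
      scores <- scores[ok]
    }
    comp <- vapply(cands, `[[`, logical(1L), "complete")
    sbrk <- vapply(cands, `[[`, logical(1L), "stop_broken")
    ilen <- vapply(cands, `[[`, numeric(1L), "ilen")
    best <- order(-comp, -scores, -sbrk, ilen)[1L]
    b <- cands[[best]]
    if (!b$complete && !b$stop_broken && !is.null(b$e2)) {
      # the splice was never validated; keep the evidence peptide but do
      # not report speculative exon coordinates
      b$e2 <- NULL
      b$intron_class <- "NONE"
    }
    g1 <- sort(c(to_genomic(b$e1[1L]), to_genomic(b$e1[2L])))
    if (!is.null(b$e2)) {
      g2 <- sort(c(to_genomic(b$e2[1L]), to_genomic(b$e2[2L])))
      span <- range(c(g1, g2))
    } else {
      g2 <- c(NA_integer_, NA_integer_)
      span <- g1
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = seed$chrom, start = span[1L], end = span[2L],
      strand = seed$strand, frame = b$frame,
      exon1_start = g1[1L], exon1_end = g1[2L],
      exon2_start = g2[1L], exon2_end = g2[2L],
      intron_class = b$intron_class, peptide = b$peptide,
      heptapeptide = b$heptapeptide, finger_type = b$finger_type,
      finger_extension = b$finger_extension, complete = b$complete,
      stop_broken = b$stop_broken, score = as.numeric(scores[best]),
      query_id = seed$query_id, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Merge overlapping domain hits into a non-redundant set
#'
#' Hits anchored at the same domain start - overlapping first-exon
#' (heptapeptide-side) footprints on the same strand - are merged, keeping
#' the most complete then highest-scoring representative.  Anchoring on
#' the first exon rather than the full footprint keeps a long-range
#' spliced reading from one gene from swallowing an unrelated neighbor
#' inside its putative intron.  Output is sorted by (chrom, start).
#'
#' @param hits A data.frame of hits (see [scan_genome()]).
#' @return The non-redundant subset, re-sorted.
#' @export
merge_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$exon1_start,
                                                hits$exon1_end),
                               strand = hits$strand)
  red <- GenomicRanges::reduce(gr)
  grp <- GenomicRanges::findOverlaps(gr, red, select = "first")
  keep <- vapply(split(seq_len(nrow(hits)), grp), function(idx) {
    idx[order(-hits$complete[idx], -hits$score[idx], hits$start[idx])][1L]
  }, integer(1L))
  out <- hits[sort(keep), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a genome for WRKY-domain-encoding loci
#'
#' Composition of [seed_search()], [reconstruct_spliced_domain()] (applied
#' to one representative seed per overlapping seed cluster) and
#' [merge_hits()].  Deterministic given identical inputs and configuration.
#'
#' @inheritParams seed_search
#' @return A data.frame of domain hits with columns `chrom`, `start`, `end`,
#'   `strand`, `frame`, `exon1_start`, `exon1_end`, `exon2_start`,
#'   `exon2_end` (`NA` for single-exon domains), `intron_class` (`PR`,
#'   `IIab`, `NONE`), `peptide`, `heptapeptide`, `finger_type`,
#'   `finger_extension`, `complete`, `score`, `query_id`.
#' @export
scan_genome <- function(genome, queries, config = scan_config()) {
  genome <- .as_genome(genome)
  queries <- .as_queries(queries)
  seeds <- seed_search(genome, queries, config)
  if (!nrow(seeds)) return(.empty_hits())
  gr <- GenomicRanges::GRanges(seeds$chrom,
                               IRanges::IRanges(seeds$start, seeds$end),
                               strand = seeds$strand)
  red <- GenomicRanges::reduce(gr)
  grp <- GenomicRanges::findOverlaps(gr, red, select = "first")
  reps <- vapply(split(seq_len(nrow(seeds)), grp), function(idx) {
    idx[order(-seeds$score[idx], seeds$start[idx], seeds$query_id[idx])][1L]
  }, integer(1L))
  hits <- do.call(rbind, lapply(sort(reps), function(i) {
    reconstruct_spliced_domain(genome, seeds[i, , drop = FALSE], queries,
                               config)
  }))
  merge_hits(hits)
}
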
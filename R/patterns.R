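## The WRKY domain pattern engine: heptapeptide variants followed, within a
## bounded window, by a zinc finger.  Finger spacing specs follow the
## canonical WRKY literature values:
##   C2H2:  C-x(4,5)-C-x(22,24)-H-x(1)-H   (Groups I and II)
##   C2HC:  C-x(7)-C-x(22,24)-H-x(1)-C     (Group III)
## An extra 9-10 residue spacer inside the finger (between the second C and
## the first H) is tolerated and reported as `finger_extension`.

#' Scanner configuration
#'
#' @param min_seed_score Absolute Smith-Waterman score threshold for seeds;
#'   if `NULL` (default) the threshold is `min_seed_score_frac` times each
#'   query's self-score.
#' @param min_seed_score_frac Permissive fraction of query self-score
#'   (default 0.25; recall-first, mirroring an e-value-10 translated search).
#' @param min_complete_score_frac A structurally complete domain must also
#'   align to its query at this fraction of the query self-score (default
#'   0.5), or the completion is rejected as a chance pattern match and the
#'   locus reported incomplete.
#' @param min_splice_gain A spliced completion must beat the best
#'   unspliced reading of the same region by this many alignment-score
#'   units (default 40), so a chance acceptor cannot "complete" a domain
#'   whose second half contributes nothing.
#' @param substitution_matrix Name of the substitution matrix (BLOSUM62).
#' @param gap_opening,gap_extension Affine gap penalties for seeding.
#' @param max_intron_len,min_intron_len Bounds on the GT..AG intron searched
#'   at the two sanctioned positions inside the domain.
#' @param context_flank Flank exported around a hit for external gene
#'   predictors (bp).
#' @param heptapeptide_variants Accepted 7-mers at the domain's N edge.
#' @param hepta_finger_gap Maximum residues between the heptapeptide end and
#'   the first finger cysteine.
#' @param c2h2_cc_gap,c2hc_cc_gap,inner_gap Finger spacing specs (residues).
#' @param extension_range Allowed extra inner-spacer lengths (set
#'   `allow_extension = FALSE` to disable).
#' @param allow_extension Tolerate the extended-finger variant?
#' @param pr_search_window Residues after the heptapeptide within which the
#'   invariant `PR` dipeptide (intron anchor) is searched.
#' @param window_aa,window_overlap Translated-search windowing (residues).
#' @param pair_max_gap Maximum genomic distance (bp) used to pair the two
#'   domains of a Group I gene.
#' @param min_protein_len Minimum credible protein length (aa) before a gene
#'   model is called `short`.
#' @return A list of class `wrky_scan_config`.
#' @export
scan_config <- function(min_seed_score = NULL,
                        min_seed_score_frac = 0.25,
                        min_complete_score_frac = 0.5,
                        min_splice_gain = 40,
                        substitution_matrix = "BLOSUM62",
                        gap_opening = 10,
                        gap_extension = 0.5,
                        max_intron_len = 10000L,
                        min_intron_len = 20L,
                        context_flank = 20000L,
                        heptapeptide_variants = c("WRKYGQK", "WRKYGKK",
                                                  "WRKYGEK", "WKKYGQK",
                                                  "WKRYGQK", "WSKYGQK"),
                        hepta_finger_gap = 30L,
                        c2h2_cc_gap = c(4L, 5L),
                        c2hc_cc_gap = 7L,
                        inner_gap = 22:24,
                        extension_range = c(9L, 10L),
                        allow_extension = TRUE,
                        pr_search_window = 15L,
                        window_aa = 1500L,
                        window_overlap = 120L,
                        pair_max_gap = 5000L,
                        min_protein_len = 120L) {
  stopifnot(max_intron_len > 0L, min_intron_len > 0L,
            all(nchar(heptapeptide_variants) == 7L))
  structure(list(
    min_seed_score = min_seed_score,
    min_seed_score_frac = min_seed_score_frac,
    min_complete_score_frac = min_complete_score_frac,
    min_splice_gain = min_splice_gain,
    substitution_matrix = substitution_matrix,
    gap_opening = gap_opening,
    gap_extension = gap_extension,
    max_intron_len = as.integer(max_intron_len),
    min_intron_len = as.integer(min_intron_len),
    context_flank = as.integer(context_flank),
    heptapeptide_variants = heptapeptide_variants,
    hepta_finger_gap = as.integer(hepta_finger_gap),
    c2h2_cc_gap = as.integer(c2h2_cc_gap),
    c2hc_cc_gap = as.integer(c2hc_cc_gap),
    inner_gap = as.integer(inner_gap),
    extension_range = as.integer(extension_range),
    allow_extension = isTRUE(allow_extension),
    pr_search_window = as.integer(pr_search_window),
    window_aa = as.integer(window_aa),
    window_overlap = as.integer(window_overlap),
    pair_max_gap = as.integer(pair_max_gap),
    min_protein_len = as.integer(min_protein_len)
  ), class = "wrky_scan_config")
}

.substitution_matrix <- function(config) {
  name <- config$substitution_matrix
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# zinc-finger search downstream of a heptapeptide; pep is a plain character
# scalar with no '*' before the region of interest (caller truncates).
# Returns NULL or list(type, c1, end, extension).
.find_finger <- function(pep, from, config, to = NULL) {
  chars <- strsplit(pep, "")[[1]]
  n <- length(chars)
  # candidate (inner spacing, extension) pairs: canonical spacings first;
  # extended spacers are decomposed preferring the modal inner spacing, so
  # an observed surplus maps to a unique reported extension
  pairs <- cbind(config$inner_gap, 0L)
  if (config$allow_extension && length(config$extension_range)) {
    med <- sort(config$inner_gap)[ceiling(length(config$inner_gap) / 2)]
    g2o <- config$inner_gap[order(abs(config$inner_gap - med),
                                  config$inner_gap)]
    ex <- expand.grid(ext = sort(config$extension_range), g2 = g2o)
    ex <- ex[order(match(ex$g2, g2o), ex$ext), ]
    pairs <- rbind(pairs, cbind(ex$g2, ex$ext))
  }
  to <- min(n, to %||% (from + config$hepta_finger_gap))
  if (from > n) return(NULL)
  for (c1 in from:to) {
    if (chars[c1] != "C") next
    for (pi in seq_len(nrow(pairs))) {
      g2 <- pairs[pi, 1L]
      ext <- pairs[pi, 2L]
      # C2H2 before C2HC at equal c1
      for (g1 in config$c2h2_cc_gap) {
        c2 <- c1 + g1 + 1L
        if (c2 > n || chars[c2] != "C") next
        h1 <- c2 + g2 + ext + 1L
        h2 <- h1 + 2L
        if (h2 > n) next
        if (chars[h1] == "H" && chars[h2] == "H") {
          return(list(type = "C2H2", c1 = c1, end = h2, extension = ext))
        }
      }
      for (g1 in config$c2hc_cc_gap) {
        c2 <- c1 + g1 + 1L
        if (c2 > n || chars[c2] != "C") next
        h1 <- c2 + g2 + ext + 1L
        h2 <- h1 + 2L
        if (h2 > n) next
        if (chars[h1] == "H" && chars[h2] == "C") {
          return(list(type = "C2HC", c1 = c1, end = h2, extension = ext))
        }
      }
    }
  }
  NULL
}

# all heptapeptide occurrences in a peptide, ordered by position
.find_hepta <- function(pep, config) {
  hits <- lapply(config$heptapeptide_variants, function(v) {
    p <- gregexpr(v, pep, fixed = TRUE)[[1]]
    if (p[1L] == -1L) integer(0) else as.integer(p)
  })
  pos <- unlist(hits)
  var <- rep(config$heptapeptide_variants, lengths(hits))
  o <- order(pos)
  data.frame(pos = pos[o], variant = var[o], stringsAsFactors = FALSE)
}

#' Match the WRKY domain pattern in a peptide
#'
#' Finds each configured heptapeptide variant and, within a bounded window
#' downstream, a zinc finger (`C2H2` or `C2HC`, optionally with a 9-10
#' residue extended inner spacer).  A heptapeptide with no downstream finger
#' - including the case where a stop codon interrupts the reading - yields
#' an `INCOMPLETE` row.
#'
#' @param peptide A protein sequence (may contain `*` and `X`).
#' @param config A [scan_config()].
#' @return A data.frame with one row per heptapeptide occurrence: columns
#'   `hepta_start`, `heptapeptide`, `finger_type` (`C2H2`, `C2HC`,
#'   `INCOMPLETE`), `finger_extension`, `domain_start`, `domain_end`
#'   (`NA` when incomplete), `complete`.
#' @export
match_domain_pattern <- function(peptide, config = scan_config()) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  hep <- .find_hepta(peptide, config)
  rows <- lapply(seq_len(nrow(hep)), function(i) {
    h <- hep$pos[i]
    # truncate the reading at the first stop at/after the heptapeptide: a
    # finger beyond an in-frame stop is not a functional domain
    rest <- substr(peptide, h, nchar(peptide))
    stop_at <- regexpr("*", rest, fixed = TRUE)
    eff <- if (stop_at > 0L) substr(rest, 1L, stop_at - 1L) else rest
    fng <- if (nchar(eff) >= 8L) .find_finger(eff, 8L, config) else NULL
    if (is.null(fng)) {
      data.frame(hepta_start = h, heptapeptide = hep$variant[i],
                 finger_type = "INCOMPLETE", finger_extension = 0L,
                 domain_start = h, domain_end = NA_integer_,
                 complete = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(hepta_start = h, heptapeptide = hep$variant[i],
                 finger_type = fng$type, finger_extension = fng$extension,
                 domain_start = h, domain_end = h + fng$end - 1L,
                 complete = TRUE, stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) {
    return(data.frame(hepta_start = integer(0), heptapeptide = character(0),
                      finger_type = character(0), finger_extension = integer(0),
                      domain_start = integer(0), domain_end = integer(0),
                      complete = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
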
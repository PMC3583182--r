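## Tandem-array detection: greedy positional chaining of same-subfamily
## family members along each chromosome.  Purely positional + subfamily;
## sequence-similarity confirmation of paralogy belongs to the phylo module.

#' Detect tandem arrays of family members
#'
#' Consecutive same-subfamily members on one chromosome whose inter-gene
#' gap (next start minus previous end) is at most `max_gap`, with at most
#' `max_intervening` foreign genes in between, are chained into maximal,
#' disjoint arrays of two or more members.
#'
#' @param records Family records (see [read_family_table()]) or any
#'   data.frame with `gene_name`, `chrom`, `start`, `end`, `subfamily`
#'   (optionally `strand`, `strand_known`).
#' @param subfamily Optional filter: only chain members of this subfamily.
#' @param max_gap Maximum inter-gene gap in bp (default 30000).
#' @param max_intervening Maximum number of foreign (other-subfamily) genes
#'   tolerated between consecutive members (default 0).
#' @param require_same_subfamily Chain only same-subfamily members
#'   (default TRUE; FALSE chains any family members).
#' @return A data.frame with one row per array: `array_id`, `chrom`,
#'   `subfamily`, `n_members`, `members` (comma-separated, sorted by
#'   start), `span_start`, `span_end`, `same_orientation` (`NA` when any
#'   member's strand is unrecorded).
#' @export
detect_tandem_arrays <- function(records, subfamily = NULL, max_gap = 30000,
                                 max_intervening = 0,
                                 require_same_subfamily = TRUE) {
  need <- c("gene_name", "chrom", "start", "end", "subfamily")
  stopifnot(all(need %in% names(records)))
  if (any(is.na(records$start)) || any(is.na(records$end))) {
    stop("records are missing locus coordinates")
  }
  all_sorted <- records[order(records$chrom, records$start), , drop = FALSE]
  pool <- all_sorted
  if (!is.null(subfamily)) {
    pool <- pool[pool$subfamily == subfamily, , drop = FALSE]
  }
  key <- if (require_same_subfamily) pool$subfamily else
    rep("any", nrow(pool))
  arrays <- list()
  for (grp in split(seq_len(nrow(pool)), list(pool$chrom, key), drop = TRUE)) {
    idx <- grp[order(pool$start[grp])]
    if (length(idx) < 2L) next
    run <- idx[1L]
    flush <- function(run) {
      if (length(run) >= 2L) arrays[[length(arrays) + 1L]] <<- pool[run, ]
    }
    for (k in idx[-1L]) {
      prev <- run[length(run)]
      gap <- pool$start[k] - pool$end[prev]
      foreign <- sum(all_sorted$chrom == pool$chrom[k] &
                       all_sorted$start > pool$end[prev] &
                       all_sorted$end < pool$start[k] &
                       all_sorted$subfamily != pool$subfamily[k])
      if (gap <= max_gap && foreign <= max_intervening) {
        run <- c(run, k)
      } else {
        flush(run)
        run <- k
      }
    }
    flush(run)
  }
  if (!length(arrays)) {
    return(data.frame(array_id = character(0), chrom = character(0),
                      subfamily = character(0), n_members = integer(0),
                      members = character(0), span_start = integer(0),
                      span_end = integer(0), same_orientation = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(arrays, function(a) {
    strands_known <- if (!is.null(a$strand_known)) all(a$strand_known) else
      !is.null(a$strand)
    data.frame(
      chrom = a$chrom[1L],
      subfamily = if (require_same_subfamily) a$subfamily[1L] else "mixed",
      n_members = nrow(a),
      members = paste(a$gene_name, collapse = ","),
      span_start = min(a$start),
      span_end = max(a$end),
      same_orientation = if (strands_known) length(unique(a$strand)) == 1L
        else NA,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$span_start), , drop = FALSE]
  out <- cbind(array_id = sprintf("array_%02d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genomic span of a tandem array
#'
#' @param array A one-row data.frame from [detect_tandem_arrays()].
#' @return Span in bp: `max(end) - min(start) + 1` over members.
#' @export
array_span <- function(array) {
  stopifnot(nrow(array) == 1L)
  if (array$n_members < 2L) {
    stop("a tandem array must have at least 2 members")
  }
  as.integer(array$span_end - array$span_start + 1L)
}
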
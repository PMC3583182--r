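## The curated family table: a 4-column TSV (gene name, location, gene
## model, comments).  Comment text encodes subfamily, gene-model status and
## pseudogene evidence in inconsistently capitalized free text, so parsing
## is keyword-based and case-insensitive.

.SUBFAMILIES <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III", "UNASSIGNED")

# checksum of the packaged family table; transcription guard
.BDWRKY_TABLE_MD5 <- "e747fd3b3cf7e551d94b75b67a148561"

.parse_subfamily <- function(comment) {
  m <- regmatches(comment, regexec(
    "[Gg]roup\\s*(III|II\\s*[a-eA-E]|I)", comment))[[1]]
  if (length(m) < 2L) {
    return(NA_character_)
  }
  tok <- gsub("\\s+", "", m[2L])
  if (toupper(tok) == "III") return("III")
  if (toupper(tok) == "I") return("I")
  paste0("II", tolower(substr(tok, 3L, 3L)))
}

.parse_comment_flags <- function(comment, model_absent) {
  sub <- .parse_subfamily(comment)
  pseudo <- grepl("pseudogene|transposon", comment, ignore.case = TRUE)
  # a "No Gene Model" comment marks the record absent even when the model
  # column carries text (the table is internally inconsistent for one row;
  # the prose counts missing models from the comments)
  status <- if (model_absent ||
                grepl("no\\s*gene\\s*model", comment, ignore.case = TRUE)) {
    "absent"
  } else if (grepl("gene\\s*model\\s*incorrect", comment, ignore.case = TRUE)) {
    "incorrect"
  } else if (grepl("gene\\s*model\\s*short", comment, ignore.case = TRUE)) {
    "short"
  } else {
    "ok"
  }
  if (is.na(sub)) {
    if (!pseudo) {
      warning("no recognizable subfamily token in comment: '", comment, "'")
    }
    sub <- "UNASSIGNED"
  }
  list(subfamily = sub, model_status = status, pseudogene = pseudo)
}

#' Read a curated family table
#'
#' Expects a TSV with columns `gene_name`, `location`, `gene_model`,
#' `comments`.  A `-` in the gene-model column means the locus has no gene
#' model.  Comment keywords are parsed case-insensitively into subfamily,
#' model status (`ok`, `incorrect`, `short`, `absent`) and a pseudogene flag
#' (set by pseudogene/transposon mentions).
#'
#' @param path Path to the TSV.
#' @return A data.frame of family records with columns `gene_name`, `chrom`,
#'   `start`, `end`, `strand`, `strand_known`, `model_id`, `subfamily`,
#'   `model_status`, `pseudogene`, `comment`.
#' @export
read_family_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_name", "location", "gene_model", "comments") %in%
                  names(tab)))
  loci <- do.call(rbind, lapply(tab$location, parse_locus_string))
  model_id <- trimws(tab$gene_model)
  absent <- model_id %in% c("-", "")
  model_id[absent] <- NA_character_
  flags <- lapply(seq_len(nrow(tab)), function(i) {
    .parse_comment_flags(tab$comments[i], absent[i])
  })
  status <- vapply(flags, `[[`, character(1L), "model_status")
  model_id[status == "absent"] <- NA_character_  # absent <=> no model id
  data.frame(
    gene_name = tab$gene_name,
    chrom = loci$chrom,
    start = loci$start,
    end = loci$end,
    strand = loci$strand,
    strand_known = FALSE,
    model_id = model_id,
    subfamily = vapply(flags, `[[`, character(1L), "subfamily"),
    model_status = status,
    pseudogene = vapply(flags, `[[`, logical(1L), "pseudogene"),
    comment = tab$comments,
    stringsAsFactors = FALSE
  )
}

#' Write family records back to the 4-column TSV dialect
#'
#' @param records A data.frame as returned by [read_family_table()].
#' @param path Output path.
#' @export
write_family_table <- function(records, path) {
  out <- data.frame(
    gene_name = records$gene_name,
    location = sprintf("%s:%d.%d", records$chrom,
                       as.integer(records$start), as.integer(records$end)),
    gene_model = ifelse(is.na(records$model_id), "-", records$model_id),
    comments = records$comment,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the bundled Brachypodium WRKY family table (86 records)
#'
#' The packaged transcription of the curated 86-member BdWRKY family table,
#' guarded by a checksum.  Record BdWRKY59 carries a known coordinate
#' misprint (end < start) that is normalized on parsing.
#'
#' @return A data.frame of 86 family records (see [read_family_table()]).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "bdwrky_family_table.tsv",
                      package = "wrkyminer", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  expected <- .BDWRKY_TABLE_MD5
  if (!identical(md5, expected)) {
    stop("bundled family table failed its checksum (got ", md5, ")")
  }
  rec <- suppressWarnings(read_family_table(path))
  stopifnot(nrow(rec) == 86L)
  rec
}
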
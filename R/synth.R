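## Synthetic genomes with known truth: well-formed WRKY genes per subfamily
## (correct heptapeptide, finger spacing, and intron position for the
## class), optional corruption modes that mirror the failure taxonomy seen
## in curated family tables (in-frame stop, frameshift, truncation,
## transposon replacement), gene models in TRUE/BAD_MODEL/NO_MODEL modes,
## and a query set of intact domains - everything needed to exercise the
## scanner, the curation rules and the audit end to end with no downloads.

# spacer alphabet: no C/H (no spurious fingers), no W (no spurious
# heptapeptides), no P (no spurious PR intron anchors)
.SAFE_AA <- c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N",
              "Q", "R", "S", "T", "V", "Y")

.spacer <- function(n, offset = 0L) {
  if (n <= 0L) return("")
  idx <- ((offset + seq_len(n) - 1L) %% length(.SAFE_AA)) + 1L
  paste(.SAFE_AA[idx], collapse = "")
}

.rand_pep <- function(n) paste(sample(.SAFE_AA, n, replace = TRUE),
                               collapse = "")

.mut <- function(s, p) {
  if (!nchar(s) || p <= 0) return(s)
  ch <- strsplit(s, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) {
    ch[i] <- sample(setdiff(.SAFE_AA, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

.codon_env <- new.env()

.codons_for <- function() {
  if (is.null(.codon_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$tab <- split(names(gc), unname(gc))
  }
  .codon_env$tab
}

# reverse-translate with uniformly sampled synonymous codons
.revtrans <- function(pep) {
  tab <- .codons_for()
  ch <- strsplit(pep, "")[[1L]]
  paste(vapply(ch, function(a) {
    cs <- tab[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1L)), collapse = "")
}

.make_intron <- function(len) {
  stopifnot(len >= 6L)
  interior <- paste(sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE),
                    collapse = "")
  # a unique AG acceptor: strip interior AG dinucleotides
  while (grepl("AG", interior, fixed = TRUE)) {
    interior <- gsub("AG", "AC", interior, fixed = TRUE)
  }
  paste0("GT", interior, "AG")
}

#' Gene template for one WRKY subfamily
#'
#' Encodes the domain grammar of the subfamily: heptapeptide variant,
#' finger type and spacings, intron class (`PR` for I-C/IIc/IId/IIe/III,
#' `IIab` for IIa/IIb, plus the intronless Group I N-terminal domain) and
#' optional extended inner spacer (Group III only).
#'
#' @param subfamily One of I, IIa, IIb, IIc, IId, IIe, III.
#' @param ext Extra finger inner-spacer residues (0, 9 or 10; III only).
#' @param intron_len Length of the domain-splitting intron in bp.
#' @param hepta Heptapeptide variant (default WRKYGQK).
#' @return A list of class `wrky_gene_template`.
#' @export
wrky_gene_template <- function(subfamily, ext = 0L, intron_len = 200L,
                               hepta = "WRKYGQK") {
  spec <- switch(subfamily,
    I   = list(pre = "SDVD", mid = "TVRGSE", gapB = "SEVD", cc = 4L,
               inner = 22L, last = "H", finger = "C2H2",
               intron_class = "PR", two_domains = TRUE),
    IIa = list(pre = "DNSL", mid = "ILGDKT", five = "KAIKN", cc = 5L,
               inner = 23L, last = "H", finger = "C2H2",
               intron_class = "IIab", two_domains = FALSE),
    IIb = list(pre = "GLDE", mid = "SVKSEV", five = "RSMDN", cc = 5L,
               inner = 23L, last = "H", finger = "C2H2",
               intron_class = "IIab", two_domains = FALSE),
    IIc = list(pre = "ENSY", mid = "QVKGSE", gapB = "SYYK", cc = 4L,
               inner = 22L, last = "H", finger = "C2H2",
               intron_class = "PR", two_domains = FALSE),
    IId = list(pre = "AGDL", mid = "TLDGYE", gapB = "TFFD", cc = 5L,
               inner = 23L, last = "H", finger = "C2H2",
               intron_class = "PR", two_domains = FALSE),
    IIe = list(pre = "KGDI", mid = "AVNGTE", gapB = "GYYR", cc = 5L,
               inner = 24L, last = "H", finger = "C2H2",
               intron_class = "PR", two_domains = FALSE),
    III = list(pre = "QSSD", mid = "EVKNLE", gapB = "SIIR", cc = 7L,
               inner = 23L, last = "C", finger = "C2HC",
               intron_class = "PR", two_domains = FALSE),
    stop("unknown subfamily: ", subfamily)
  )
  if (ext != 0L && spec$finger != "C2HC") {
    stop("extended fingers are a Group III feature (got subfamily ",
         subfamily, ")")
  }
  if (ext != 0L && !ext %in% c(9L, 10L)) {
    stop("finger extension must be 0, 9 or 10")
  }
  off <- match(subfamily, c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III"))
  structure(c(spec, list(subfamily = subfamily, ext = as.integer(ext),
                         intron_len = as.integer(intron_len), hepta = hepta,
                         offset = off)),
            class = "wrky_gene_template")
}

# domain halves for an intron-bearing domain; positions are residues
.domain_halves <- function(tpl, mutate_p) {
  off <- tpl$offset
  if (tpl$intron_class == "PR") {
    part1 <- paste0(tpl$hepta, .mut(tpl$mid, mutate_p), "PR")
    part2 <- paste0(.mut(tpl$gapB, mutate_p),
                    "C", .mut(.spacer(tpl$cc, off), mutate_p),
                    "C", .mut(.spacer(tpl$inner + tpl$ext, off + 3L), mutate_p),
                    "H", .mut(.spacer(1L, off + 7L), mutate_p), tpl$last)
  } else {
    stopifnot(tpl$cc == 5L)  # the IIab intron anchor is C-X5-C
    part1 <- paste0(tpl$hepta, .mut(tpl$mid, mutate_p),
                    "C", .mut(.spacer(5L, off), mutate_p),
                    "C", .mut(tpl$five, mutate_p))
    part2 <- paste0(.mut(.spacer(tpl$inner + tpl$ext - 5L, off + 3L), mutate_p),
                    "H", .mut(.spacer(1L, off + 7L), mutate_p), "H")
  }
  list(part1 = part1, part2 = part2)
}

# the intronless Group I N-terminal domain (single exon)
.n_domain <- function(mutate_p) {
  paste0("WRKYGQK", .mut("DGFNSG", mutate_p), .mut("TQSA", mutate_p),
         "C", .mut(.spacer(4L, 9L), mutate_p),
         "C", .mut(.spacer(22L, 11L), mutate_p),
         "H", .mut(.spacer(1L, 13L), mutate_p), "H")
}

#' Generate one synthetic WRKY gene
#'
#' Emits a CDS whose spliced translation contains a well-formed domain for
#' the template's subfamily, with a GT..AG intron at exactly the sanctioned
#' position for the intron class (Group I genes get an intronless
#' N-terminal domain plus an intron-split C-terminal domain).  Uses the
#' session RNG: seed upstream for reproducibility.
#'
#' @param template A [wrky_gene_template()].
#' @param mutate_p Per-residue substitution rate applied to non-structural
#'   domain spacers (default 0.08).
#' @return A list: `seq` (gene nucleotide sequence), `protein` (spliced
#'   translation), `exons`/`intron` (gene-local coordinates), `domains`
#'   (per-domain truth: coordinates, peptide, class), `subfamily`,
#'   `corruption` (`"NONE"`).
#' @export
make_wrky_gene <- function(template, mutate_p = 0.08) {
  stopifnot(inherits(template, "wrky_gene_template"))
  halves <- .domain_halves(template, mutate_p)
  nflank <- paste0("M", .rand_pep(sample(44:80, 1L)))
  cflank <- .rand_pep(sample(60:120, 1L))
  pre <- .mut(template$pre, mutate_p)
  if (template$two_domains) {
    ndom <- .n_domain(mutate_p)
    linker <- .rand_pep(sample(25:40, 1L))
    pepA <- paste0(nflank, pre, ndom, linker, "SDVD", halves$part1)
    n_start_res <- nchar(nflank) + nchar(pre) + 1L
    c_start_res <- nchar(pepA) - nchar(halves$part1) + 1L
  } else {
    pepA <- paste0(nflank, pre, halves$part1)
    c_start_res <- nchar(pepA) - nchar(halves$part1) + 1L
  }
  pepB <- paste0(halves$part2, cflank)
  exon1_nt <- .revtrans(pepA)
  exon2_nt <- paste0(.revtrans(pepB), "TAA")
  intron <- .make_intron(template$intron_len)
  seqs <- paste0(exon1_nt, intron, exon2_nt)
  e1 <- nchar(exon1_nt)
  il <- nchar(intron)
  total <- nchar(seqs)
  exons <- data.frame(start = c(1L, e1 + il + 1L),
                      end = c(e1, total), phase = c(0L, 0L))
  dom_rows <- list()
  if (template$two_domains) {
    n_start <- 3L * (n_start_res - 1L) + 1L
    n_end <- 3L * (n_start_res - 1L + nchar(ndom))
    dom_rows[[1L]] <- data.frame(
      domain = 1L, start = n_start, end = n_end,
      exon1_start = n_start, exon1_end = n_end,
      exon2_start = NA_integer_, exon2_end = NA_integer_,
      intron_class = "NONE", finger_type = "C2H2", finger_extension = 0L,
      heptapeptide = "WRKYGQK", peptide = ndom, stringsAsFactors = FALSE)
  }
  c_start <- 3L * (c_start_res - 1L) + 1L
  c_end <- e1 + il + 3L * nchar(halves$part2)
  dom_rows[[length(dom_rows) + 1L]] <- data.frame(
    domain = length(dom_rows) + 1L, start = c_start, end = c_end,
    exon1_start = c_start, exon1_end = e1,
    exon2_start = e1 + il + 1L, exon2_end = c_end,
    intron_class = template$intron_class, finger_type = template$finger,
    finger_extension = template$ext, heptapeptide = template$hepta,
    peptide = paste0(halves$part1, halves$part2), stringsAsFactors = FALSE)
  domains <- do.call(rbind, dom_rows)
  gene <- list(seq = seqs, protein = paste0(pepA, pepB), exons = exons,
               intron = c(e1 + 1L, e1 + il), domains = domains,
               subfamily = template$subfamily, corruption = "NONE",
               repeat_local = NULL)
  # internal consistency: every intact gene must pass the pattern engine
  chk <- match_domain_pattern(gene$protein, scan_config())
  stopifnot(any(chk$complete))
  gene
}

# low-complexity A/T/G cassette (no cytosine: its translations can encode
# neither C nor H, so it can never fake a zinc finger)
.TRANSPOSON_UNIT <- "TTAGGATTAATGGTTAGATTGAATTGGATAGATTAAGTTG"

#' Corrupt a synthetic gene
#'
#' Modes mirror curated-table failure classes: `STOP` substitutes a domain
#' codon (in the intron-distal half) with `TAA`; `FRAMESHIFT` deletes 1 bp
#' just upstream of the finger's first structural position in the second
#' exon; `TRUNCATION` drops the gene beyond the domain's first exon;
#' `TRANSPOSON` additionally replaces the removed region with a marked
#' repeat cassette recorded in `repeat_local`; `NONE` is the identity.
#'
#' @param gene A gene from [make_wrky_gene()].
#' @param mode One of NONE, STOP, FRAMESHIFT, TRUNCATION, TRANSPOSON.
#' @return The adjusted gene, with `corruption` set.
#' @export
corrupt_gene <- function(gene, mode = c("NONE", "STOP", "FRAMESHIFT",
                                        "TRUNCATION", "TRANSPOSON")) {
  mode <- match.arg(mode)
  if (mode == "NONE") return(gene)
  d <- gene$domains[nrow(gene$domains), ]  # the intron-bearing domain
  stopifnot(!is.na(d$exon2_start))
  if (mode == "STOP") {
    # third residue of the second exon: inside the domain, upstream of the
    # finger's structural positions
    p <- d$exon2_start + 6L
    substr(gene$seq, p, p + 2L) <- "TAA"
    gene$domains$peptide[nrow(gene$domains)] <- NA_character_
  } else if (mode == "FRAMESHIFT") {
    p <- d$exon2_start + 3L
    gene$seq <- paste0(substr(gene$seq, 1L, p - 1L),
                       substr(gene$seq, p + 1L, nchar(gene$seq)))
    gene$exons$end[nrow(gene$exons)] <- nchar(gene$seq)
    gene$domains$end[nrow(gene$domains)] <- d$end - 1L
    gene$domains$exon2_end[nrow(gene$domains)] <- d$exon2_end - 1L
    gene$domains$peptide[nrow(gene$domains)] <- NA_character_
  } else {
    cut <- d$exon1_end + 10L
    kept <- substr(gene$seq, 1L, cut)
    if (mode == "TRANSPOSON") {
      cassette <- paste(rep(.TRANSPOSON_UNIT, 4L), collapse = "")
      gene$seq <- paste0(kept, cassette)
      gene$repeat_local <- c(cut + 1L, nchar(gene$seq))
    } else {
      gene$seq <- kept
    }
    gene$exons <- gene$exons[1L, , drop = FALSE]
    gene$exons$end <- min(gene$exons$end, nchar(gene$seq))
    gene$intron <- NULL
    gene$domains$end[nrow(gene$domains)] <- d$exon1_end
    gene$domains$exon2_start[nrow(gene$domains)] <- NA_integer_
    gene$domains$exon2_end[nrow(gene$domains)] <- NA_integer_
    gene$domains$peptide[nrow(gene$domains)] <- NA_character_
  }
  gene$corruption <- mode
  gene
}

.map_local <- function(s, e, off, glen, strand) {
  if (strand == "+") {
    c(off + s, off + e)
  } else {
    c(off + glen - e + 1L, off + glen - s + 1L)
  }
}

#' The default 12-gene study condition
#'
#' Twelve intact genes covering all seven subfamilies, both intron classes,
#' and the extended-finger Group III variants (9 and 10 extra residues).
#'
#' @return A data.frame usable as the `spec` of [build_synthetic_genome()].
#' @export
default_synth_spec <- function() {
  data.frame(
    subfamily = c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III",
                  "I", "IIc", "III", "III", "III"),
    ext = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 9L, 10L),
    corruption = "NONE",
    model_mode = "TRUE",
    stringsAsFactors = FALSE)
}

#' Build a synthetic genome with implanted WRKY genes and known truth
#'
#' Implants the specified genes at non-overlapping random positions (both
#' strands) in an i.i.d. background of configurable GC content, and emits
#' gene models per `model_mode` (`"TRUE"`, `"BAD_MODEL"` - a domain-breaking
#' exon-boundary shift - or `"NO_MODEL"`), a query set holding one intact
#' domain peptide per subfamily present (plus the Group I N-terminal
#' domain), a repeat annotation for transposon corruptions, and truth
#' tables at gene and domain level.
#'
#' @param spec A data.frame with columns `subfamily`, `corruption`,
#'   `model_mode` and optionally `ext` (see [default_synth_spec()]).
#' @param background_len Chromosome length in bp (default 1e6).
#' @param seed Optional integer seed (restores the session RNG on exit).
#' @param gc Background GC fraction (default 0.44).
#' @param chrom Chromosome name.
#' @param mutate_p Spacer substitution rate passed to [make_wrky_gene()].
#' @return A list: `genome` (DNAStringSet), `models` (as [read_gff3()]),
#'   `truth_genes`, `truth_domains`, `queries` (AAStringSet), `repeats`
#'   (data.frame), `spec`.
#' @export
build_synthetic_genome <- function(spec, background_len = 1e6, seed = NULL,
                                   gc = 0.44, chrom = "synChr1",
                                   mutate_p = 0.08) {
  stopifnot(nrow(spec) >= 1L, "subfamily" %in% names(spec))
  if (is.null(spec$ext)) spec$ext <- 0L
  if (is.null(spec$corruption)) spec$corruption <- "NONE"
  if (is.null(spec$model_mode)) spec$model_mode <- "TRUE"
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  n <- nrow(spec)
  genes <- lapply(seq_len(n), function(i) {
    tpl <- wrky_gene_template(spec$subfamily[i], ext = spec$ext[i],
                              intron_len = sample(90:350, 1L))
    corrupt_gene(make_wrky_gene(tpl, mutate_p = mutate_p),
                 spec$corruption[i])
  })
  glens <- vapply(genes, function(g) nchar(g$seq), integer(1L))
  margin <- 6000L
  background_len <- as.integer(background_len)
  slack <- background_len - sum(glens) - (n + 1L) * margin
  if (slack < 0L) stop("genome too small to place ", n, " genes")
  u <- stats::runif(n + 1L)
  gaps <- as.integer(margin + floor(slack * u / sum(u)))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  bg <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  pieces <- character(2L * n + 1L)
  offs <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- bg(gaps[i])
    pos <- pos + gaps[i]
    offs[i] <- pos
    pieces[2L * i] <- if (strands[i] == "+") genes[[i]]$seq else
      .revcomp(genes[[i]]$seq)
    pos <- pos + glens[i]
  }
  pieces[2L * n + 1L] <- bg(background_len - pos)
  genome <- Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""),
                                              chrom))

  gene_names <- sprintf("SYNW%02d", seq_len(n))
  models <- list()
  repeats <- list()
  truth_genes <- list()
  truth_domains <- list()
  for (i in seq_len(n)) {
    g <- genes[[i]]
    glen <- glens[i]
    span <- .map_local(1L, glen, offs[i], glen, strands[i])
    mm <- spec$model_mode[i]
    model_id <- NA_character_
    if (mm != "NO_MODEL") {
      ex <- g$exons
      if (mm == "BAD_MODEL") {
        if (nrow(ex) < 2L) stop("BAD_MODEL requires an intron-bearing gene")
        # shift the acceptor 30 bp into the second exon: in frame, but the
        # translation now lacks part of the domain
        ex$start[nrow(ex)] <- ex$start[nrow(ex)] + 30L
      }
      gex <- t(vapply(seq_len(nrow(ex)), function(k) {
        .map_local(ex$start[k], ex$end[k], offs[i], glen, strands[i])
      }, integer(2L)))
      ord <- order(gex[, 1L], decreasing = (strands[i] == "-"))
      model_id <- paste0(gene_names[i], ".1")
      models[[model_id]] <- list(
        model_id = model_id, chrom = chrom,
        start = min(gex[, 1L]), end = max(gex[, 2L]), strand = strands[i],
        exons = data.frame(start = gex[ord, 1L], end = gex[ord, 2L],
                           phase = ex$phase[ord]))
    }
    if (!is.null(g$repeat_local)) {
      rl <- .map_local(g$repeat_local[1L], g$repeat_local[2L], offs[i],
                       glen, strands[i])
      repeats[[length(repeats) + 1L]] <- data.frame(
        chrom = chrom, start = rl[1L], end = rl[2L],
        name = paste0(gene_names[i], ".repeat"), stringsAsFactors = FALSE)
    }
    expected_status <- if (mm == "NO_MODEL") "missing" else
      if (mm == "BAD_MODEL") "mispredicted" else "match"
    truth_genes[[i]] <- data.frame(
      gene = gene_names[i], chrom = chrom, start = span[1L], end = span[2L],
      strand = strands[i], subfamily = spec$subfamily[i],
      corruption = g$corruption, model_mode = mm, model_id = model_id,
      expected_status = expected_status,
      expected_pseudogene = g$corruption != "NONE",
      stringsAsFactors = FALSE)
    dd <- g$domains
    for (k in seq_len(nrow(dd))) {
      dspan <- .map_local(dd$start[k], dd$end[k], offs[i], glen, strands[i])
      e1 <- .map_local(dd$exon1_start[k], dd$exon1_end[k], offs[i], glen,
                       strands[i])
      e2 <- if (is.na(dd$exon2_start[k])) c(NA_integer_, NA_integer_) else
        .map_local(dd$exon2_start[k], dd$exon2_end[k], offs[i], glen,
                   strands[i])
      # the last (intron-bearing) domain is the one corruption breaks
      intact <- g$corruption == "NONE" || k < nrow(dd)
      truth_domains[[length(truth_domains) + 1L]] <- data.frame(
        gene = gene_names[i], domain = dd$domain[k], chrom = chrom,
        start = dspan[1L], end = dspan[2L], strand = strands[i],
        exon1_start = min(e1), exon1_end = max(e1),
        exon2_start = min(e2), exon2_end = max(e2),
        intron_class = dd$intron_class[k], finger_type = dd$finger_type[k],
        finger_extension = dd$finger_extension[k],
        heptapeptide = dd$heptapeptide[k], peptide = dd$peptide[k],
        complete_expected = intact, stringsAsFactors = FALSE)
    }
  }

  # one intact domain peptide per subfamily present, from pristine templates
  qnames <- character(0)
  qseqs <- character(0)
  for (sf in unique(spec$subfamily)) {
    ext <- spec$ext[match(sf, spec$subfamily)]
    tpl <- wrky_gene_template(sf, ext = ext)
    halves <- .domain_halves(tpl, mutate_p = 0)
    qnames <- c(qnames, sf)
    qseqs <- c(qseqs, paste0(halves$part1, halves$part2))
    if (sf == "I") {
      qnames <- c(qnames, "I.N")
      qseqs <- c(qseqs, .n_domain(0))
    }
  }
  queries <- Biostrings::AAStringSet(setNames(qseqs, qnames))

  list(genome = genome, models = models,
       truth_genes = do.call(rbind, truth_genes),
       truth_domains = do.call(rbind, truth_domains),
       queries = queries,
       repeats = if (length(repeats)) do.call(rbind, repeats) else
         data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), name = character(0),
                    stringsAsFactors = FALSE),
       spec = spec)
}

#' Write synthetic fixtures to disk
#'
#' Emits `genome.fa`, `truth.gff3`, `repeats.gff3`, `queries.fa`,
#' `truth_genes.tsv` and `truth_domains.tsv` under `dir`.
#'
#' @param synth Output of [build_synthetic_genome()].
#' @param dir Output directory (created if needed).
#' @export
write_synthetic_fixtures <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(synth$genome, file.path(dir, "genome.fa"))
  write_gff3(synth$models, file.path(dir, "truth.gff3"))
  write_fasta(synth$queries, file.path(dir, "queries.fa"))
  rep_lines <- "##gff-version 3"
  for (k in seq_len(nrow(synth$repeats))) {
    r <- synth$repeats[k, ]
    rep_lines <- c(rep_lines, paste(
      r$chrom, "wrkyminer", "repeat_region", r$start, r$end, ".", "+", ".",
      paste0("ID=", r$name), sep = "\t"))
  }
  writeLines(rep_lines, file.path(dir, "repeats.gff3"))
  utils::write.table(synth$truth_genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(synth$truth_domains, file.path(dir, "truth_domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
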
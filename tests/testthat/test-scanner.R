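# scanner behavior on small genomes with implanted domains

test_that("verbatim implants seed at self-score on both strands", {
  cfg <- scan_config()
  set.seed(31)
  tpl <- wrky_gene_template("IIc")
  g <- make_wrky_gene(tpl, mutate_p = 0)
  qpep <- g$domains$peptide[1L]
  qnt <- fixed_revtrans(qpep)
  queries <- Biostrings::AAStringSet(c(IIc = qpep))

  genome <- random_genome(3e4, seed = 101)
  genome <- implant(genome, qnt, 5001L, "+")
  seeds <- seed_search(genome, queries, cfg)
  self <- Biostrings::pairwiseAlignment(qpep, qpep, type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = cfg$gap_opening,
    gapExtension = cfg$gap_extension, scoreOnly = TRUE)
  top <- seeds[which.max(seeds$score), ]
  expect_equal(top$score, self)
  expect_equal(top$start, 5001L)
  expect_equal(top$end, 5001L + nchar(qnt) - 1L)
  expect_equal(top$strand, "+")

  # strand symmetry: the same implant on the minus strand scores equally
  genome2 <- implant(random_genome(3e4, seed = 102), qnt, 5001L, "-")
  seeds2 <- seed_search(genome2, queries, cfg)
  top2 <- seeds2[which.max(seeds2$score), ]
  expect_equal(top2$score, self)
  expect_equal(top2$strand, "-")
  expect_equal(top2$start, 5001L)

  # a half-domain fragment (pseudogene scenario) still seeds
  frag <- substr(qpep, 1L, floor(nchar(qpep) / 2))
  genome3 <- implant(random_genome(3e4, seed = 103),
                     fixed_revtrans(frag), 9001L, "+")
  seeds3 <- seed_search(genome3, queries, cfg)
  expect_true(any(seeds3$start <= 9001L &
                    seeds3$end >= 9001L + 3L * nchar(frag) - 4L))

  expect_error(seed_search(genome, Biostrings::AAStringSet(), cfg),
               "empty query set")
})

test_that("spliced domains are reconstructed at both sanctioned positions", {
  for (sf in c("IIc", "IIb")) {
    syn <- build_synthetic_genome(
      data.frame(subfamily = sf, corruption = "NONE", model_mode = "TRUE"),
      background_len = 4e4, seed = 7 + nchar(sf))
    hits <- scan_genome(syn$genome, syn$queries)
    td <- syn$truth_domains
    expect_equal(sum(hits$complete), 1L)
    h <- hits[hits$complete, ]
    expect_equal(h$intron_class, td$intron_class)
    expect_equal(h$start, td$start)
    expect_equal(h$end, td$end)
    expect_equal(h$exon1_start, td$exon1_start)
    expect_equal(h$exon2_end, td$exon2_end)
    expect_equal(h$peptide, td$peptide)
  }
})

test_that("an intron moved off the sanctioned position is not spliced", {
  set.seed(9)
  tpl <- wrky_gene_template("IIc", intron_len = 150L)
  g <- make_wrky_gene(tpl, mutate_p = 0)
  # relocate the intron 6 codons (18 nt) downstream of the PR boundary
  i1 <- g$intron[1L]
  i2 <- g$intron[2L]
  moved <- paste0(substr(g$seq, 1L, i1 - 1L),
                  substr(g$seq, i2 + 1L, i2 + 18L),
                  substr(g$seq, i1, i2),
                  substr(g$seq, i2 + 19L, nchar(g$seq)))
  genome <- implant(random_genome(4e4, seed = 104), moved, 12001L, "+")
  queries <- Biostrings::AAStringSet(
    setNames(g$domains$peptide[1L], "IIc"))
  hits <- scan_genome(genome, queries)
  expect_equal(sum(hits$complete), 0L)
  expect_gte(nrow(hits), 1L)  # flagged, never silently dropped
})

test_that("overlapping and duplicate hits merge to the best representative", {
  h <- data.frame(
    chrom = "c1", start = c(100L, 120L, 5000L), end = c(400L, 380L, 5300L),
    strand = "+", frame = 0L, exon1_start = c(100L, 120L, 5000L),
    exon1_end = c(400L, 380L, 5300L), exon2_start = NA_integer_,
    exon2_end = NA_integer_, intron_class = "NONE",
    peptide = "X", heptapeptide = "WRKYGQK",
    finger_type = c("C2H2", "INCOMPLETE", "C2H2"),
    finger_extension = 0L, complete = c(TRUE, FALSE, TRUE),
    stop_broken = FALSE, score = c(200, 250, 150), query_id = "q",
    stringsAsFactors = FALSE)
  m <- merge_hits(h)
  expect_equal(nrow(m), 2L)
  # completeness outranks score within an overlap group
  expect_true(m$complete[1L])
  expect_equal(m$start, c(100L, 5000L))
  expect_equal(nrow(merge_hits(h[0L, ])), 0L)
})

test_that("scanning is deterministic and strand-symmetric", {
  syn <- build_synthetic_genome(
    data.frame(subfamily = c("IIc", "III"), corruption = "NONE",
               model_mode = "TRUE"),
    background_len = 5e4, seed = 13)
  h1 <- scan_genome(syn$genome, syn$queries)
  h2 <- scan_genome(syn$genome, syn$queries)
  expect_identical(h1, h2)

  # reverse-complementing the genome mirrors every hit
  L <- length(syn$genome[[1L]])
  rc <- Biostrings::reverseComplement(syn$genome)
  names(rc) <- names(syn$genome)
  h3 <- scan_genome(rc, syn$queries)
  expect_equal(nrow(h3), nrow(h1))
  mirrored <- data.frame(start = L - h1$end + 1L, end = L - h1$start + 1L,
                         strand = ifelse(h1$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(h3$start, mirrored$start)
  expect_equal(h3$end, mirrored$end)
  expect_equal(h3$strand, mirrored$strand)
  expect_equal(sum(h3$complete), sum(h1$complete))
})

test_that("every complete hit re-passes the pattern engine", {
  syn <- build_synthetic_genome(
    data.frame(subfamily = c("I", "IIa", "IIe"), corruption = "NONE",
               model_mode = "TRUE"),
    background_len = 6e4, seed = 17)
  hits <- scan_genome(syn$genome, syn$queries)
  for (i in which(hits$complete)) {
    m <- match_domain_pattern(hits$peptide[i])
    expect_true(any(m$complete & m$hepta_start == 1L))
  }
})
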
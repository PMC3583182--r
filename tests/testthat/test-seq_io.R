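test_that("FASTA reading normalizes case, wrapping and U/T; round-trips", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a descr text", "acgtacgtac", ">b", "ACGTACGTACGTACGTACGT"),
             path)
  x <- read_fasta(path, type = "dna")
  expect_equal(names(x), c("a", "b"))
  expect_equal(as.character(x[["a"]]), "ACGTACGTAC")
  expect_equal(Biostrings::width(x), c(10L, 20L))

  writeLines(c(">r", "acgu", "ACGU"), path)
  expect_equal(as.character(read_fasta(path, type = "dna")[["r"]]),
               "ACGTACGT")

  writeLines(c(">d1", "ACGT", ">d1", "ACGT"), path)
  expect_error(read_fasta(path), "duplicate")

  writeLines(character(0), path)
  expect_warning(x0 <- read_fasta(path, type = "dna"), "empty")
  expect_length(x0, 0L)

  # generator output re-read is byte-identical
  syn <- build_synthetic_genome(data.frame(subfamily = "IIc"),
                                background_len = 3e4, seed = 3)
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(syn$genome, out)
  expect_identical(as.character(read_fasta(out, type = "dna")),
                   as.character(syn$genome))
})

test_that("locus strings parse in all table dialects", {
  l <- parse_locus_string("Bd2:14220256.14222873")
  expect_equal(unlist(l[c("chrom", "start", "end", "strand")]),
               c(chrom = "Bd2", start = "14220256", end = "14222873",
                 strand = "+"))
  l2 <- parse_locus_string("Bd2: 52664751 - 52666466")
  expect_equal(l2$start, 52664751)
  expect_equal(l2$end, 52666466)
  l3 <- parse_locus_string("Bd1:5.5")
  expect_equal(l3$end - l3$start + 1, 1)
  expect_error(parse_locus_string("Bd1;5.5"), "malformed")
  expect_error(parse_locus_string("chr1:12"), "malformed")
  # the reversed-coordinate misprint dialect is accepted with a warning
  expect_warning(lr <- parse_locus_string("Bd4:48418469.4842114"), "reversed")
  expect_lt(lr$start, lr$end)
})

test_that("every bundled family-table location parses; census is exact", {
  fam <- load_table1_fixture()
  expect_equal(nrow(fam), 86L)
  expect_true(all(fam$end >= fam$start))
  expect_equal(fam$subfamily[fam$gene_name == "BdWRKY72"], "IIc")
  expect_match(fam$comment[fam$gene_name == "BdWRKY72"], "WKKY")
  expect_true(fam$pseudogene[fam$gene_name == "BdWRKY18"])
  expect_equal(fam$model_status[fam$gene_name == "BdWRKY3"], "incorrect")
  expect_equal(fam$subfamily[fam$gene_name == "BdWRKY3"], "IIc")
  expect_true(is.na(fam$model_id[fam$gene_name == "BdWRKY33"]))
  expect_equal(fam$model_status[fam$gene_name == "BdWRKY33"], "absent")
  expect_equal(fam$model_status[fam$gene_name == "BdWRKY51"], "short")
  expect_equal(fam$subfamily[fam$gene_name == "BdWRKY35"], "IId")
})

test_that("family table write/read round-trips", {
  fam <- load_table1_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_family_table(fam, path)
  back <- suppressWarnings(read_family_table(path))
  expect_equal(back, fam)
})

test_that("extract_region honors flanks, clipping and strand", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTTAACC"))
  expect_equal(extract_region(g, "chr1", 3, 6), "CCGG")
  expect_equal(nchar(extract_region(g, "chr1", 3, 6)), 6 - 3 + 1)
  # flank clipped at position 1, never padded
  expect_equal(extract_region(g, "chr1", 2, 4, flank = 5), "AACCGGTTA")
  # minus strand is the reverse complement of the plus extraction
  plus <- extract_region(g, "chr1", 3, 8, "+")
  minus <- extract_region(g, "chr1", 3, 8, "-")
  expect_equal(minus, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(plus))))
  expect_error(extract_region(g, "chrX", 1, 2), "unknown chromosome")
})

test_that("GFF3 written by the generator reads back as the truth models", {
  syn <- build_synthetic_genome(
    data.frame(subfamily = c("IIc", "I"), corruption = "NONE",
               model_mode = "TRUE"),
    background_len = 5e4, seed = 21)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(syn$models, path)
  back <- read_gff3(path)
  expect_equal(length(back), length(syn$models))
  for (id in names(syn$models)) {
    expect_equal(back[[id]]$exons, syn$models[[id]]$exons)
    expect_equal(back[[id]]$strand, syn$models[[id]]$strand)
    expect_equal(back[[id]]$chrom, syn$models[[id]]$chrom)
  }
  # minus-strand models keep exons in transcription order
  neg <- Filter(function(m) m$strand == "-", back)
  for (m in neg) {
    expect_true(all(diff(m$exons$start) < 0))
  }
})

test_that("orphan CDS features are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tmRNA\t1\t90\t.\t+\t.\tID=m1",
               "c1\tsrc\tCDS\t1\t30\t.\t+\t0\tID=c1;Parent=m1",
               "c1\tsrc\tCDS\t61\t90\t.\t+\t0\tID=orphan"), path)
  expect_warning(models <- read_gff3(path), "without a parent")
  expect_equal(nrow(models[["m1"]]$exons), 1L)
})
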
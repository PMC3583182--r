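# subfamily assignment, pseudogene flagging and gene-model auditing

scan_once <- function(spec, len = 6e4, seed = 23) {
  syn <- build_synthetic_genome(spec, background_len = len, seed = seed)
  hits <- scan_genome(syn$genome, syn$queries)
  list(syn = syn, hits = hits, loci = pair_group1_domains(hits))
}

test_that("Group I domains pair within the distance guard only", {
  r <- scan_once(data.frame(subfamily = c("I", "IIc", "IIc"),
                            corruption = "NONE", model_mode = "TRUE"))
  expect_equal(nrow(r$loci), 3L)
  gi <- r$loci[r$loci$n_domains == 2L, ]
  expect_equal(nrow(gi), 1L)
  expect_true(gi$complete)
  expect_equal(gi$d1_intron_class, "NONE")  # N-domain upstream, intronless
  expect_equal(gi$d2_intron_class, "PR")
  # the two distant IIc genes stay separate single-domain loci
  expect_equal(sum(r$loci$n_domains == 1L), 2L)
})

test_that("the subfamily cascade follows domain structure and references", {
  r <- scan_once(data.frame(
    subfamily = c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III"),
    corruption = "NONE", model_mode = "TRUE"), len = 9e4, seed = 29)
  loci <- assign_subfamily(r$loci, references = r$syn$queries)
  truth <- r$syn$truth_genes[order(r$syn$truth_genes$start), ]
  expect_equal(loci$subfamily, truth$subfamily)
  # structural rules are certain; intron-degenerate groups are flagged
  expect_equal(loci$confidence[loci$subfamily == "I"], "rule")
  expect_equal(loci$confidence[loci$subfamily == "III"], "rule")
  expect_true(all(loci$confidence[loci$subfamily %in%
                                    c("IIa", "IIb", "IIc", "IId", "IIe")] ==
                    "ambiguous"))
  expect_true(all(grepl("TWO_DOMAINS", loci$evidence[loci$subfamily == "I"])))
  expect_true(all(grepl("FINGER_C2HC", loci$evidence[loci$subfamily == "III"])))
  expect_true(all(grepl("INTRON_IIAB",
                        loci$evidence[loci$subfamily %in% c("IIa", "IIb")])))

  # tree placements confirm the degenerate groups
  pl <- placements_from_tree(
    setNames(loci$peptide, loci$locus_name), r$syn$queries)
  loci2 <- assign_subfamily(r$loci, references = r$syn$queries,
                            placements = pl)
  expect_equal(loci2$subfamily, truth$subfamily)
  expect_true(all(loci2$confidence[loci2$subfamily %in%
                                     c("IIa", "IIb", "IIc", "IId", "IIe")] ==
                    "tree-confirmed"))

  # without references the degenerate groups stay unassigned
  loci3 <- assign_subfamily(r$loci)
  expect_true(all(loci3$subfamily[loci3$finger_type == "C2H2" &
                                    loci3$n_domains == 1L] == "UNASSIGNED"))
})

test_that("pseudogene evidence matches the corruption mode", {
  r <- scan_once(data.frame(
    subfamily = c("IIc", "IId", "IIe", "IIb"),
    corruption = c("NONE", "STOP", "FRAMESHIFT", "TRUNCATION"),
    model_mode = "TRUE"), len = 7e4, seed = 37)
  loci <- flag_pseudogene(r$loci, r$syn$genome)
  truth <- r$syn$truth_genes[order(r$syn$truth_genes$start), ]
  ev <- setNames(loci$pseudogene_evidence, truth$corruption)
  expect_equal(unname(ev[["NONE"]]), "")
  expect_setequal(strsplit(ev[["STOP"]], ",")[[1L]],
                  c("PARTIAL_DOMAIN", "INTERNAL_STOP"))
  expect_setequal(strsplit(ev[["FRAMESHIFT"]], ",")[[1L]],
                  c("PARTIAL_DOMAIN", "FRAMESHIFT"))
  expect_setequal(strsplit(ev[["TRUNCATION"]], ",")[[1L]],
                  "PARTIAL_DOMAIN")
  expect_equal(loci$pseudogene, truth$corruption != "NONE")
})

test_that("transposon evidence needs a repeat annotation", {
  r <- scan_once(data.frame(subfamily = "IIc", corruption = "TRANSPOSON",
                            model_mode = "NO_MODEL"), len = 4e4, seed = 41)
  with_rep <- flag_pseudogene(r$loci, r$syn$genome, repeats = r$syn$repeats)
  expect_match(with_rep$pseudogene_evidence, "ADJACENT_TRANSPOSON")
  without <- flag_pseudogene(r$loci, r$syn$genome)
  expect_no_match(without$pseudogene_evidence, "ADJACENT_TRANSPOSON")
  expect_true(without$pseudogene)  # still a pseudogene via PARTIAL_DOMAIN
})

test_that("audit statuses reproduce the generator's truth", {
  r <- scan_once(data.frame(
    subfamily = c("IIc", "III", "I", "IIe"),
    corruption = "NONE",
    model_mode = c("TRUE", "BAD_MODEL", "TRUE", "NO_MODEL")),
    len = 7e4, seed = 43)
  rep <- audit_gene_models(r$loci, r$syn$models, r$syn$genome)
  truth <- r$syn$truth_genes[order(r$syn$truth_genes$start), ]
  expect_equal(rep$status, truth$expected_status)
  # statuses partition loci
  expect_equal(nrow(rep), nrow(r$loci))
  expect_true(all(rep$status %in% c("match", "mispredicted", "missing",
                                    "short")))
})

test_that("ATG-shift tolerance: moving the start codon never flips a match", {
  r <- scan_once(data.frame(subfamily = "IIc", corruption = "NONE",
                            model_mode = "TRUE"), len = 4e4, seed = 47)
  for (delta in c(-30L, 30L)) {
    shifted <- lapply(r$syn$models, shift_model_start, delta = delta)
    rep <- audit_gene_models(r$loci, shifted, r$syn$genome)
    expect_equal(rep$status, "match")
  }
})

test_that("short predicted proteins are reported as short, not incorrect", {
  r <- scan_once(data.frame(subfamily = "IIc", corruption = "NONE",
                            model_mode = "TRUE"), len = 4e4, seed = 53)
  rep <- audit_gene_models(r$loci, r$syn$models, r$syn$genome,
                           config = scan_config(min_protein_len = 500L))
  expect_equal(rep$status, "short")
})

test_that("summaries count the curated table and empty input exactly", {
  s <- summarize_family(load_table1_fixture())
  expect_equal(s$total, 86L)
  expect_equal(s$n_flagged, 20L)
  expect_equal(s$n_mispredicted + s$n_missing, s$n_flagged)
  expect_equal(s$n_pseudogenes, 3L)
  expect_equal(s$n_short, 2L)
  expect_equal(unname(s$per_subfamily[c("I", "IIa", "IIb", "IIc", "IId",
                                        "IIe", "III", "UNASSIGNED")]),
               c(15L, 3L, 6L, 21L, 6L, 10L, 23L, 2L))
  expect_equal(sum(s$per_subfamily), s$total)

  e <- summarize_family(load_table1_fixture()[0L, ])
  expect_equal(e$total, 0L)
  expect_equal(e$n_flagged, 0L)
  expect_equal(sum(e$per_subfamily), 0L)
})
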
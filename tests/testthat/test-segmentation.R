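test_that("find_motif handles fixed, degenerate and preferred positions", {
  expect_equal(find_motif("AAQCGGAA", "QCGG"), 3L)
  # two occurrences: first vs last
  s <- "QCGGAAAAQCGGAA"
  expect_equal(find_motif(s, "QCGG", pick = "first"), 1L)
  expect_equal(find_motif(s, "QCGG", pick = "last"), 9L)
  # degenerate fixed sets
  expect_equal(find_motif("ATNIKA", "[ST][ND]IK"), 2L)
  expect_equal(find_motif("ASDIKA", "[ST][ND]IK"), 2L)
  # preferred wildcards: best-scoring match wins, ties to earliest
  s2 <- "AAAQCAAASQCLAAA"   # xQCx at 3 (score 0) and SQCL at 9 (score 2)
  expect_equal(find_motif(s2, "(S)QC(L)", pick = "best"), 9L)
  expect_equal(find_motif(s2, "(S)QC(L)", pick = "first"), 3L)
  # no match -> NA
  expect_true(is.na(find_motif("AAAA", "QCGG")))
  # window limits the search
  expect_true(is.na(find_motif(s, "QCGG", window = c(2L, 6L))))
  expect_error(find_motif("AAA", "QCGG", window = c(1L, 10L)), "bounds")
  # a motif needs at least one fixed position
  expect_error(find_motif("AAA", "(S)(T)"), "fixed position")
})

test_that("each scheme recovers the generator's true linker exactly", {
  set.seed(101)
  for (cl in c("CBM1_GH6", "GH7_CBM1", "CBM2_GH6", "GH6_CBM2")) {
    for (i in 1:20) {
      p <- sample_protein(cl)
      s <- segment_record("r1", p$seq, cl)
      expect_equal(s$status, "ok", info = cl)
      expect_equal(s$linker, p$truth$linker, info = cl)
      # boundary indices match the truth table
      tab <- segmentation_table(list(s))
      expect_equal(tab$cbm_start, p$truth$cbm_start, info = cl)
      expect_equal(tab$cbm_end, p$truth$cbm_end, info = cl)
      expect_equal(tab$gh_start, p$truth$gh_start, info = cl)
      expect_equal(tab$gh_end, p$truth$gh_end, info = cl)
      # concatenation invariant on the post-trim sequence
      if (s$order == "cbm_first") {
        expect_equal(paste0(s$cbm, s$linker, s$gh), s$seq)
      } else {
        expect_equal(paste0(s$gh, s$linker, s$cbm), s$seq)
      }
      expect_gt(nchar(s$cbm), 0)
      expect_gt(nchar(s$gh), 0)
    }
  }
})

test_that("signal peptides are trimmed to 6 residues before QCGG", {
  set.seed(5)
  p <- sample_protein("CBM1_GH6")
  s <- segment_record("r", p$seq, "CBM1_GH6")
  expect_equal(s$trim_offset, p$truth$trim_offset)
  expect_equal(nchar(s$seq), nchar(p$seq) - p$truth$trim_offset)
  # post-trim sequence starts exactly 6 residues before QCGG
  expect_equal(find_motif(s$seq, "QCGG"), 7L)
})

test_that("missing anchors give failed status, never partial output", {
  expect_equal(segment_cbm1_gh6("r", "AAAASQCLAAAGNPFAAA")$status, "failed")
  expect_match(segment_cbm1_gh6("r", "AAAASQCLAAAGNPFAAA")$reason, "CBM1")
  expect_match(segment_gh7_cbm1("r", "AAAAAAAQCGGAAA")$reason, "GH7")
  # GH7: QCGG present only before the GH cut -> no CBM anchor
  seq <- paste0("AQCGGA", "TNIK", strrep("A", 9), strrep("G", 20))
  res <- segment_gh7_cbm1("r", seq)
  expect_equal(res$status, "failed")
  expect_match(res$reason, "CBM1")
  # CBM2_GH6: no cysteine in the leading window
  expect_match(segment_cbm2_gh6("r", paste0(strrep("A", 50), "RVDNAA"))$reason,
               "CBM2")
  # CBM2_GH6: YVD fallback when RVDN is absent
  seq2 <- paste0(strrep("A", 20), "C", "AG", strrep("T", 20), "YVD",
                 strrep("A", 30))
  res2 <- segment_cbm2_gh6("r", seq2)
  expect_equal(res2$status, "ok")
  expect_equal(res2$gh, paste0("YVD", strrep("A", 30)))
  # GH6_CBM2: missing FVML
  expect_match(segment_gh6_cbm2("r", strrep("A", 60))$reason, "GH6")
  expect_true(is.na(segment_cbm1_gh6("r", "AAAA")$cbm))
})

test_that("zero-length linkers are segmented as empty, status ok", {
  seq <- paste0(strrep("A", 8), "QCGG", strrep("G", 20), "SQCL",
                # no linker at all:
                "DDDDD", "GNPF", strrep("E", 30))
  s <- segment_cbm1_gh6("r", seq)
  expect_equal(s$status, "ok")
  expect_equal(s$linker, "")
  expect_equal(paste0(s$cbm, s$gh), s$seq)
})

test_that("GH6_CBM2 min_linker guard skips early hydrophobics", {
  # an L sits 3 residues into the linker (inside the min_linker guard);
  # the true CBM cysteine 14 residues downstream must still be chosen
  linker <- "TTLTTTTTTTTTTT"   # length 14, L at position 3
  seq <- paste0(strrep("A", 20), "FVML", strrep("G", 8), linker, "C",
                strrep("D", 20))
  s <- segment_gh6_cbm2("r", seq)
  expect_equal(s$status, "ok")
  expect_equal(s$linker, linker)
  expect_equal(substr(s$cbm, 1, 1), "C")
})

test_that("GH7_CBM1 cut sits 9 residues after the S/T-N/D-I-K motif", {
  linker <- strrep("S", 12)
  seq <- paste0(strrep("G", 30), "SDIK", strrep("A", 9), linker,
                strrep("T", 6), "QCGG", strrep("D", 20))
  s <- segment_gh7_cbm1("r", seq)
  expect_equal(s$status, "ok")
  expect_equal(nchar(s$gh), 30 + 4 + 9)
  expect_equal(s$linker, linker)
  expect_equal(nchar(s$cbm), 6 + 4 + 20)
})

test_that("batch_segment collects failures and keeps provenance", {
  set.seed(202)
  gen <- generate_dataset("CBM2_GH6", n = 25)
  res <- batch_segment(gen$dataset)
  expect_equal(res$linkers$n, 25L)
  expect_equal(nrow(res$failures), 0L)
  expect_equal(res$linkers$linkers$id, gen$dataset$records$id)
  # corrupt one record: failure reported, others unaffected
  ds <- gen$dataset
  ds$records$seq[3] <- gsub("C", "A", ds$records$seq[3])
  res2 <- batch_segment(ds)
  expect_equal(res2$linkers$n, 24L)
  expect_equal(res2$failures$id, ds$records$id[3])
  expect_match(res2$failures$reason, "CBM2")
  # scheme/label mismatch is refused
  expect_error(batch_segment(gen$dataset, "GH7_CBM1"), "does not match")
  # determinism: same input, same config -> identical output
  res3 <- batch_segment(gen$dataset)
  expect_identical(res$linkers$linkers, res3$linkers$linkers)
})
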
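test_that("the bundled Gonnet matrix is symmetric with known entries", {
  g <- gonnet250()
  expect_equal(dim(g), c(21, 21))
  expect_equal(g, t(g))
  expect_equal(g["C", "C"], 11.5)
  expect_equal(g["W", "W"], 14.2)
  expect_equal(g["S", "T"], 1.5)
  expect_true(all(g["X", ] == 0))
})

test_that("global_align on identical and near-identical sequences", {
  r <- global_align("PEPTIDE", "PEPTIDE")
  expect_equal(r$percent_identity, 100)
  expect_false(grepl("-", r$aligned_a))

  # one internal deletion: one gap column, 3 identities
  r2 <- global_align("PEPT", "PET")
  expect_equal(r2$identities, 3L)
  expect_equal(r2$aligned_columns, 4L)
  expect_equal(nchar(r2$aligned_a), 4L)
  expect_equal(sum(strsplit(r2$aligned_b, "")[[1]] == "-"), 1L)
  # removing gaps recovers the inputs
  expect_equal(gsub("-", "", r2$aligned_a), "PEPT")
  expect_equal(gsub("-", "", r2$aligned_b), "PET")

  expect_error(global_align("", "PEPT"), "empty")
})

test_that("gap costs follow the open + (L-1)*extend convention", {
  # A run of k gaps should cost 10 + (k-1)*0.05, not 10 + k*0.05
  a <- "CCCCWWCCCC"
  b <- "CCCCCCCC"
  r <- global_align(a, b)
  # expected: 8 C-C matches (8 * 11.5) minus one length-2 gap
  expect_equal(r$score, 8 * 11.5 - (10 + 0.05), tolerance = 1e-9)
})

test_that("alignment score equals the pure-R dynamic-programming oracle", {
  set.seed(61)
  for (i in 1:40) {
    a <- random_aa(sample(3:12, 1))
    b <- random_aa(sample(3:12, 1))
    expect_equal(global_align(a, b)$score, align_score_dp(a, b),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("the DP oracle itself equals literal exhaustive enumeration", {
  set.seed(62)
  for (i in 1:15) {
    a <- random_aa(sample(2:5, 1))
    b <- random_aa(sample(2:5, 1))
    expect_equal(align_score_dp(a, b), align_score_enum(a, b),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("alignment score agrees with Biostrings as independent check", {
  # Biostrings charges open + L*extend per gap, so equalise conventions by
  # reducing its opening penalty by one extension
  set.seed(63)
  for (i in 1:15) {
    a <- random_aa(sample(10:60, 1))
    b <- random_aa(sample(10:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = gonnet250(), type = "global",
      gapOpening = 10 - 0.05, gapExtension = 0.05, scoreOnly = TRUE)
    expect_equal(global_align(a, b)$score, ref, tolerance = 1e-4,
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric and self-identity is 100", {
  set.seed(64)
  for (i in 1:10) {
    a <- random_aa(sample(5:30, 1))
    b <- random_aa(sample(5:30, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
    expect_equal(global_align(a, a)$percent_identity, 100)
  }
})

test_that("percent identity excludes terminal overhangs from the denominator", {
  # b is a prefix of a: the trailing overhang must not dilute identity
  a <- "CCCCCWWWWW"
  b <- "CCCCC"
  r <- global_align(a, b)
  expect_equal(r$percent_identity, 100)
  expect_equal(r$aligned_columns, 5L)
})

test_that("identity_matrix and identity_histogram count all pairs", {
  seqs <- c(a = "CCCCCCCC", b = "CCCCCCCC", c = "CCCCCCCC")
  im <- identity_matrix(seqs)
  expect_equal(unname(diag(im$values)), rep(100, 3))
  expect_equal(im$values, t(im$values))
  h <- identity_histogram(im)
  expect_equal(sum(h$count), 3L)  # n(n-1)/2
  expect_equal(h$count[h$bin_start == 95], 3L)

  # 2 sequences -> a single pair
  h2 <- identity_histogram(c(x = "CCCC", y = "CCWC"))
  expect_equal(sum(h2$count), 1L)
  expect_error(identity_matrix("CCC"), ">= 2")

  set.seed(65)
  seqs3 <- replicate(6, random_aa(20))
  names(seqs3) <- paste0("s", 1:6)
  expect_equal(sum(identity_histogram(seqs3)$count), 15L)
})

test_that("linker identities sit left of structured-domain identities", {
  set.seed(66)
  gen <- generate_dataset("GH7_CBM1", n = 12)
  seg <- batch_segment(gen$dataset)
  ok <- Filter(function(s) s$status == "ok", seg$segments)
  doms <- function(d) {
    s <- vapply(ok, `[[`, character(1), d)
    names(s) <- vapply(ok, `[[`, character(1), "id")
    s
  }
  mean_pid <- function(seqs) {
    v <- identity_matrix(seqs)$values
    mean(v[upper.tri(v)])
  }
  pid_linker <- mean_pid(doms("linker"))
  pid_gh <- mean_pid(doms("gh"))
  pid_cbm <- mean_pid(doms("cbm"))
  expect_lt(pid_linker, pid_gh)
  expect_lt(pid_linker, pid_cbm)
})

test_that("subset_by_ec splits exo/endo and raises within-group identity", {
  set.seed(67)
  gen <- generate_dataset("GH7_CBM1", n = 20)
  split <- subset_by_ec(gen$dataset)
  expect_equal(nrow(split$exo$records) + nrow(split$endo$records), 20L)
  expect_true(all(startsWith(split$exo$records$ec_number, "3.2.1.91")))
  expect_true(all(split$endo$records$ec_number == "3.2.1.4"))

  # no EC metadata: everything unclassified
  ds <- gen$dataset
  ds$records$ec_number <- NA_character_
  split2 <- subset_by_ec(ds)
  expect_equal(nrow(split2$exo$records), 0L)
  expect_equal(nrow(split2$unclassified), 20L)

  # catalytic-domain identity: within-subfamily > between-subfamily
  seg <- batch_segment(gen$dataset)
  gh <- vapply(seg$segments, `[[`, character(1), "gh")
  names(gh) <- gen$dataset$records$id
  exo_ids <- split$exo$records$id
  endo_ids <- split$endo$records$id
  v <- identity_matrix(gh)$values
  within <- c(v[exo_ids, exo_ids][upper.tri(diag(length(exo_ids)))],
              v[endo_ids, endo_ids][upper.tri(diag(length(endo_ids)))])
  between <- as.vector(v[exo_ids, endo_ids])
  expect_gt(mean(within), mean(between))
})

test_that("nj_tree recovers a 4-taxon additive metric exactly", {
  # quartet ((A,B),(C,D)) with internal edge 3
  # dAB=2, dCD=2, dAC=dAD=dBC=dBD=5
  d <- matrix(c(0, 2, 5, 5,
                2, 0, 5, 5,
                5, 5, 0, 2,
                5, 5, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- nj_tree(100 - d)
  expect_s3_class(tree, "phylo")
  coph <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(coph, d, tolerance = 1e-9)
  # serializes to valid Newick
  f <- tempfile(fileext = ".nwk")
  write_newick(tree, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, LETTERS[1:4])

  expect_error(nj_tree(matrix(100, 2, 2)), ">= 3")
  m <- matrix(c(100, 1, 2, 100), 2, 2)
  expect_error(nj_tree(rbind(cbind(m, 3), c(9, 9, 100))), "symmetric")
})

test_that("outlier records form their own clade in the NJ tree", {
  set.seed(68)
  gen <- generate_dataset("CBM1_GH6", n = 12, n_outliers = 5)
  recs <- gen$dataset$records
  im <- identity_matrix(setNames(recs$seq, recs$id))
  tree <- nj_tree(im)
  out_ids <- recs$id[recs$subset_flag == "ruminal_fungi"]
  core_ids <- setdiff(recs$id, out_ids)
  rooted <- ape::root(tree, outgroup = core_ids[1], resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, out_ids))
})
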
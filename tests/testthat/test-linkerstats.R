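test_that("length_stats matches hand arithmetic and its invariants", {
  s <- length_stats(c(10, 10, 10))
  expect_equal(s$average, 10)
  expect_equal(s$sd, 0)
  expect_equal(s$range, 0)

  s2 <- length_stats(c(16, 30, 47))
  expect_equal(round(s2$average), 31)
  expect_equal(s2$median, 30)
  expect_equal(s2$range, 31)
  expect_equal(s2$sd, sd(c(16, 30, 47)))  # sample (n-1) convention

  # even n: midpoint median; permutation invariance
  lens <- c(4, 8, 15, 16)
  expect_equal(length_stats(lens)$median, 11.5)
  expect_identical(length_stats(lens), length_stats(rev(lens)))
  expect_true(s2$min <= s2$median && s2$median <= s2$max)
  expect_error(length_stats(numeric(0)), "empty")
})

test_that("length_histogram uses half-open 5-residue bins summing to n", {
  h <- length_histogram(c(4, 5, 6), bin_width = 5)
  expect_equal(h$count, c(1, 2))
  expect_equal(h$bin_start, c(0, 5))
  expect_equal(nrow(length_histogram(numeric(0))), 0L)
  expect_error(length_histogram(c(1, 2), bin_width = 0), "bin_width")
  # brute-force count comparison on uniform lengths
  set.seed(3)
  lens <- floor(runif(100, 0, 50))
  h2 <- length_histogram(lens, 5)
  expect_equal(sum(h2$count), 100)
  brute <- vapply(0:9, function(b) sum(lens >= 5 * b & lens < 5 * (b + 1)),
                  integer(1))
  expect_equal(h2$count[1:10], brute)
})

test_that("ttest_lengths is the pooled-variance Student's t", {
  # identical samples: t = 0, p = 1
  tt <- ttest_lengths(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_false(tt$significant_95)

  # closed-form check against the textbook formula
  x <- c(1, 2, 3); y <- c(11, 12, 13)
  tt2 <- ttest_lengths(x, y)
  sp <- sqrt(((2 * var(x)) + (2 * var(y))) / 4)
  t_manual <- (mean(x) - mean(y)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(tt2$t, t_manual)
  expect_equal(tt2$df, 4)
  expect_true(tt2$significant_95)

  # antisymmetry
  tt3 <- ttest_lengths(y, x)
  expect_equal(tt3$t, -tt2$t)
  expect_equal(tt3$p, tt2$p)

  expect_error(ttest_lengths(c(1), c(1, 2)), "n >= 2")

  # Welch variant differs when variances do
  set.seed(4)
  a <- rnorm(20, 10, 1); b <- rnorm(8, 12, 6)
  expect_false(isTRUE(all.equal(ttest_lengths(a, b)$df,
                                ttest_lengths(a, b, welch = TRUE)$df)))
})

test_that("composition_vs_length recovers exact linear relations", {
  # constant 50% S+T regardless of length: slope 0
  ls <- make_linker_set(c("STAB" = "STGA", "x" = "SSTTGGAA",
                          "y" = "SSSTTTGGGAAA"),
                        ids = c("a", "b", "c"))
  tr <- suppressWarnings(composition_vs_length(ls, c("S", "T")))
  expect_equal(tr$fit$slope, 0, tolerance = 1e-12)
  expect_equal(tr$fit$intercept, 50, tolerance = 1e-9)

  # exact line: r_squared 1 (P fraction rises linearly with length)
  mk <- function(L, nP) paste0(strrep("P", nP), strrep("A", L - nP))
  seqs <- c(mk(10, 2), mk(20, 6), mk(40, 14))  # percent = 20, 30, 35
  ls2 <- make_linker_set(seqs)
  tr2 <- composition_vs_length(ls2, "P")
  expect_gt(tr2$fit$slope, 0)
  expect_equal(tr2$fit$r_squared,
               summary(lm(c(20, 30, 35) ~ c(10, 20, 40)))$r.squared)

  # zero-length linkers excluded with a warning
  ls3 <- make_linker_set(c("SSSS", "", "SSTTT"))
  expect_warning(tr3 <- composition_vs_length(ls3, "S"), "zero-length")
  expect_equal(nrow(tr3$points), 2L)

  # identical lengths: slope undefined
  ls4 <- make_linker_set(c("SSSS", "STTT"))
  expect_error(composition_vs_length(ls4, "S"), "identical")
})

test_that("generator trend coupling shows up as a proline slope", {
  set.seed(77)
  specs <- default_class_specs()
  bact <- linker_set(paste0("b", 1:120),
                     vapply(1:120, function(i) sample_linker(specs$CBM2_GH6),
                            character(1)), label = "bact")
  euk <- linker_set(paste0("e", 1:120),
                    vapply(1:120, function(i) sample_linker(specs$GH7_CBM1),
                           character(1)), label = "euk")
  tr_b <- composition_vs_length(bact, "P")
  tr_e <- composition_vs_length(euk, "P")
  expect_gt(tr_b$fit$slope, 0.1)       # ~0.3 %/residue by construction
  expect_lt(abs(tr_e$fit$slope), 0.15) # no coupling for eukaryotic linkers
})

test_that("genus_overlap is directional set arithmetic", {
  mk_ds <- function(genera, label = "GH7_CBM1") {
    n <- length(genera)
    fa <- data.frame(id = paste0("g", seq_len(n)), desc = "",
                     seq = rep("PEPT", n), stringsAsFactors = FALSE)
    md <- data.frame(id = fa$id, organism = paste(genera, "sp."),
                     genus = genera, dataset = label, subset_flag = "core",
                     ec_number = NA_character_, stringsAsFactors = FALSE)
    assemble_dataset(fa, md, label)
  }
  A <- mk_ds(c("X", "Y", "Z", "W", "V"))
  B <- mk_ds(c("x", "y", "z", "w", "Q"))  # case-insensitive
  expect_equal(genus_overlap(A, B), 80)
  expect_equal(genus_overlap(A, A), 100)
  expect_equal(genus_overlap(mk_ds(c("A", "B")), mk_ds(c("C", "D"))), 0)
  noann <- mk_ds("X")
  noann$records$genus <- NA_character_
  expect_error(genus_overlap(noann, A), "genus")
})

test_that("report tables have the survey layout", {
  set.seed(9)
  sets <- list(
    GH7_CBM1 = make_linker_set(replicate(10, random_aa(30))),
    CBM1_GH6 = make_linker_set(replicate(10, random_aa(42))))
  tab <- report_length_table(sets)
  expect_equal(names(tab)[1:8],
               c("label", "average", "median", "max", "min", "range", "sd", "n"))
  expect_equal(tab$average, round(tab$average_exact))
  tt <- report_ttest_matrix(sets)
  expect_equal(nrow(tt), 1L)  # one unordered pair
})
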
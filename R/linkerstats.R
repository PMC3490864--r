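# Length statistics, histograms, two-sample tests, composition-vs-length
# trends and genus-overlap measures on linker sets.

linker_lengths <- function(x) {
  if (inherits(x, "linker_set")) return(x$linkers$length)
  if (is.numeric(x)) return(x)
  stop("expected a linker_set or a numeric vector of lengths")
}

#' Summary length statistics for a linker set
#'
#' Mean, median (midpoint convention for even n), extremes, range and the
#' sample (n-1) standard deviation of the linker lengths. The mean is kept
#' at full precision; survey-style reports round it to an integer (see
#' [report_length_table()]).
#'
#' @param x A `linker_set` or numeric vector of lengths.
#' @return A list of class `length_stats`: `average`, `median`, `max`,
#'   `min`, `range`, `sd`, `n`.
#' @export
length_stats <- function(x) {
  len <- linker_lengths(x)
  if (length(len) < 1L) stop("length_stats: empty linker set")
  structure(list(average = mean(len), median = stats::median(len),
                 max = max(len), min = min(len), range = max(len) - min(len),
                 sd = if (length(len) > 1L) stats::sd(len) else 0,
                 n = length(len)),
            class = "length_stats")
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf(
    "<length_stats> n=%d  average=%d  median=%g  max=%d  min=%d  range=%d  sd=%.1f\n",
    x$n, round(x$average), x$median, x$max, x$min, x$range, x$sd))
  invisible(x)
}

#' Histogram of linker lengths
#'
#' Counts lengths in half-open bins `[0,w), [w,2w), ...` of width `w`
#' residues (default 5, the convention used for linker-length
#' distributions).
#'
#' @param x A `linker_set` or numeric vector of lengths.
#' @param bin_width Bin width in residues (>= 1).
#' @return A data.frame `bin_start`, `bin_end`, `count`; counts sum to n.
#'   Empty input yields a zero-row data.frame.
#' @export
length_histogram <- function(x, bin_width = 5L) {
  if (bin_width < 1) stop("bin_width must be >= 1")
  len <- linker_lengths(x)
  if (length(len) == 0L) {
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0)))
  }
  idx <- floor(len / bin_width)
  tab <- table(factor(idx, levels = 0:max(idx)))
  data.frame(bin_start = as.numeric(names(tab)) * bin_width,
             bin_end = (as.numeric(names(tab)) + 1) * bin_width,
             count = as.integer(tab))
}

#' Two-sample Student's t-test on linker lengths
#'
#' Classic pooled-variance two-sample two-tailed Student's t by default
#' (`welch = TRUE` gives the unequal-variance variant). Significance is
#' assessed at the 95% confidence level.
#'
#' @param a,b `linker_set`s or numeric length vectors, each with n >= 2.
#' @param welch Use Welch's unequal-variance variant.
#' @return A list of class `linker_ttest`: `t`, `df`, `p`,
#'   `significant_95`.
#' @export
ttest_lengths <- function(a, b, welch = FALSE) {
  x <- linker_lengths(a); y <- linker_lengths(b)
  if (length(x) < 2L || length(y) < 2L) {
    stop("ttest_lengths: both samples need n >= 2")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # degenerate: both samples constant
    if (mean(x) == mean(y)) {
      res <- list(t = 0, df = length(x) + length(y) - 2, p = 1)
    } else {
      res <- list(t = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p = 0)
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = !welch)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(c(res, list(significant_95 = res$p < 0.05)),
            class = "linker_ttest")
}

#' @export
print.linker_ttest <- function(x, ...) {
  cat(sprintf("<linker_ttest> t=%.3f df=%.1f p=%.3g %s at 95%%\n",
              x$t, x$df, x$p,
              if (x$significant_95) "significant" else "not significant"))
  invisible(x)
}

#' Residue-group content as a function of linker length
#'
#' For each linker: x = length, y = 100 * (count of residues in
#' `residue_group`) / length. An ordinary least-squares line is fitted
#' through the points (used to ask e.g. whether proline content rises with
#' length in bacterial linkers but not eukaryotic ones). Zero-length
#' linkers are excluded with a warning (no composition is defined for
#' them).
#'
#' @param x A `linker_set`.
#' @param residue_group Character vector of residues, e.g. `c("S","T")`.
#' @return A list of class `composition_trend`: `points` (data.frame `id`,
#'   `length`, `percent`) and `fit` (`slope`, `intercept`, `r_squared`).
#' @export
composition_vs_length <- function(x, residue_group) {
  stopifnot(inherits(x, "linker_set"), length(residue_group) > 0)
  df <- x$linkers
  zero <- df$length == 0L
  if (any(zero)) {
    warning("excluding ", sum(zero), " zero-length linker(s) from composition")
    df <- df[!zero, , drop = FALSE]
  }
  if (nrow(df) < 2L) stop("composition_vs_length: need >= 2 non-empty linkers")
  counts <- vapply(strsplit(df$seq, ""), function(ch) {
    sum(ch %in% residue_group)
  }, numeric(1))
  pts <- data.frame(id = df$id, length = df$length,
                    percent = 100 * counts / df$length,
                    stringsAsFactors = FALSE)
  if (length(unique(pts$length)) < 2L) {
    stop("composition_vs_length: all lengths identical, slope undefined")
  }
  fit <- stats::lm(percent ~ length, data = pts)
  structure(list(points = pts,
                 fit = list(slope = unname(stats::coef(fit)[2]),
                            intercept = unname(stats::coef(fit)[1]),
                            r_squared = summary(fit)$r.squared)),
            class = "composition_trend")
}

#' @export
print.composition_trend <- function(x, ...) {
  cat(sprintf(
    "<composition_trend> n=%d  slope=%.3f %%/res  intercept=%.1f%%  R^2=%.3f\n",
    nrow(x$points), x$fit$slope, x$fit$intercept, x$fit$r_squared))
  invisible(x)
}

#' Percentage of one dataset's genera present in another
#'
#' `100 * |genera(A) intersect genera(B)| / |genera(A)|`, genera
#' deduplicated and compared case-insensitively. Used to rule out
#' sequencing bias as the source of between-dataset linker differences.
#'
#' @param a,b `cellu_dataset`s with genus metadata.
#' @return A single percentage.
#' @export
genus_overlap <- function(a, b) {
  stopifnot(inherits(a, "cellu_dataset"), inherits(b, "cellu_dataset"))
  ga <- unique(tolower(a$records$genus[!is.na(a$records$genus) &
                                         nzchar(a$records$genus)]))
  gb <- unique(tolower(b$records$genus[!is.na(b$records$genus) &
                                         nzchar(b$records$genus)]))
  if (length(ga) == 0L) stop("genus_overlap: first dataset has no genus annotations")
  100 * length(intersect(ga, gb)) / length(ga)
}

#' Survey-style length table over several linker sets
#'
#' One row per set with the rounded average (matching how such tables are
#' conventionally printed) alongside median, extremes, range, sample SD
#' and n; full-precision averages are in `average_exact`.
#'
#' @param sets Named list of `linker_set`s.
#' @return A data.frame.
#' @export
report_length_table <- function(sets) {
  rows <- lapply(names(sets), function(nm) {
    s <- length_stats(sets[[nm]])
    data.frame(label = nm, average = round(s$average),
               median = s$median, max = s$max, min = s$min,
               range = s$range, sd = s$sd, n = s$n,
               average_exact = s$average, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise t-test matrix over several linker sets
#'
#' @param sets Named list of `linker_set`s.
#' @param welch Use Welch's variant.
#' @return A data.frame with one row per unordered pair: `a`, `b`, `t`,
#'   `df`, `p`, `significant_95`.
#' @export
report_ttest_matrix <- function(sets, welch = FALSE) {
  nms <- names(sets)
  rows <- list()
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      tt <- ttest_lengths(sets[[i]], sets[[j]], welch = welch)
      rows[[length(rows) + 1L]] <-
        data.frame(a = nms[i], b = nms[j], t = tt$t, df = tt$df, p = tt$p,
                   significant_95 = tt$significant_95,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
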
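# Motif-anchored segmentation of multidomain cellulases into
# CBM / linker / catalytic (GH) domain.
#
# Motif pattern mini-language:
#   "QCGG"      four fixed positions
#   "[ST][ND]IK" fixed alternative sets (position must be S or T, etc.)
#   "(S)QC(L)"  parenthesised positions are preferred-but-not-required
#               wildcards: any residue matches, matches are *scored* by the
#               number of preferred residues present (pick = "best").
# All coordinates in this file are 1-based inclusive.

parse_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  pos <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- which(chars == ")" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unbalanced '(' in motif: ", pattern)
      pos[[length(pos) + 1L]] <- list(kind = "pref", set = chars[(i + 1L):(j - 1L)])
      i <- j + 1L
    } else if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unbalanced '[' in motif: ", pattern)
      pos[[length(pos) + 1L]] <- list(kind = "fixed", set = chars[(i + 1L):(j - 1L)])
      i <- j + 1L
    } else {
      pos[[length(pos) + 1L]] <- list(kind = "fixed", set = ch)
      i <- i + 1L
    }
  }
  if (!any(vapply(pos, function(p) p$kind == "fixed", logical(1)))) {
    stop("motif must have at least one fixed position: ", pattern)
  }
  pos
}

#' Locate a motif in a sequence
#'
#' Scans `seq` for matches to `motif` within `window`. A position matches
#' when every fixed motif position matches; parenthesised (preferred)
#' positions always match but contribute +1 to the match score when the
#' preferred residue is present. `pick = "best"` returns the highest-scoring
#' match, ties broken by the earliest position.
#'
#' @param seq An amino-acid string.
#' @param motif Motif pattern (see Details in the package vignette), e.g.
#'   `"QCGG"`, `"(S)QC(L)"`, `"[ST][ND]IK"`.
#' @param window Integer pair `c(start, end)`: 1-based inclusive bounds on
#'   the match *start* position. Defaults to the whole sequence.
#' @param pick One of `"first"`, `"last"`, `"best"`.
#' @return The 1-based start index of the selected match, or `NA_integer_`
#'   when there is no match in the window.
#' @export
find_motif <- function(seq, motif, window = NULL, pick = c("first", "last", "best")) {
  pick <- match.arg(pick)
  pos <- if (is.character(motif)) parse_motif(motif) else motif
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- length(pos)
  if (is.null(window)) window <- c(1L, L)
  if (window[1] < 1L || window[2] > L) stop("window outside sequence bounds")
  last_start <- min(window[2], L - k + 1L)
  if (last_start < window[1]) return(NA_integer_)
  starts <- integer(0)
  scores <- integer(0)
  for (s in window[1]:last_start) {
    ok <- TRUE
    sc <- 0L
    for (j in seq_len(k)) {
      p <- pos[[j]]
      r <- chars[s + j - 1L]
      if (p$kind == "fixed") {
        if (!(r %in% p$set)) { ok <- FALSE; break }
      } else if (r %in% p$set) {
        sc <- sc + 1L
      }
    }
    if (ok) { starts <- c(starts, s); scores <- c(scores, sc) }
  }
  if (length(starts) == 0L) return(NA_integer_)
  switch(pick,
         first = starts[1L],
         last  = starts[length(starts)],
         best  = starts[which.max(scores)])  # which.max ties -> earliest
}

#' Default segmentation scheme parameters
#'
#' Returns the motif-anchored cutting rules for one of the four
#' architectures as a plain list, so individual motifs, offsets and windows
#' can be overridden without code changes (see [segment_record()]).
#'
#' @param name Architecture name.
#' @return A list of class `segmentation_scheme`.
#' @export
segmentation_scheme <- function(name = DATASET_LABELS) {
  name <- match.arg(name)
  params <- switch(name,
    CBM1_GH6 = list(
      # signal trim: drop residues more than `signal_keep` N-terminal to QCGG
      trim_motif = "QCGG", signal_keep = 6L,
      # CBM/linker cut: after the (S)QC(L) motif, searched past QCGG
      cbm_motif = "(S)QC(L)",
      # linker/GH cut: 5 residues N-terminal to the (G)N(P)(F) motif start
      gh_motif = "(G)N(P)(F)", gh_offset = 5L),
    GH7_CBM1 = list(
      # GH/linker cut: 9 residues after the last residue of [ST][ND]IK
      gh_motif = "[ST][ND]IK", gh_tail = 9L,
      # linker/CBM cut: 6 residues N-terminal to QCGG, searched past GH cut
      cbm_motif = "QCGG", cbm_offset = 6L),
    CBM2_GH6 = list(
      # CBM/linker cut: 2 residues C-terminal to the last Cys in the leading
      # window (~ signal peptide + CBM2 length)
      cys_window = 140L, cys_tail = 2L,
      # linker/GH cut: at RVDN, falling back to YVD
      gh_motif = "RVDN", gh_fallback = "YVD"),
    GH6_CBM2 = list(
      # GH/linker cut: 8 residues after the last residue of FVML
      gh_motif = "FVML", gh_tail = 8L,
      # linker/CBM cut: first C/L/I/F at least min_linker residues
      # downstream of the GH cut (guards against firing inside the GH tail)
      cbm_set = c("C", "L", "I", "F"), min_linker = 10L))
  structure(c(list(name = name), params), class = "segmentation_scheme")
}

seg_fail <- function(id, scheme, seq, reason) {
  structure(list(id = id, scheme = scheme, seq = seq, trim_offset = 0L,
                 cbm = NA_character_, linker = NA_character_,
                 gh = NA_character_, boundaries = NULL,
                 status = "failed", reason = reason),
            class = "segmented_protein")
}

seg_ok <- function(id, scheme, seq, trim_offset, cut1, cut2, order) {
  # cut1/cut2: 1-based inclusive end of first segment and of linker, on the
  # post-trim sequence; order is "cbm_first" or "gh_first".
  L <- nchar(seq)
  first  <- substr(seq, 1L, cut1)
  linker <- if (cut2 >= cut1 + 1L) substr(seq, cut1 + 1L, cut2) else ""
  last   <- substr(seq, cut2 + 1L, L)
  b <- c(first_start = 1L, first_end = cut1,
         linker_start = if (cut2 > cut1) cut1 + 1L else NA_integer_,
         linker_end = if (cut2 > cut1) cut2 else NA_integer_,
         last_start = cut2 + 1L, last_end = L)
  if (order == "cbm_first") {
    res <- list(cbm = first, linker = linker, gh = last)
  } else {
    res <- list(cbm = last, linker = linker, gh = first)
  }
  structure(c(list(id = id, scheme = scheme, seq = seq,
                   trim_offset = trim_offset),
              res,
              list(boundaries = b, order = order,
                   status = "ok", reason = NA_character_)),
            class = "segmented_protein")
}

#' @export
print.segmented_protein <- function(x, ...) {
  cat("<segmented_protein> ", x$id, " [", x$scheme, "] status=", x$status,
      sep = "")
  if (x$status == "ok") {
    cat("  cbm=", nchar(x$cbm), " linker=", nchar(x$linker),
        " gh=", nchar(x$gh), " res", sep = "")
  } else {
    cat("  (", x$reason, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

segment_cbm1_gh6_impl <- function(id, seq, sch) {
  q <- find_motif(seq, sch$trim_motif, pick = "first")
  if (is.na(q)) return(seg_fail(id, sch$name, seq, "no CBM1 anchor"))
  trim_start <- max(1L, q - sch$signal_keep)
  trim_offset <- trim_start - 1L
  s2 <- substr(seq, trim_start, nchar(seq))
  q2 <- q - trim_offset
  L <- nchar(s2)
  # CBM/linker boundary: (S)QC(L), searched past the QCGG anchor
  m_start <- q2 + 4L
  if (m_start > L - 3L) return(seg_fail(id, sch$name, s2, "no CBM1 anchor"))
  m <- find_motif(s2, sch$cbm_motif, window = c(m_start, L), pick = "best")
  if (is.na(m)) return(seg_fail(id, sch$name, s2, "no CBM1 anchor"))
  cut1 <- m + 3L                      # CBM keeps the full 4-residue motif
  # linker/GH boundary: GH starts gh_offset residues before (G)N(P)(F)
  if (cut1 + 1L > L) return(seg_fail(id, sch$name, s2, "no GH6 anchor"))
  g <- find_motif(s2, sch$gh_motif, window = c(cut1 + 1L, L), pick = "best")
  if (is.na(g)) return(seg_fail(id, sch$name, s2, "no GH6 anchor"))
  gh_start <- g - sch$gh_offset
  if (gh_start < cut1 + 1L) return(seg_fail(id, sch$name, s2, "no GH6 anchor"))
  seg_ok(id, sch$name, s2, trim_offset, cut1, gh_start - 1L, "cbm_first")
}

segment_gh7_cbm1_impl <- function(id, seq, sch) {
  t0 <- find_motif(seq, sch$gh_motif, pick = "first")
  if (is.na(t0)) return(seg_fail(id, sch$name, seq, "no GH7 anchor"))
  cut1 <- t0 + 3L + sch$gh_tail       # GH keeps motif + gh_tail residues
  L <- nchar(seq)
  if (cut1 >= L) return(seg_fail(id, sch$name, seq, "no CBM1 anchor"))
  q <- find_motif(seq, sch$cbm_motif, window = c(cut1 + 1L, L), pick = "first")
  if (is.na(q)) return(seg_fail(id, sch$name, seq, "no CBM1 anchor"))
  cbm_start <- q - sch$cbm_offset
  if (cbm_start < cut1 + 1L) return(seg_fail(id, sch$name, seq, "no CBM1 anchor"))
  seg_ok(id, sch$name, seq, 0L, cut1, cbm_start - 1L, "gh_first")
}

segment_cbm2_gh6_impl <- function(id, seq, sch) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  win <- min(sch$cys_window, L)
  cys <- which(chars[seq_len(win)] == "C")
  if (length(cys) == 0L) return(seg_fail(id, sch$name, seq, "no CBM2 anchor"))
  cut1 <- cys[length(cys)] + sch$cys_tail
  if (cut1 >= L) return(seg_fail(id, sch$name, seq, "no GH6 anchor"))
  g <- find_motif(seq, sch$gh_motif, window = c(cut1 + 1L, L), pick = "first")
  if (is.na(g)) {
    g <- find_motif(seq, sch$gh_fallback, window = c(cut1 + 1L, L), pick = "first")
  }
  if (is.na(g)) return(seg_fail(id, sch$name, seq, "no GH6 anchor"))
  seg_ok(id, sch$name, seq, 0L, cut1, g - 1L, "cbm_first")
}

segment_gh6_cbm2_impl <- function(id, seq, sch) {
  f <- find_motif(seq, sch$gh_motif, pick = "first")
  if (is.na(f)) return(seg_fail(id, sch$name, seq, "no GH6 anchor"))
  cut1 <- f + 3L + sch$gh_tail
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  from <- cut1 + sch$min_linker + 1L
  if (from > L) return(seg_fail(id, sch$name, seq, "no CBM2 anchor"))
  hits <- which(chars[from:L] %in% sch$cbm_set)
  if (length(hits) == 0L) return(seg_fail(id, sch$name, seq, "no CBM2 anchor"))
  cbm_start <- from + hits[1L] - 1L
  seg_ok(id, sch$name, seq, 0L, cut1, cbm_start - 1L, "gh_first")
}

#' Segment one protein record into CBM, linker and GH domain
#'
#' Applies the motif-anchored cutting rules of the record's architecture.
#' Never errors on biologically malformed input: a record whose anchors
#' cannot be located is returned with `status = "failed"` and a reason.
#'
#' @param id Record id (for provenance).
#' @param seq Full-length amino-acid sequence.
#' @param scheme A `segmentation_scheme` or an architecture name.
#' @return A `segmented_protein`.
#' @export
segment_record <- function(id, seq, scheme) {
  if (is.character(scheme)) scheme <- segmentation_scheme(scheme)
  stopifnot(inherits(scheme, "segmentation_scheme"))
  switch(scheme$name,
         CBM1_GH6 = segment_cbm1_gh6_impl(id, seq, scheme),
         GH7_CBM1 = segment_gh7_cbm1_impl(id, seq, scheme),
         CBM2_GH6 = segment_cbm2_gh6_impl(id, seq, scheme),
         GH6_CBM2 = segment_gh6_cbm2_impl(id, seq, scheme))
}

#' @rdname segment_record
#' @export
segment_cbm1_gh6 <- function(id, seq) segment_record(id, seq, "CBM1_GH6")

#' @rdname segment_record
#' @export
segment_gh7_cbm1 <- function(id, seq) segment_record(id, seq, "GH7_CBM1")

#' @rdname segment_record
#' @export
segment_cbm2_gh6 <- function(id, seq) segment_record(id, seq, "CBM2_GH6")

#' @rdname segment_record
#' @export
segment_gh6_cbm2 <- function(id, seq) segment_record(id, seq, "GH6_CBM2")

#' Construct a linker set
#'
#' A `linker_set` is the unit of all downstream statistics: a labelled
#' collection of linker sequences with per-linker provenance.
#'
#' @param id,seq,subset_flag Per-linker vectors (recycled flags allowed).
#' @param label Dataset class label.
#' @return A `linker_set`: list with `label` and data.frame `linkers`
#'   (`id`, `seq`, `subset_flag`, `length`).
#' @export
linker_set <- function(id, seq, subset_flag = "core", label = NA_character_) {
  if (anyDuplicated(id)) stop("duplicate linker id(s)")
  df <- data.frame(id = as.character(id), seq = as.character(seq),
                   subset_flag = rep_len(as.character(subset_flag), length(id)),
                   length = nchar(as.character(seq)),
                   stringsAsFactors = FALSE)
  structure(list(label = label, linkers = df, n = nrow(df)),
            class = "linker_set")
}

#' @export
print.linker_set <- function(x, ...) {
  cat("<linker_set> ", x$label, ": n=", x$n, sep = "")
  if (x$n > 0) {
    cat(", lengths ", min(x$linkers$length), "-", max(x$linkers$length), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Segment every record of a dataset
#'
#' Applies the architecture's scheme to each record. Failures are collected
#' in a report, never silently dropped.
#'
#' @param dataset A `cellu_dataset`.
#' @param scheme Optional `segmentation_scheme`; defaults to the scheme
#'   named by the dataset label.
#' @return A list with `linkers` (a `linker_set` of the successfully
#'   segmented records), `segments` (list of `segmented_protein`), and
#'   `failures` (data.frame `id`, `reason`).
#' @export
batch_segment <- function(dataset, scheme = NULL) {
  stopifnot(inherits(dataset, "cellu_dataset"))
  if (is.null(scheme)) scheme <- segmentation_scheme(dataset$label)
  if (is.character(scheme)) scheme <- segmentation_scheme(scheme)
  if (scheme$name != dataset$label) {
    stop("scheme ", scheme$name, " does not match dataset label ",
         dataset$label)
  }
  recs <- dataset$records
  segs <- lapply(seq_len(nrow(recs)), function(i) {
    segment_record(recs$id[i], recs$seq[i], scheme)
  })
  ok <- vapply(segs, function(s) s$status == "ok", logical(1))
  failures <- data.frame(
    id = vapply(segs[!ok], `[[`, character(1), "id"),
    reason = vapply(segs[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  ls <- linker_set(id = recs$id[ok],
                   seq = vapply(segs[ok], `[[`, character(1), "linker"),
                   subset_flag = recs$subset_flag[ok],
                   label = dataset$label)
  list(linkers = ls, segments = segs, failures = failures)
}

#' Tabulate segmentation boundaries
#'
#' One row per record with 1-based inclusive start/end positions of each
#' domain on the (post-signal-trim) sequence, suitable for TSV export.
#'
#' @param segments A list of `segmented_protein` (e.g. from
#'   [batch_segment()]).
#' @return A data.frame with columns `id`, `scheme`, `cbm_start`, `cbm_end`,
#'   `linker_start`, `linker_end`, `gh_start`, `gh_end`, `status`.
#' @export
segmentation_table <- function(segments) {
  rows <- lapply(segments, function(s) {
    if (s$status != "ok") {
      return(data.frame(id = s$id, scheme = s$scheme,
                        cbm_start = NA_integer_, cbm_end = NA_integer_,
                        linker_start = NA_integer_, linker_end = NA_integer_,
                        gh_start = NA_integer_, gh_end = NA_integer_,
                        status = paste0("failed:", s$reason),
                        stringsAsFactors = FALSE))
    }
    b <- s$boundaries
    if (s$order == "cbm_first") {
      cbm <- b[c("first_start", "first_end")]; gh <- b[c("last_start", "last_end")]
    } else {
      gh <- b[c("first_start", "first_end")]; cbm <- b[c("last_start", "last_end")]
    }
    data.frame(id = s$id, scheme = s$scheme,
               cbm_start = cbm[1], cbm_end = cbm[2],
               linker_start = b[["linker_start"]],
               linker_end = b[["linker_end"]],
               gh_start = gh[1], gh_end = gh[2],
               status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
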
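# Amino-acid composition, 11-bin positional residue-density profiles, and
# N-glycosylation sequon statistics.

#' Pooled amino-acid composition of a linker set
#'
#' Counts are pooled over all linkers before division, so long linkers
#' contribute proportionally to their length.
#'
#' @param x A `linker_set` with at least one non-empty linker.
#' @return A list of class `composition_profile`: `fractions` (named
#'   vector over the full alphabet, zeros included) and `total_residues`.
#' @export
aa_composition <- function(x) {
  stopifnot(inherits(x, "linker_set"))
  seqs <- x$linkers$seq[x$linkers$length > 0L]
  if (length(seqs) == 0L) stop("aa_composition: no non-empty linkers")
  chars <- unlist(strsplit(seqs, ""), use.names = FALSE)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  total <- length(chars)
  structure(list(fractions = stats::setNames(as.numeric(counts) / total,
                                             AA_ALPHABET),
                 counts = stats::setNames(as.integer(counts), AA_ALPHABET),
                 total_residues = total),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, digits = 3, ...) {
  cat("<composition_profile> total residues:", x$total_residues, "\n")
  fr <- sort(x$fractions[x$fractions > 0], decreasing = TRUE)
  print(round(fr, digits))
  invisible(x)
}

#' Positional residue-density profile
#'
#' Each linker is split from N- to C-terminus into `n_bins` approximately
#' equal sections: residue `i` (1-based) of a length-`L` linker is assigned
#' to bin `floor((i-1) * n_bins / L) + 1`, so remainder residues land in
#' the later bins. Group counts and position counts are pooled across the
#' set per bin *before* division, i.e. the per-bin density is (group
#' residues in bin) / (total residues in bin). Used to ask where putative
#' O-glycosylation sites (S/T), glycines, or prolines sit along linkers.
#'
#' @param x A `linker_set`.
#' @param residue_group Character vector of residues, e.g. `c("S","T")`.
#' @param n_bins Number of sections (default 11).
#' @return A list of class `positional_profile`: `n_bins`,
#'   `residue_group`, `per_bin_fraction`, `per_bin_group`,
#'   `per_bin_positions`.
#' @export
positional_profile <- function(x, residue_group, n_bins = 11L) {
  stopifnot(inherits(x, "linker_set"), n_bins >= 1L,
            length(residue_group) > 0)
  keep <- x$linkers$length >= 1L
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " empty linker(s)")
  }
  seqs <- x$linkers$seq[keep]
  grp <- integer(n_bins)
  tot <- integer(n_bins)
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    bins <- floor((seq_len(L) - 1L) * n_bins / L) + 1L
    tot <- tot + tabulate(bins, nbins = n_bins)
    tot_grp <- tabulate(bins[ch %in% residue_group], nbins = n_bins)
    grp <- grp + tot_grp
  }
  frac <- ifelse(tot > 0L, grp / tot, NA_real_)
  structure(list(n_bins = n_bins, residue_group = residue_group,
                 per_bin_fraction = frac, per_bin_group = grp,
                 per_bin_positions = tot),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("<positional_profile> residues {",
      paste(x$residue_group, collapse = ","), "}, ", x$n_bins, " bins\n",
      sep = "")
  print(round(x$per_bin_fraction, 3))
  invisible(x)
}

#' Scan one sequence for N-glycosylation sequons and N-P motifs
#'
#' A sequon is `N-X-S/T` with `X != P` (position `i` counts when
#' `seq[i] == N`, `seq[i+1] != P`, `seq[i+2]` is S or T). An `N-P` motif
#' (asparagine immediately followed by proline) precludes N-glycan
#' attachment. Overlapping matches are all counted; an N within the last
#' one or two positions contributes only to the N total.
#'
#' @param seq Amino-acid string (may be empty: all counts zero).
#' @return A list of class `sequon_counts`: `n_sequons`, `n_NP`,
#'   `total_N`, `total_P`, `total_residues`.
#' @export
sequon_scan <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  n_pos <- which(ch == "N")
  seq_ok <- n_pos[n_pos <= L - 2L]
  n_sequons <- sum(ch[seq_ok + 1L] != "P" & ch[seq_ok + 2L] %in% c("S", "T"))
  np_ok <- n_pos[n_pos <= L - 1L]
  n_NP <- sum(ch[np_ok + 1L] == "P")
  structure(list(n_sequons = as.integer(n_sequons), n_NP = as.integer(n_NP),
                 total_N = length(n_pos), total_P = sum(ch == "P"),
                 total_residues = L),
            class = "sequon_counts")
}

#' @export
print.sequon_counts <- function(x, ...) {
  cat(sprintf(
    "<sequon_counts> sequons=%d  N-P=%d  N=%d  P=%d  residues=%d\n",
    x$n_sequons, x$n_NP, x$total_N, x$total_P, x$total_residues))
  invisible(x)
}

#' Aggregate sequon counts over a linker set
#'
#' Element-wise sum of per-linker [sequon_scan()] counts.
#'
#' @param x A `linker_set`.
#' @return A `sequon_counts`.
#' @export
aggregate_sequons <- function(x) {
  stopifnot(inherits(x, "linker_set"))
  per <- lapply(x$linkers$seq, sequon_scan)
  fields <- c("n_sequons", "n_NP", "total_N", "total_P", "total_residues")
  out <- lapply(fields, function(f) {
    sum(vapply(per, function(p) as.numeric(p[[f]]), numeric(1)))
  })
  names(out) <- fields
  out <- lapply(out, as.integer)
  structure(out, class = "sequon_counts")
}

#' Sequon summary table over several linker sets
#'
#' One row per set plus a `combined` row, in the layout
#' `dataset  n_sequons  n_NP  total_N  total_P  total_residues`.
#'
#' @param sets Named list of `linker_set`s.
#' @return A data.frame.
#' @export
report_sequon_table <- function(sets) {
  rows <- lapply(names(sets), function(nm) {
    s <- aggregate_sequons(sets[[nm]])
    data.frame(dataset = nm, n_sequons = s$n_sequons, n_NP = s$n_NP,
               total_N = s$total_N, total_P = s$total_P,
               total_residues = s$total_residues, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  comb <- data.frame(dataset = "combined",
                     n_sequons = sum(out$n_sequons), n_NP = sum(out$n_NP),
                     total_N = sum(out$total_N), total_P = sum(out$total_P),
                     total_residues = sum(out$total_residues),
                     stringsAsFactors = FALSE)
  out <- rbind(out, comb)
  rownames(out) <- NULL
  out
}
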
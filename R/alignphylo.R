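# Pairwise global alignment with Gonnet scoring, percent-identity
# distributions, EC-based subsetting, and neighbor-joining trees.

.pkg_cache <- new.env(parent = emptyenv())

#' The Gonnet (1992) substitution matrix
#'
#' The published Gonnet PAM250-equivalent log-odds table over the 20
#' standard residues, with an all-zero row/column appended for `X`
#' (ambiguous residues neither rewarded nor penalised). Shipped as a
#' plain-text table so scoring is bit-exact across platforms.
#'
#' @return A symmetric 21 x 21 numeric matrix with residue dimnames.
#' @export
gonnet250 <- function() {
  if (is.null(.pkg_cache$gonnet)) {
    path <- system.file("extdata", "gonnet1992.tab", package = "cellulinker",
                        mustWork = TRUE)
    m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
    storage.mode(m) <- "double"
    .pkg_cache$gonnet <- m
  }
  .pkg_cache$gonnet
}

#' Optimal affine-gap global alignment of two protein sequences
#'
#' Three-state dynamic program (Gotoh) with end gaps penalised. The gap
#' convention follows the stated alignment parameters: a gap of length L
#' costs `gap_open + (L-1) * gap_extend` (open charged at the first gapped
#' column). Tie-breaking is deterministic: substitution is preferred over
#' a gap in `a` over a gap in `b` on equal score.
#'
#' Percent identity is `100 * identities / aligned columns`, where the
#' denominator includes internal gap columns but excludes terminal-gap
#' overhangs (columns before the first or after the last position where
#' both sequences have a residue).
#'
#' @param a,b Non-empty amino-acid strings.
#' @param substitution Substitution matrix (default [gonnet250()]).
#' @param gap_open,gap_extend Affine gap penalties (positive costs);
#'   defaults 10 and 0.05.
#' @return A list of class `alignment_result`: `aligned_a`, `aligned_b`,
#'   `score`, `identities`, `aligned_columns`, `percent_identity`.
#' @export
global_align <- function(a, b, substitution = gonnet250(),
                         gap_open = 10, gap_extend = 0.05) {
  if (!nzchar(a) || !nzchar(b)) stop("global_align: empty sequence")
  res <- .gotoh_align(a, b, substitution, colnames(substitution),
                      gap_open, gap_extend)
  ca <- strsplit(res$aligned_a, "")[[1]]
  cb <- strsplit(res$aligned_b, "")[[1]]
  both <- which(ca != "-" & cb != "-")
  if (length(both) == 0L) {
    cols <- 0L; ident <- 0L; pid <- NA_real_
  } else {
    span <- both[1L]:both[length(both)]
    cols <- length(span)
    ident <- sum(ca[span] == cb[span] & ca[span] != "-")
    pid <- 100 * ident / cols
  }
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, identities = ident,
                 aligned_columns = cols, percent_identity = pid),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score=%.2f  identity=%.1f%% (%d/%d cols)\n",
              x$score, x$percent_identity, x$identities, x$aligned_columns))
  if (nchar(x$aligned_a) <= 80) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  }
  invisible(x)
}

#' All-pairs percent-identity matrix
#'
#' Aligns every unordered pair of sequences globally and records the
#' percent identity; the diagonal is 100.
#'
#' @param seqs Named character vector of sequences (>= 2).
#' @param ... Passed to [global_align()].
#' @return A list of class `identity_matrix`: `labels`, `values`
#'   (symmetric numeric matrix).
#' @export
identity_matrix <- function(seqs, ...) {
  if (length(seqs) < 2L) stop("identity_matrix: need >= 2 sequences")
  labels <- names(seqs)
  if (is.null(labels)) labels <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  v <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- global_align(seqs[[i]], seqs[[j]], ...)$percent_identity
      v[i, j] <- pid
      v[j, i] <- pid
    }
  }
  structure(list(labels = labels, values = v), class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("<identity_matrix> ", length(x$labels), " sequences; off-diagonal ",
      sprintf("%.1f-%.1f%%", min(x$values[upper.tri(x$values)]),
              max(x$values[upper.tri(x$values)])), "\n", sep = "")
  invisible(x)
}

#' Histogram of pairwise percent identities
#'
#' Bins the `n(n-1)/2` pairwise identities of a sequence collection into
#' half-open percent bins (`[0,5), [5,10), ...`; the final `[95,100]` bin
#' is closed so 100% identities are counted).
#'
#' @param seqs Named character vector of sequences, or an
#'   `identity_matrix`.
#' @param bin_width Bin width in percent (default 5).
#' @param ... Passed to [identity_matrix()] when `seqs` is raw sequences.
#' @return A data.frame `bin_start`, `bin_end`, `count`; counts sum to
#'   `n(n-1)/2`.
#' @export
identity_histogram <- function(seqs, bin_width = 5, ...) {
  im <- if (inherits(seqs, "identity_matrix")) seqs else identity_matrix(seqs, ...)
  pid <- im$values[upper.tri(im$values)]
  idx <- pmin(floor(pid / bin_width), floor(100 / bin_width) - 1L)
  nb <- ceiling(100 / bin_width)
  tab <- tabulate(idx + 1L, nbins = nb)
  data.frame(bin_start = (seq_len(nb) - 1L) * bin_width,
             bin_end = seq_len(nb) * bin_width,
             count = tab)
}

#' Split a dataset into exo- and endo-acting subsets by EC number
#'
#' Cellobiohydrolases (exoglucanases, e.g. EC 3.2.1.91/3.2.1.176) and
#' endoglucanases (EC 3.2.1.4) are separated by Enzyme Commission prefix;
#' records with no or unmatched EC annotation are reported separately.
#'
#' @param dataset A `cellu_dataset`.
#' @param exo_prefixes,endo_prefixes Character vectors of EC prefixes.
#' @return A list with `cellu_dataset`s `exo` and `endo`, and
#'   `unclassified` (data.frame of the remaining records).
#' @export
subset_by_ec <- function(dataset,
                         exo_prefixes = c("3.2.1.91", "3.2.1.176"),
                         endo_prefixes = "3.2.1.4") {
  stopifnot(inherits(dataset, "cellu_dataset"))
  ec <- dataset$records$ec_number
  has <- !is.na(ec) & nzchar(ec)
  match_any <- function(prefixes) {
    has & Reduce(`|`, lapply(prefixes, function(p) startsWith(ec, p)),
                 accumulate = FALSE, init = FALSE)
  }
  is_exo <- match_any(exo_prefixes)
  is_endo <- match_any(endo_prefixes) & !is_exo
  subds <- function(keep) {
    out <- dataset
    out$records <- dataset$records[keep, , drop = FALSE]
    rownames(out$records) <- NULL
    out
  }
  list(exo = subds(is_exo), endo = subds(is_endo),
       unclassified = dataset$records[!(is_exo | is_endo), , drop = FALSE])
}

#' Neighbor-joining tree from a percent-identity matrix
#'
#' Builds an unrooted NJ tree on the distance `d = 100 - percent
#' identity`; negative branch lengths (an NJ artefact) are clamped to 0.
#' Used to spot evolutionarily divergent clades (e.g. ruminal-fungal or
#' proteobacterial outliers sitting on their own branch).
#'
#' @param im An `identity_matrix` (>= 3 labels), or a symmetric numeric
#'   identity matrix with dimnames.
#' @return An [ape::nj()] `phylo` object.
#' @export
nj_tree <- function(im) {
  v <- if (inherits(im, "identity_matrix")) im$values else as.matrix(im)
  if (nrow(v) < 3L) stop("nj_tree: need >= 3 labels")
  if (max(abs(v - t(v))) > 1e-8) stop("nj_tree: matrix is not symmetric")
  d <- 100 - v
  diag(d) <- 0
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Serialize a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
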
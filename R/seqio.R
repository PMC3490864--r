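# Sequence and metadata I/O: reading FASTA, sidecar metadata tables, and
# assembling per-architecture datasets.

# Closed residue alphabet: the 20 standard amino acids plus X for ambiguity.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

# The four multidomain architectures handled by the segmentation rules,
# named N- to C-terminus.
DATASET_LABELS <- c("GH7_CBM1", "CBM1_GH6", "CBM2_GH6", "GH6_CBM2")

# Record subset flags; ruminal-fungal and proteobacterial outlier clades are
# removed from the core linker comparisons.
SUBSET_FLAGS <- c("core", "ruminal_fungi", "proteobacteria")

#' Read protein sequences from a FASTA file
#'
#' Reads amino-acid FASTA. Sequences are uppercased and whitespace-stripped;
#' the record id is the first whitespace-delimited token of the header
#' (GenBank convention) and the full remainder is kept as the description.
#' Residues outside the 20-letter alphabet plus `X` are rejected, because all
#' downstream composition arithmetic assumes a closed alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `desc`, `seq`, one row per record,
#'   in file order. An empty file yields a zero-row data.frame with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("FASTA file is empty: ", path)
    return(data.frame(id = character(0), desc = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence before first header at line ", first,
         " of ", path)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  desc <- sub("^[^ \t]+[ \t]*", "", headers)
  seqs <- toupper(gsub("[ \t\r]", "", as.character(set)))
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), seqs)
  if (any(bad)) {
    stop("record(s) with residues outside the allowed alphabet (20 AA + X): ",
         paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces the
#' `(id, seq)` pairs.
#'
#' @param x A data.frame with columns `id` and `seq` (optionally `desc`).
#' @param path Output file path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  headers <- x$id
  if (!is.null(x$desc)) {
    has_desc <- !is.na(x$desc) & nzchar(x$desc)
    headers[has_desc] <- paste(x$id[has_desc], x$desc[has_desc])
  }
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a record metadata table
#'
#' Metadata is a tab-separated sidecar file (one row per accession) rather
#' than FASTA-header annotation, mirroring how organism and subset labels are
#' curated in supplementary tables. Expected columns: `id` (mandatory),
#' `organism`, `genus`, `dataset`, `subset_flag`, `ec_number`; missing
#' optional columns are filled. `genus` defaults to the first
#' whitespace-delimited token of `organism`; `subset_flag` defaults to
#' `"core"`.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame with the six canonical columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"id" %in% names(tab)) stop("metadata is missing the mandatory 'id' column")
  if (anyDuplicated(tab$id)) {
    dup <- unique(tab$id[duplicated(tab$id)])
    stop("duplicate id(s) in metadata: ", paste(dup, collapse = ", "))
  }
  if (is.null(tab$organism)) tab$organism <- NA_character_
  if (is.null(tab$genus) || all(is.na(tab$genus) | !nzchar(tab$genus))) {
    tab$genus <- ifelse(is.na(tab$organism), NA_character_,
                        vapply(strsplit(tab$organism, "[ \t]+"),
                               `[`, character(1), 1L))
  }
  if (is.null(tab$dataset)) tab$dataset <- NA_character_
  known <- is.na(tab$dataset) | tab$dataset %in% DATASET_LABELS
  if (!all(known)) {
    stop("unknown dataset label(s): ",
         paste(unique(tab$dataset[!known]), collapse = ", "),
         " (allowed: ", paste(DATASET_LABELS, collapse = ", "), ")")
  }
  if (is.null(tab$subset_flag)) tab$subset_flag <- "core"
  tab$subset_flag[is.na(tab$subset_flag) | !nzchar(tab$subset_flag)] <- "core"
  bad_flag <- !tab$subset_flag %in% SUBSET_FLAGS
  if (any(bad_flag)) {
    stop("unknown subset_flag(s): ",
         paste(unique(tab$subset_flag[bad_flag]), collapse = ", "))
  }
  if (is.null(tab$ec_number)) tab$ec_number <- NA_character_
  tab[, c("id", "organism", "genus", "dataset", "subset_flag", "ec_number")]
}

#' Assemble one architecture dataset from FASTA records and metadata
#'
#' Selects the metadata rows carrying `label`, attaches the matching
#' sequences, and returns a `cellu_dataset`. Row order follows the metadata
#' table; every selected metadata id must have a FASTA record.
#'
#' @param fasta A data.frame from [read_fasta()].
#' @param metadata A data.frame from [read_metadata()].
#' @param label One of `"GH7_CBM1"`, `"CBM1_GH6"`, `"CBM2_GH6"`, `"GH6_CBM2"`.
#' @param provenance Optional character vector of source file paths.
#' @return A `cellu_dataset`: list with `label`, `records` (data.frame with
#'   metadata columns plus `seq`), and `provenance`.
#' @export
assemble_dataset <- function(fasta, metadata, label, provenance = character(0)) {
  label <- match.arg(label, DATASET_LABELS)
  rows <- metadata[!is.na(metadata$dataset) & metadata$dataset == label, ,
                   drop = FALSE]
  missing <- setdiff(rows$id, fasta$id)
  if (length(missing) > 0L) {
    stop("metadata id(s) with no FASTA record: ",
         paste(missing, collapse = ", "))
  }
  rows$seq <- fasta$seq[match(rows$id, fasta$id)]
  rownames(rows) <- NULL
  structure(list(label = label, records = rows, provenance = provenance),
            class = "cellu_dataset")
}

#' @export
print.cellu_dataset <- function(x, ...) {
  cat("<cellu_dataset> ", x$label, ": ", nrow(x$records), " record(s)\n",
      sep = "")
  flags <- table(x$records$subset_flag)
  if (length(flags)) {
    cat("  subset flags:",
        paste(sprintf("%s=%d", names(flags), flags), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Remove a flagged subset of records from a dataset
#'
#' Drops records whose `subset_flag` equals `flag` (e.g. the ruminal-fungal
#' or proteobacterial outlier clades, which are excluded from the core linker
#' comparisons). The number of removed records is reported via `message()`.
#'
#' @param dataset A `cellu_dataset`.
#' @param flag One of `"ruminal_fungi"`, `"proteobacteria"`, `"core"`.
#' @return A new `cellu_dataset` without the flagged records.
#' @export
exclude_subset <- function(dataset, flag) {
  stopifnot(inherits(dataset, "cellu_dataset"))
  flag <- match.arg(flag, SUBSET_FLAGS)
  keep <- dataset$records$subset_flag != flag
  removed <- sum(!keep)
  message("exclude_subset: removed ", removed, " record(s) flagged '",
          flag, "' from ", dataset$label)
  out <- dataset
  out$records <- dataset$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  if (nrow(out$records) == 0L) {
    warning("all records removed: dataset ", dataset$label, " is now empty")
  }
  out
}
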
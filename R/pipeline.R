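# End-to-end orchestration: run every analysis stage on the four datasets
# and emit machine-readable report tables plus a run manifest.

#' Build a pipeline configuration
#'
#' All knobs of the end-to-end analysis in one validated list. With
#' `fasta`/`metadata` unset the pipeline generates the synthetic four-class
#' bundle (with outlier records in the CBM1_GH6 and CBM2_GH6 sets) from
#' `seed`; otherwise it reads the given FASTA and metadata TSV.
#'
#' @param out_dir Output directory for report files.
#' @param seed Integer RNG seed (drives synthetic generation; reruns with
#'   the same config and seed are byte-identical).
#' @param fasta,metadata Optional input file paths (real data).
#' @param n Named integer vector: records per class (defaults to the
#'   survey sizes 79/39/25/15).
#' @param n_outliers Named integer vector: outlier records for CBM1_GH6
#'   (ruminal-fungal-like) and CBM2_GH6 (proteobacterial-like).
#' @param exclude_outliers Drop flagged outlier subsets before the linker
#'   comparisons (the trees are always built on the pre-exclusion sets).
#' @param bin_width Length/identity histogram bin width.
#' @param n_bins Positional-profile bin count.
#' @param gap_open,gap_extend Alignment gap penalties.
#' @param mut_rate Synthetic stub-domain mutation rate.
#' @param welch Use Welch's t-test variant.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, fasta = NULL, metadata = NULL,
                            n = CLASS_N,
                            n_outliers = c(CBM1_GH6 = 5L, CBM2_GH6 = 5L),
                            exclude_outliers = TRUE, bin_width = 5L,
                            n_bins = 11L, gap_open = 10, gap_extend = 0.05,
                            mut_rate = 0.05, welch = FALSE) {
  if (!is.null(fasta) && !file.exists(fasta)) stop("fasta not found: ", fasta)
  if (!is.null(metadata) && !file.exists(metadata)) {
    stop("metadata not found: ", metadata)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), fasta = fasta,
                 metadata = metadata, n = n, n_outliers = n_outliers,
                 exclude_outliers = exclude_outliers,
                 bin_width = bin_width, n_bins = n_bins,
                 gap_open = gap_open, gap_extend = gap_extend,
                 mut_rate = mut_rate, welch = welch),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a plain-text file
#'
#' Debian-control-style `key: value` lines; unknown keys error. `out_dir`
#' is mandatory.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- read.dcf(path)
  keys <- colnames(kv)
  allowed <- c("out_dir", "seed", "fasta", "metadata", "exclude_outliers",
               "bin_width", "n_bins", "gap_open", "gap_extend", "mut_rate",
               "welch")
  bad <- setdiff(keys, allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!"out_dir" %in% keys) stop("config must set out_dir")
  val <- function(k, default, f = identity) {
    if (k %in% keys) f(kv[1, k]) else default
  }
  pipeline_config(
    out_dir = val("out_dir", NULL),
    seed = val("seed", 1L, as.integer),
    fasta = val("fasta", NULL),
    metadata = val("metadata", NULL),
    exclude_outliers = val("exclude_outliers", TRUE, as.logical),
    bin_width = val("bin_width", 5L, as.integer),
    n_bins = val("n_bins", 11L, as.integer),
    gap_open = val("gap_open", 10, as.numeric),
    gap_extend = val("gap_extend", 0.05, as.numeric),
    mut_rate = val("mut_rate", 0.05, as.numeric),
    welch = val("welch", FALSE, as.logical))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full linker analysis
#'
#' Stages: assemble (or simulate) the four datasets; neighbor-joining
#' trees of the full-length CBM1_GH6 and CBM2_GH6 sets (outliers
#' included); exclude flagged outlier subsets; segment every record;
#' linker length statistics, histograms and pairwise t-tests; pooled
#' amino-acid composition; positional profiles for S/T, G and P; sequon
#' statistics; per-domain percent-identity histograms. Each result is
#' written as one TSV (trees as Newick) under `config$out_dir`, plus a
#' `manifest.json` recording the configuration, versions, per-stage row
#' counts and any segmentation failures.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with all in-memory results (`datasets`,
#'   `linker_sets`, `tables`, `files`, `manifest`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  set.seed(config$seed)
  files <- character(0)
  warnings_log <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  # -- assemble ------------------------------------------------------------
  datasets <- stage("assemble", {
    if (!is.null(config$fasta)) {
      fa <- read_fasta(config$fasta)
      md <- read_metadata(config$metadata)
      labs <- intersect(DATASET_LABELS, unique(md$dataset))
      stats::setNames(lapply(labs, function(l) {
        assemble_dataset(fa, md, l, provenance = config$fasta)
      }), labs)
    } else {
      stats::setNames(lapply(DATASET_LABELS, function(l) {
        no <- if (l %in% names(config$n_outliers)) config$n_outliers[[l]] else 0L
        generate_dataset(l, n = config$n[[l]], n_outliers = no,
                         mut_rate = config$mut_rate)$dataset
      }), DATASET_LABELS)
    }
  })

  # -- trees on the full-length pre-exclusion sets -------------------------
  tree_labels <- intersect(c("CBM1_GH6", "CBM2_GH6"), names(datasets))
  trees <- stage("trees", {
    res <- list()
    for (l in tree_labels) {
      recs <- datasets[[l]]$records
      if (nrow(recs) < 3L) next
      im <- identity_matrix(stats::setNames(recs$seq, recs$id),
                            gap_open = config$gap_open,
                            gap_extend = config$gap_extend)
      res[[l]] <- nj_tree(im)
      f <- file.path(out, paste0("tree_", l, ".nwk"))
      write_newick(res[[l]], f)
      files <- c(files, f)
    }
    res
  })

  # -- exclusion -----------------------------------------------------------
  core <- stage("exclude", {
    res <- datasets
    if (config$exclude_outliers) {
      flags <- c(CBM1_GH6 = "ruminal_fungi", CBM2_GH6 = "proteobacteria")
      for (l in intersect(names(flags), names(res))) {
        if (any(res[[l]]$records$subset_flag == flags[[l]])) {
          res[[l]] <- suppressWarnings(exclude_subset(res[[l]], flags[[l]]))
        }
      }
    }
    res
  })

  # -- segmentation --------------------------------------------------------
  seg <- stage("segment", lapply(core, batch_segment))
  linker_sets <- lapply(seg, `[[`, "linkers")
  seg_tab <- do.call(rbind, lapply(seg, function(s) {
    segmentation_table(s$segments)
  }))
  rownames(seg_tab) <- NULL
  files <- c(files, write_tsv(seg_tab, file.path(out, "segmentation.tsv")))
  linker_fa <- do.call(rbind, lapply(linker_sets, function(ls) {
    keep <- ls$linkers$length > 0L
    data.frame(id = ls$linkers$id[keep], desc = paste0("linker ", ls$label),
               seq = ls$linkers$seq[keep], stringsAsFactors = FALSE)
  }))
  rownames(linker_fa) <- NULL
  f <- file.path(out, "linkers.fasta")
  write_fasta(linker_fa, f)
  files <- c(files, f)
  for (s in seg) {
    if (nrow(s$failures) > 0L) {
      warnings_log <- c(warnings_log, sprintf(
        "segmentation failure %s: %s", s$failures$id, s$failures$reason))
    }
  }

  # -- length statistics ---------------------------------------------------
  tables <- list()
  tables$length_stats <- stage("stats", report_length_table(linker_sets))
  files <- c(files, write_tsv(tables$length_stats,
                              file.path(out, "length_stats.tsv")))
  tables$length_histograms <- do.call(rbind, lapply(names(linker_sets),
    function(l) {
      h <- length_histogram(linker_sets[[l]], config$bin_width)
      if (nrow(h) == 0L) return(NULL)
      cbind(dataset = l, h, stringsAsFactors = FALSE)
    }))
  files <- c(files, write_tsv(tables$length_histograms,
                              file.path(out, "length_histograms.tsv")))
  tables$ttests <- report_ttest_matrix(linker_sets, welch = config$welch)
  files <- c(files, write_tsv(tables$ttests, file.path(out, "ttests.tsv")))

  # -- composition ---------------------------------------------------------
  tables$composition <- stage("composition", {
    comp <- lapply(linker_sets, aa_composition)
    df <- data.frame(residue = AA_ALPHABET, stringsAsFactors = FALSE)
    for (l in names(comp)) df[[l]] <- unname(comp[[l]]$fractions)
    df
  })
  files <- c(files, write_tsv(tables$composition,
                              file.path(out, "composition.tsv")))
  tables$trends <- do.call(rbind, lapply(names(linker_sets), function(l) {
    do.call(rbind, lapply(list(ST = c("S", "T"), P = "P", G = "G"),
      function(grp) {
        tr <- composition_vs_length(linker_sets[[l]], grp)
        data.frame(dataset = l, group = paste(grp, collapse = "+"),
                   slope = tr$fit$slope, intercept = tr$fit$intercept,
                   r_squared = tr$fit$r_squared, stringsAsFactors = FALSE)
      }))
  }))
  rownames(tables$trends) <- NULL
  files <- c(files, write_tsv(tables$trends, file.path(out, "trends.tsv")))

  # -- positional profiles -------------------------------------------------
  tables$profiles <- stage("profiles", {
    do.call(rbind, lapply(names(linker_sets), function(l) {
      do.call(rbind, lapply(list(ST = c("S", "T"), G = "G", P = "P"),
        function(grp) {
          pr <- positional_profile(linker_sets[[l]], grp, config$n_bins)
          data.frame(dataset = l, group = paste(grp, collapse = "+"),
                     bin = seq_len(pr$n_bins),
                     fraction = pr$per_bin_fraction,
                     positions = pr$per_bin_positions,
                     stringsAsFactors = FALSE)
        }))
    }))
  })
  rownames(tables$profiles) <- NULL
  files <- c(files, write_tsv(tables$profiles, file.path(out, "profiles.tsv")))

  # -- sequons -------------------------------------------------------------
  tables$sequons <- stage("sequons", report_sequon_table(linker_sets))
  files <- c(files, write_tsv(tables$sequons, file.path(out, "sequons.tsv")))

  # -- per-domain identity histograms --------------------------------------
  tables$identity <- stage("identity", {
    do.call(rbind, lapply(names(core), function(l) {
      segs <- seg[[l]]$segments
      ok <- Filter(function(s) s$status == "ok", segs)
      if (length(ok) < 2L) return(NULL)
      do.call(rbind, lapply(c("cbm", "linker", "gh"), function(dom) {
        seqs <- vapply(ok, `[[`, character(1), dom)
        names(seqs) <- vapply(ok, `[[`, character(1), "id")
        seqs <- seqs[nzchar(seqs)]
        if (length(seqs) < 2L) return(NULL)
        h <- identity_histogram(seqs, bin_width = config$bin_width,
                                gap_open = config$gap_open,
                                gap_extend = config$gap_extend)
        cbind(dataset = l, domain = dom, h, stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(tables$identity) <- NULL
  files <- c(files, write_tsv(tables$identity,
                              file.path(out, "identity_histograms.tsv")))

  # -- manifest ------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               null = "null")
  manifest <- list(
    package = "cellulinker",
    package_version = as.character(utils::packageVersion("cellulinker")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = jsonlite::fromJSON(cfg_json),
    config_checksum = sum(utf8ToInt(cfg_json)),
    datasets = lapply(datasets, function(d) nrow(d$records)),
    linkers = lapply(linker_sets, function(l) l$n),
    warnings = warnings_log,
    outputs = c(basename(files), "manifest.json"))
  f <- file.path(out, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), f)
  files <- c(files, f)

  invisible(list(datasets = datasets, core = core, trees = trees,
                 segmentation = seg, linker_sets = linker_sets,
                 tables = tables, files = files, manifest = manifest))
}
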
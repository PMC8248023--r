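# Delimited-text I/O for connectivity matrices, node labels and manifests.
# All on-disk artifacts are plain text: TSV matrices (header = node labels),
# a TSV node-label table and a JSON cohort manifest.

#' Write a square connectivity matrix as TSV
#'
#' @param m Square numeric matrix.
#' @param path Output file.
#' @param labels Optional character vector of node labels used as the header;
#'   defaults to `V1..Vn`.
#' @export
write_matrix_tsv <- function(m, path, labels = NULL) {
  stop_if_not_square(m)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(m)))
  stopifnot(length(labels) == ncol(m))
  df <- as.data.frame(m)
  names(df) <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a square connectivity matrix from TSV
#'
#' @param path File written by [write_matrix_tsv()] (or any headered TSV
#'   holding a square numeric matrix).
#' @return Numeric matrix with node labels as dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("malformed matrix in '%s': %d rows x %d cols",
                 path, nrow(m), ncol(m)), call. = FALSE)
  }
  rownames(m) <- colnames(m)
  storage.mode(m) <- "double"
  m
}

#' Node-label table bundled with the package
#'
#' Returns the 90-region anatomical parcellation table (1-based region index,
#' region name, hemisphere). Odd indices are left-hemisphere regions, even
#' indices right, following the standard interleaved ordering of the atlas.
#'
#' @return Data frame with columns `index`, `name`, `hemisphere`.
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "longconn")
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a cohort to disk with a JSON manifest
#'
#' One TSV matrix file and one waytotal vector file per subject/timepoint;
#' the manifest records subject ids, timepoint labels, relative file paths,
#' the generator seed and (optionally) the ground truth.
#'
#' @param cohort A cohort as returned by [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- names(cohort$counts)
  entries <- list()
  for (s in subjects) {
    for (tp in c(1L, 2L)) {
      mfile <- sprintf("%s_t%d_counts.tsv", s, tp)
      wfile <- sprintf("%s_t%d_waytotal.tsv", s, tp)
      write_matrix_tsv(cohort$counts[[s]][[tp]], file.path(dir, mfile))
      utils::write.table(
        data.frame(waytotal = cohort$waytotals[[s]][[tp]]),
        file.path(dir, wfile), sep = "\t", quote = FALSE, row.names = FALSE)
      entries[[length(entries) + 1L]] <- list(
        subject = s, timepoint = tp, counts = mfile, waytotal = wfile)
    }
  }
  manifest <- list(
    n_nodes = cohort$config$n_nodes,
    seed = cohort$config$seed,
    subjects = subjects,
    files = entries,
    ground_truth = cohort$truth
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `manifest.json` and the per-subject files.
#' @return List with `counts`, `waytotals` (per subject, per timepoint),
#'   `subjects`, `n_nodes`, `seed`, `truth`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  counts <- list()
  waytotals <- list()
  files <- manifest$files
  for (k in seq_len(nrow(files))) {
    s <- files$subject[k]
    tp <- files$timepoint[k]
    if (is.null(counts[[s]])) {
      counts[[s]] <- vector("list", 2L)
      waytotals[[s]] <- vector("list", 2L)
    }
    counts[[s]][[tp]] <- read_matrix_tsv(file.path(dir, files$counts[k]))
    waytotals[[s]][[tp]] <- utils::read.table(
      file.path(dir, files$waytotal[k]), header = TRUE)$waytotal
  }
  list(counts = counts, waytotals = waytotals,
       subjects = manifest$subjects, n_nodes = manifest$n_nodes,
       seed = manifest$seed, truth = manifest$ground_truth)
}
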
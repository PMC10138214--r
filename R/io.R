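#' Read a feature matrix from CSV/TSV or MatrixMarket files
#'
#' CSV/TSV files are read with the first column as row names when the header
#' has one fewer field than the body. MatrixMarket (`.mtx`) files are read
#' with companion `<stem>.rownames` / `<stem>.colnames` text files when
#' present.
#'
#' @param path file path (`.csv`, `.tsv`, or `.mtx`).
#' @return numeric matrix, items in rows.
#' @export
read_view_matrix <- function(path) {
  if (!file.exists(path)) stop("view file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("reading MatrixMarket files requires the Matrix package")
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    rn <- paste0(stem, ".rownames")
    cn <- paste0(stem, ".colnames")
    if (file.exists(rn)) rownames(m) <- readLines(rn)
    if (file.exists(cn)) colnames(m) <- readLines(cn)
    return(m)
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = NULL)
  if (!is.numeric(df[[1L]])) {
    rn <- df[[1L]]
    df <- df[-1L]
    m <- as.matrix(df)
    rownames(m) <- rn
  } else m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}

#' Write the artifacts of a pipeline run to a directory
#'
#' Emits the standard output bundle: final labels (`labels.csv`), the merge
#' tree (`merge_tree.json` and `merge_tree.nwk`), the per-cluster tightness
#' report (`tightness.csv`), the view-contribution table
#' (`contribution.csv`), the product codebook (`codebook.csv`) and a run
#' manifest (`manifest.json`) holding the parameters and summary metrics so
#' a run is replayable from its manifest alone.
#'
#' @param res a `cps_merge_result`.
#' @param dir output directory (created if absent).
#' @param extra named list merged into the manifest (e.g. seeds, input
#'   paths, recovery metrics).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(res, dir, extra = list()) {
  stopifnot(inherits(res, "cps_merge_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(item = seq_len(res$final$n), final = res$final$labels),
    file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(tightness_report(res$stability),
                   file.path(dir, "tightness.csv"), row.names = FALSE)
  utils::write.csv(res$contributions$table,
                   file.path(dir, "contribution.csv"), row.names = FALSE)
  utils::write.csv(res$product$codebook, file.path(dir, "codebook.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$tree$events, file.path(dir, "merge_tree.json"),
                       auto_unbox = TRUE, digits = 8)
  writeLines(merge_tree_newick(res$tree), file.path(dir, "merge_tree.nwk"))
  manifest <- c(list(
    package = "cpsmerge",
    version = as.character(utils::packageVersion("cpsmerge")),
    params = res$params,
    final_clusters = res$final$K,
    mean_tightness = res$stability$mean_tightness,
    contribution_measure = res$contributions$selected
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 8, null = "null")
  invisible(dir)
}

#' Write a simulated scenario to disk
#'
#' Writes the two view matrices (`view_a.csv`, `view_b.csv`), the truth
#' labels (`truth.csv`) and a scenario manifest (`scenario.json`).
#'
#' @param sc a `cps_scenario` from [simulate_views()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sc, dir) {
  stopifnot(inherits(sc, "cps_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(sc$view_a), file.path(dir, "view_a.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sc$view_b), file.path(dir, "view_b.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(item = seq_len(sc$n), truth = sc$truth,
               truth_a = sc$truth_a, truth_b = sc$truth_b),
    file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    sc[c("regime", "n", "k_a", "k_b", "separation", "dims", "seed")],
    file.path(dir, "scenario.json"), auto_unbox = TRUE)
  invisible(dir)
}
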
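# Columnar positions files and result writing.

#' Read flock snapshots from a positions file
#'
#' The file is comma- or tab-delimited (auto-detected from the header line)
#' with required columns `snapshot_id, bird_id, x, y, z`; one row per bird.
#' Rows are grouped by `snapshot_id` (order of first appearance preserved,
#' row order preserved within a snapshot).
#'
#' @param path path to the file.
#' @return List of [flock_snapshot()]s, named by snapshot id.
#' @export
read_positions <- function(path) {
  if (!file.exists(path)) stop("positions file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  req <- c("snapshot_id", "bird_id", "x", "y", "z")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L)
    stop("positions file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("positions file contains no rows")
  for (col in c("x", "y", "z")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad) > 0L)
      stop("non-numeric or non-finite value in column '", col,
           "', data row ", bad[1L], " ('", df[[col]][bad[1L]], "')")
    df[[col]] <- vals
  }
  ids <- unique(df$snapshot_id)
  snaps <- lapply(ids, function(id) {
    sub <- df[df$snapshot_id == id, , drop = FALSE]
    flock_snapshot(as.matrix(sub[, c("x", "y", "z")]),
                   snapshot_id = id, bird_ids = sub$bird_id)
  })
  stats::setNames(snaps, ids)
}

#' Write flock snapshots to a positions file
#'
#' @param snapshots a [flock_snapshot()] or list of them.
#' @param path output path.
#' @param sep `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_positions <- function(snapshots, path, sep = ",") {
  if (inherits(snapshots, "flock_snapshot")) snapshots <- list(snapshots)
  rows <- lapply(snapshots, function(s)
    data.frame(snapshot_id = s$snapshot_id, bird_id = s$bird_ids,
               x = s$positions[, 1L], y = s$positions[, 2L],
               z = s$positions[, 3L], stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Writes each table as CSV (stable column order) plus a `manifest.json`
#' recording the configuration, seed and package version, so a run can be
#' reproduced exactly. Refuses to overwrite a non-empty directory unless
#' `force = TRUE`.
#'
#' @param tables named list of data.frames.
#' @param manifest list of run metadata (config, seeds, ...); the package
#'   version and R version are added automatically.
#' @param out_dir output directory (created if absent).
#' @param force overwrite existing outputs.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(tables, manifest, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force)
    stop("output directory '", out_dir,
         "' already contains files; use force = TRUE to overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  manifest$package_version <- as.character(utils::packageVersion("flocknet"))
  manifest$r_version <- R.version.string
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
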
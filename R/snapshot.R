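#' Create a flock snapshot
#'
#' A snapshot holds the 3-D positions of all N individuals of one flock at
#' one instant. It is the raw input to every analysis in the package.
#'
#' @param positions numeric matrix (or coercible) with N rows and 3 columns
#'   (x, y, z coordinates in metres).
#' @param snapshot_id character label for the snapshot.
#' @param bird_ids optional character vector of N unique individual labels;
#'   defaults to `"1" ... "N"`.
#'
#' @return An object of class `flock_snapshot`: a list with elements
#'   `snapshot_id`, `positions` (N x 3 numeric matrix) and `bird_ids`.
#' @examples
#' snap <- flock_snapshot(matrix(rnorm(30), ncol = 3), "example")
#' snap
#' @export
flock_snapshot <- function(positions, snapshot_id = "snapshot", bird_ids = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L)
    stop("positions must have exactly 3 columns (x, y, z)")
  n <- nrow(positions)
  if (n < 1L)
    stop("a snapshot must contain at least one bird")
  if (!all(is.finite(positions)))
    stop("non-finite coordinate in positions of snapshot '", snapshot_id, "'")
  if (is.null(bird_ids))
    bird_ids <- as.character(seq_len(n))
  bird_ids <- as.character(bird_ids)
  if (length(bird_ids) != n)
    stop("bird_ids must have one entry per row of positions")
  if (anyDuplicated(bird_ids))
    stop("duplicate bird_id within snapshot '", snapshot_id, "': ",
         paste(unique(bird_ids[duplicated(bird_ids)]), collapse = ", "))
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  structure(
    list(snapshot_id = as.character(snapshot_id)[1L],
         positions = positions,
         bird_ids = bird_ids),
    class = "flock_snapshot"
  )
}

#' @export
print.flock_snapshot <- function(x, ...) {
  cat("<flock_snapshot> '", x$snapshot_id, "': ", nrow(x$positions),
      " birds\n", sep = "")
  invisible(x)
}

n_birds <- function(snapshot) nrow(snapshot$positions)

assert_snapshot <- function(snapshot) {
  if (!inherits(snapshot, "flock_snapshot"))
    stop("expected a 'flock_snapshot' object; see flock_snapshot()")
  invisible(snapshot)
}
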
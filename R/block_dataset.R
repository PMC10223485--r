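#' Construct a block dataset
#'
#' A block dataset is the columnar container for segmented sensor windows:
#' an `N x W x C` sample array plus per-block label and provenance vectors.
#' Provenance (subject, source trial, window start) is carried through every
#' transformation so subject-wise splits stay honest.
#'
#' @param samples Numeric array `N x W x C`.
#' @param label Integer vector of block labels (codes 0/1/2).
#' @param subject_id Character vector of subject ids.
#' @param source_trial Character vector naming the originating trial.
#' @param start_index Integer vector of 0-based window starts.
#' @return A `block_dataset`.
#' @export
block_dataset <- function(samples, label, subject_id, source_trial, start_index) {
  stopifnot(is.array(samples), length(dim(samples)) == 3L)
  n <- dim(samples)[1L]
  label <- validate_labels(label, "block labels")
  stopifnot(
    length(label) == n, length(subject_id) == n,
    length(source_trial) == n, length(start_index) == n,
    all(start_index >= 0L)
  )
  structure(
    list(
      samples      = samples,
      label        = label,
      subject_id   = as.character(subject_id),
      source_trial = as.character(source_trial),
      start_index  = as.integer(start_index)
    ),
    class = "block_dataset"
  )
}

empty_block_dataset <- function(width, channels) {
  block_dataset(
    samples = array(numeric(0), dim = c(0L, width, channels)),
    label = integer(0), subject_id = character(0),
    source_trial = character(0), start_index = integer(0)
  )
}

#' Number of blocks in a dataset
#' @param ds A `block_dataset`.
#' @return Integer count.
#' @export
n_blocks <- function(ds) {
  stopifnot(inherits(ds, "block_dataset"))
  dim(ds$samples)[1L]
}

#' @export
length.block_dataset <- function(x) n_blocks(x)

#' Subset a block dataset
#' @param x A `block_dataset`.
#' @param i Index vector of blocks to keep.
#' @param ... Ignored.
#' @return A `block_dataset` with the selected blocks, in order.
#' @export
`[.block_dataset` <- function(x, i, ...) {
  block_dataset(
    samples      = x$samples[i, , , drop = FALSE],
    label        = x$label[i],
    subject_id   = x$subject_id[i],
    source_trial = x$source_trial[i],
    start_index  = x$start_index[i]
  )
}

#' Concatenate block datasets
#' @param ... `block_dataset` objects with identical block shapes.
#' @return A single combined `block_dataset`.
#' @export
combine_blocks <- function(...) {
  parts <- Filter(function(d) n_blocks(d) > 0L, list(...))
  if (length(parts) == 0L) {
    all_parts <- list(...)
    stopifnot(length(all_parts) > 0L)
    return(all_parts[[1L]])
  }
  shapes <- vapply(parts, function(d) dim(d$samples)[2:3], numeric(2))
  stopifnot(all(shapes == shapes[, 1L]))
  W <- dim(parts[[1L]]$samples)[2L]
  C <- dim(parts[[1L]]$samples)[3L]
  n <- sum(vapply(parts, n_blocks, 0L))
  samples <- array(0, dim = c(n, W, C))
  off <- 0L
  for (d in parts) {
    k <- n_blocks(d)
    samples[off + seq_len(k), , ] <- d$samples
    off <- off + k
  }
  block_dataset(
    samples,
    label        = unlist(lapply(parts, `[[`, "label")),
    subject_id   = unlist(lapply(parts, `[[`, "subject_id")),
    source_trial = unlist(lapply(parts, `[[`, "source_trial")),
    start_index  = unlist(lapply(parts, `[[`, "start_index"))
  )
}

#' Extract one block
#' @param ds A `block_dataset`.
#' @param i Block index.
#' @return List with `samples` (`W x C` matrix), `label`, `subject_id`,
#'   `source_trial`, `start_index`.
#' @export
get_block <- function(ds, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= n_blocks(ds))
  W <- dim(ds$samples)[2L]; C <- dim(ds$samples)[3L]
  list(
    samples      = matrix(ds$samples[i, , ], W, C),
    label        = ds$label[i],
    subject_id   = ds$subject_id[i],
    source_trial = ds$source_trial[i],
    start_index  = ds$start_index[i]
  )
}

#' @export
print.block_dataset <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<block_dataset> %d blocks of %d x %d\n", d[1L], d[2L], d[3L]))
  if (d[1L] > 0L) {
    tab <- table(factor(x$label, levels = class_labels(),
                        labels = names(class_labels())))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat("  subjects:", paste(unique(x$subject_id), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Persist / reload a processed block dataset
#'
#' The on-disk container is R's native serialization, which round-trips the
#' sample array, labels, and subject provenance bitwise-losslessly.
#'
#' @param ds A non-empty `block_dataset`.
#' @param path Destination file.
#' @return `save_block_dataset` invisibly returns `path`;
#'   `load_block_dataset` returns the reloaded `block_dataset`.
#' @export
save_block_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "block_dataset"))
  if (n_blocks(ds) == 0L) stop("refusing to save an empty block dataset", call. = FALSE)
  saveRDS(ds, path)
  invisible(path)
}

#' @rdname save_block_dataset
#' @export
load_block_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ds <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable block dataset container: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!inherits(ds, "block_dataset")) {
    stop("file does not contain a block dataset", call. = FALSE)
  }
  ds
}
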
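# Reading and writing the pipeline's on-disk formats.

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are stored as 32-bit float, one page per frame, preserving the
#' simulated values exactly.
#'
#' @param stack Numeric array `height x width x n_frames` (a single matrix is
#'   treated as one frame).
#' @param path Output file path.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' @param path TIFF file path.
#' @return Numeric array `height x width x n_frames`.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Read a count matrix with sample metadata
#'
#' @param counts_path TSV of integer counts: first column gene id, remaining
#'   columns one per sample.
#' @param meta_path TSV with columns `sample`, `treatment`, `replicate`.
#' @return A [wound_counts()] object.
#' @export
read_counts <- function(counts_path, meta_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  meta <- utils::read.delim(meta_path)
  wound_counts(counts[, meta$sample, drop = FALSE], meta)
}

#' Write a count matrix and its metadata
#'
#' @param cm A [wound_counts()] object.
#' @param counts_path,meta_path Output TSV paths.
#' @export
write_counts <- function(cm, counts_path, meta_path) {
  stopifnot(inherits(cm, "wound_counts"))
  tab <- data.frame(gene = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}
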
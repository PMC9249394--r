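# File interfaces: multi-page TIFF stacks, CSV trace/behavior tables,
# JSON ground-truth sidecars.

#' Write a 3-D stack or image list as a multi-page TIFF
#'
#' Intensities are rescaled to [0, 1] for storage; the scale factor is
#' returned invisibly.
#'
#' @param stack 3-D array (Z, Y, X) or list of matrices.
#' @param path output file.
#' @return invisibly, the maximum used for rescaling.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF output")
  if (is.list(stack)) pages <- stack
  else pages <- lapply(seq_len(dim(stack)[1]), function(z)
    matrix(stack[z, , ], dim(stack)[2], dim(stack)[3]))
  mx <- max(1e-12, max(vapply(pages, max, numeric(1))))
  pages <- lapply(pages, function(p) pmax(p, 0) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(mx)
}

#' Read a multi-page TIFF as a (Z, Y, X) stack
#'
#' @param path TIFF file.
#' @return 3-D numeric array (Z, Y, X) in [0, 1].
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF input")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  out
}

#' Write per-cell fluorescence traces in long CSV form
#'
#' Columns: `cell_id`, `frame`, `f_soma`, `f_neuropil`.
#'
#' @param f_soma,f_neuropil cells x frames matrices.
#' @param path output CSV.
#' @export
write_traces_csv <- function(f_soma, f_neuropil, path) {
  stopifnot(all(dim(f_soma) == dim(f_neuropil)))
  nc <- nrow(f_soma); nf <- ncol(f_soma)
  df <- data.frame(cell_id = rep(seq_len(nc), each = nf),
                   frame = rep(seq_len(nf), nc),
                   f_soma = as.vector(t(f_soma)),
                   f_neuropil = as.vector(t(f_neuropil)))
  write.csv(df, path, row.names = FALSE)
}

#' Read per-cell traces written by [write_traces_csv()]
#'
#' @param path CSV file.
#' @return list with `f_soma` and `f_neuropil` matrices.
#' @export
read_traces_csv <- function(path) {
  df <- read.csv(path)
  nc <- max(df$cell_id); nf <- max(df$frame)
  ord <- order(df$cell_id, df$frame)
  list(f_soma = matrix(df$f_soma[ord], nc, nf, byrow = TRUE),
       f_neuropil = matrix(df$f_neuropil[ord], nc, nf, byrow = TRUE))
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth a list (e.g. the `truth` element of a simulation).
#' @param path output JSON file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
}

#' Read a ground-truth sidecar written by [write_truth_json()]
#'
#' @param path JSON file.
#' @return list.
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
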
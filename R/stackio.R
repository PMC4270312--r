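# Plain-text serialization of image stacks (one file per well per channel,
# `<plate>_<well>_<channel>.txt`). A vendor-neutral text format is used in
# place of TIFF so stacks remain portable without an image library: a header
# line `H W T` followed by T whitespace-delimited H x W frame blocks.

#' Write an image stack to text files
#'
#' @param stack list with `cfp`, `yfp` (H x W x T arrays) and `nuclear`
#'   (H x W matrix), as produced by [render_field()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix, conventionally `<plate>_<well>`.
#' @return invisibly, the written file paths.
#' @export
write_stack_txt <- function(stack, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(a, path) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(dim(a), collapse = " "), con)
    for (f in seq_len(dim(a)[3])) {
      utils::write.table(format(a[, , f], digits = 10, trim = TRUE),
                         con, row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    }
    path
  }
  paths <- c(
    write_one(stack$cfp, file.path(dir, paste0(prefix, "_cfp.txt"))),
    write_one(stack$yfp, file.path(dir, paste0(prefix, "_yfp.txt"))),
    write_one(stack$nuclear, file.path(dir, paste0(prefix, "_nuclear.txt"))))
  invisible(paths)
}

#' Read an image stack written by [write_stack_txt()]
#'
#' @param dir directory holding the channel files.
#' @param prefix filename prefix used when writing.
#' @return list with `cfp`, `yfp` arrays and `nuclear` matrix.
#' @export
read_stack_txt <- function(dir, prefix) {
  read_one <- function(path) {
    lines <- readLines(path)
    dims <- as.integer(strsplit(lines[1], " ")[[1]])
    vals <- scan(text = lines[-1], quiet = TRUE)
    a <- array(0, dim = dims)
    per <- dims[1] * dims[2]
    for (f in seq_len(dims[3])) {
      block <- vals[((f - 1) * per + 1):(f * per)]
      a[, , f] <- matrix(block, dims[1], dims[2], byrow = TRUE)
    }
    a
  }
  nuc <- read_one(file.path(dir, paste0(prefix, "_nuclear.txt")))
  list(cfp = read_one(file.path(dir, paste0(prefix, "_cfp.txt"))),
       yfp = read_one(file.path(dir, paste0(prefix, "_yfp.txt"))),
       nuclear = nuc[, , 1])
}
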
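# Shared I/O helpers: atomic writes and byte-exact MD5 digests.

# Write via a temp file in the target directory, then rename. Readers
# never observe a half-written output.
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("atomic write failed: cannot rename onto ", path)
  }
  invisible(path)
}

#' MD5 digests of character strings
#'
#' Lowercase hex MD5 of the exact UTF-8 bytes of each string (no trailing
#' newline).
#'
#' @param x character vector.
#' @return Character vector of 32-character hex digests.
#' @export
md5_hex <- function(x) {
  if (length(x) == 0L) return(character(0))
  dir <- tempfile("md5-")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- file.path(dir, seq_along(x))
  for (i in seq_along(x)) {
    con <- file(paths[i], "wb")
    writeBin(charToRaw(enc2utf8(x[i])), con)
    close(con)
  }
  unname(tools::md5sum(paths))
}
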
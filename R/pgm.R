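# Minimal binary PGM (P5) reader/writer. Frames are stored on disk as
# 8-bit portable graymaps because the toolchain has no video codecs; PGM is
# lossless and trivially parseable.

write_pgm <- function(mat, path) {
  # mat: raw or integer matrix, rows = image rows (y), cols = x
  if (is.raw(mat)) {
    vals <- mat
  } else {
    v <- as.integer(mat)
    if (anyNA(v) || any(v < 0L) || any(v > 255L)) stop("pgm values must be 0..255")
    vals <- as.raw(v)
  }
  dim(vals) <- dim(mat)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(mat), nrow(mat)), con, eos = NULL)
  # PGM is row-major (top row first); R matrices are column-major
  writeBin(as.raw(t(vals)), con)
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- c()
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("truncated pgm header: ", path)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (magic != "P5") stop("not a binary PGM (P5) file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (maxval > 255) stop("only 8-bit PGM supported: ", path)
  dat <- readBin(con, "raw", n = w * h)
  if (length(dat) < w * h) stop("truncated pgm data: ", path)
  m <- matrix(dat, nrow = h, ncol = w, byrow = TRUE)
  m
}
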
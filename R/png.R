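# Minimal PNG codec (8-bit RGB, no interlace, writer emits filter type 0
# rows; reader supports exactly that subset plus tEXt metadata chunks).
# Implemented in-package because no PNG library is available; zlib streams
# come from memCompress/memDecompress and CRC32 is table-driven below.

# 32-bit unsigned xor on doubles in [0, 2^32)
xor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(crc_env$tab)) return(crc_env$tab)
  tab <- numeric(256)
  for (n in 0:255) {
    c_ <- n
    for (k in 1:8)
      c_ <- if (c_ %% 2 == 1) xor32(c_ %/% 2, 3988292384) else c_ %/% 2
    tab[n + 1] <- c_
  }
  crc_env$tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  b <- as.integer(bytes)
  c_ <- 4294967295
  for (i in seq_along(b)) {
    idx <- bitwXor(as.integer(c_ %% 256), b[i]) + 1L
    c_ <- xor32(tab[idx], c_ %/% 256)
  }
  xor32(c_, 4294967295)
}

u32_be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

be_u32 <- function(r) {
  sum(as.numeric(r) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(crc32(body)))
}

# pixels: H x W x 3 integer array, values 0..255
write_png <- function(pixels, path, text = list()) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3L] == 3L)
  h <- dim(pixels)[1L]; w <- dim(pixels)[2L]
  px <- as.integer(pixels)
  if (anyNA(px) || any(px < 0L | px > 255L))
    stop("pixel values must be integers in 0..255")
  ihdr <- c(u32_be(w), u32_be(h), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  # per-row byte layout: filter byte 0 then RGB interleaved left to right
  arr <- aperm(array(px, dim(pixels)), c(3L, 2L, 1L))  # (channel, x, y)
  rows <- matrix(as.raw(arr), nrow = 3L * w)
  raw_stream <- as.vector(rbind(as.raw(0L), rows))
  idat <- memCompress(raw_stream, type = "gzip")
  text_chunks <- unlist(lapply(names(text), function(k)
    png_chunk("tEXt", c(charToRaw(k), as.raw(0L),
                        charToRaw(as.character(text[[k]]))))))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           text_chunks,
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

read_png <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  if (length(bytes) < 8L || !identical(bytes[1:8], sig))
    stop("not a PNG file: ", path)
  pos <- 9L
  w <- h <- NULL
  idat <- raw()
  text <- list()
  while (pos + 8L <= length(bytes)) {
    len <- be_u32(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw()
    if (type == "IHDR") {
      w <- be_u32(data[1:4]); h <- be_u32(data[5:8])
      if (as.integer(data[9L]) != 8L || as.integer(data[10L]) != 2L)
        stop("unsupported PNG subtype (need 8-bit RGB): ", path)
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "tEXt") {
      z <- which(data == as.raw(0L))[1L]
      text[[rawToChar(data[seq_len(z - 1L)])]] <-
        rawToChar(data[(z + 1L):length(data)])
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(w)) stop("PNG missing IHDR: ", path)
  raw_stream <- memDecompress(idat, type = "gzip")
  stride <- 3L * w + 1L
  rows <- matrix(raw_stream, nrow = stride)
  if (any(rows[1L, ] != as.raw(0L)))
    stop("unsupported PNG row filter (this reader handles filter 0 only): ",
         path)
  arr <- array(as.integer(rows[-1L, , drop = FALSE]), c(3L, w, h))
  list(pixels = aperm(arr, c(3L, 2L, 1L)), text = text)
}
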
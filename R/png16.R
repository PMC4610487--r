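# Minimal 16-bit grayscale PNG encoder.
#
# Depth frames are 16-bit single-channel images; the installed PNG writers only
# emit 8-bit grayscale, which would destroy millimetre depth resolution, so the
# package carries its own encoder for this one fixed layout (bit depth 16,
# colour type 0, filter 0, zlib-compressed scanlines). Decoding goes through
# png::readPNG, which handles 16-bit natively.

# CRC state kept as two 16-bit halves: the bit pattern 0x80000000 is
# NA_integer_ in R, so full-width integer bit operations are unsafe.
.crc32_table <- local({
  th <- tl <- integer(256L)
  for (i in 0:255) {
    ch <- 0L; cl <- i
    for (k in 1:8) {
      odd <- cl %% 2L
      nl <- cl %/% 2L + (ch %% 2L) * 32768L
      nh <- ch %/% 2L
      if (odd == 1L) {                  # reversed polynomial 0xEDB88320
        nh <- bitwXor(nh, 60856L)       # 0xEDB8
        nl <- bitwXor(nl, 33568L)       # 0x8320
      }
      ch <- nh; cl <- nl
    }
    th[i + 1L] <- ch; tl[i + 1L] <- cl
  }
  list(hi = th, lo = tl)
})

.crc32 <- function(bytes) {
  th <- .crc32_table$hi; tl <- .crc32_table$lo
  ch <- 65535L; cl <- 65535L
  for (b in as.integer(bytes)) {
    idx <- bitwXor(cl %% 256L, b) + 1L
    sl <- (ch %% 256L) * 256L + cl %/% 256L
    sh <- ch %/% 256L
    ch <- bitwXor(sh, th[idx])
    cl <- bitwXor(sl, tl[idx])
  }
  bitwXor(ch, 65535L) * 65536 + bitwXor(cl, 65535L)
}

.u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

.png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(.u32be(length(data)), td, .u32be(.crc32(td)))
}

# m: integer matrix (rows = image rows), values in [0, 65535]
.write_png16 <- function(m, path) {
  h <- nrow(m)
  w <- ncol(m)
  vals <- t(m)                         # column-major of t(m) == row-major of m
  hi <- as.raw(vals %/% 256L)
  lo <- as.raw(vals %% 256L)
  px <- as.raw(rbind(hi, lo))          # big-endian sample interleave
  dim(px) <- NULL
  rows <- matrix(px, nrow = 2L * w)
  scan <- as.raw(rbind(rep(as.raw(0L), h), rows))  # filter byte 0 per scanline
  dim(scan) <- NULL
  ihdr <- c(.u32be(w), .u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(
    as.raw(c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)),
    .png_chunk("IHDR", ihdr),
    .png_chunk("IDAT", memCompress(scan, "gzip")),
    .png_chunk("IEND", raw(0L))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
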
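# Minimal 16-bit grayscale PNG writer used to exercise 16-bit raster input
# without shipping binary fixtures. Pixels are stored uncompressed inside a
# valid zlib stream (deflate "stored" blocks), with CRC32/Adler32 computed in
# plain R; fine for the tiny test images.

png16_crc32 <- function(bytes) {
  # reflected CRC-32, polynomial 0xEDB88320, bit vectors LSB-first
  poly_msb <- c(1,1,1,0, 1,1,0,1, 1,0,1,1, 1,0,0,0,
                1,0,0,0, 0,0,1,1, 0,0,1,0, 0,0,0,0) == 1
  poly <- rev(poly_msb)
  crc <- rep(TRUE, 32L)
  for (b in as.integer(bytes)) {
    bbits <- as.logical(intToBits(b))[1:8]
    for (k in 1:8) {
      fb <- xor(crc[1L], bbits[k])
      crc <- c(crc[-1L], FALSE)
      if (fb) crc <- xor(crc, poly)
    }
  }
  sum(2^(0:31) * !crc)
}

png16_adler32 <- function(bytes) {
  a <- 1
  b <- 0
  for (v in as.integer(bytes)) {
    a <- (a + v) %% 65521
    b <- (b + a) %% 65521
  }
  b * 65536 + a
}

png16_be <- function(value, n) {
  as.raw(sapply(rev(seq_len(n)) - 1L, function(k) floor(value / 256^k) %% 256))
}

png16_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(png16_be(length(data), 4L), body, png16_be(png16_crc32(body), 4L))
}

# values: integer matrix in [0, 65535]
write_png16 <- function(values, path) {
  h <- nrow(values)
  w <- ncol(values)
  ihdr <- c(png16_be(w, 4L), png16_be(h, 4L),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))   # 16-bit, grayscale
  scan <- unlist(lapply(seq_len(h), function(r) {
    px <- as.vector(rbind(values[r, ] %/% 256L, values[r, ] %% 256L))
    c(0L, px)   # filter byte 0 then big-endian 16-bit samples
  }))
  stopifnot(length(scan) <= 65535)   # single stored deflate block
  zlib <- c(as.raw(c(0x78, 0x01, 0x01)),
            png16_be(length(scan), 2L)[2:1],              # LEN little-endian
            png16_be(bitwAnd(bitwXor(length(scan), 0xFFFF), 0xFFFF), 2L)[2:1],
            as.raw(scan),
            png16_be(png16_adler32(scan), 4L))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png16_chunk("IHDR", ihdr),
           png16_chunk("IDAT", zlib),
           png16_chunk("IEND", raw(0L)))
  writeBin(out, path)
  invisible(path)
}
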
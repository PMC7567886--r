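# Minimal stored (uncompressed) ZIP writer so ROI-set reading can be
# tested without an external zip binary; utils::unzip validates it.

.crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  vapply(0:255, function(i) {
    c <- as.integer(i)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), poly)
      } else {
        bitwShiftR(c, 1L)
      }
    }
    c
  }, integer(1))
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), .crc32_table[idx + 1L])
  }
  bitwXor(crc, -1L)
}

.le <- function(value, n_bytes) {
  # little-endian raw encoding of a signed 32-bit integer
  out <- raw(n_bytes)
  v <- value
  for (i in seq_len(n_bytes)) {
    out[i] <- as.raw(bitwAnd(v, 255L))
    v <- bitwShiftR(v, 8L)
  }
  out
}

write_stored_zip <- function(zip_path, files, dir) {
  con <- file(zip_path, "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  entries <- list()
  pos <- 0L
  for (i in seq_along(files)) {
    data <- readBin(file.path(dir, files[i]), "raw",
                    file.info(file.path(dir, files[i]))$size)
    name <- charToRaw(files[i])
    crc <- crc32(data)
    header <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), .le(20L, 2), .le(0L, 2),
                .le(0L, 2), .le(0L, 2), .le(0L, 2), .le(crc, 4),
                .le(length(data), 4), .le(length(data), 4),
                .le(length(name), 2), .le(0L, 2), name)
    offsets[i] <- pos
    writeBin(c(header, data), con)
    pos <- pos + length(header) + length(data)
    entries[[i]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), .le(20L, 2),
                      .le(20L, 2), .le(0L, 2), .le(0L, 2), .le(0L, 2),
                      .le(0L, 2), .le(crc, 4), .le(length(data), 4),
                      .le(length(data), 4), .le(length(name), 2),
                      .le(0L, 2), .le(0L, 2), .le(0L, 2), .le(0L, 2),
                      .le(0L, 4), .le(offsets[i], 4), name)
  }
  cd <- do.call(c, entries)
  writeBin(cd, con)
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), .le(0L, 2), .le(0L, 2),
             .le(length(files), 2), .le(length(files), 2),
             .le(length(cd), 4), .le(pos, 4), .le(0L, 2)), con)
  invisible(zip_path)
}
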
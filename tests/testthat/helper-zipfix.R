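# Minimal stored-format (no compression) ZIP writer, used to build PHD-zip
# fixtures in code: no zip binary is assumed to exist.

.crc32_table <- local({
  t <- integer(256)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) != 0L)
        bitwXor(bitwShiftR(cc, 1L), -306674912L)  # 0xEDB88320
      else bitwShiftR(cc, 1L)
    }
    t[i + 1L] <- cc
  }
  t
})

.crc32 <- function(bytes) {
  cc <- -1L
  for (b in as.integer(bytes)) {
    cc <- bitwXor(bitwShiftR(cc, 8L),
                  .crc32_table[bitwAnd(bitwXor(cc, b), 255L) + 1L])
  }
  cc <- bitwXor(cc, -1L)
  if (cc < 0) cc + 2^32 else as.numeric(cc)
}

.le_bytes <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# files: named character vector (name -> content)
write_stored_zip <- function(files, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  central <- list()
  pos <- 0
  for (i in seq_along(files)) {
    nm <- names(files)[i]
    data <- charToRaw(files[[i]])
    crc <- .crc32(data)
    offsets[i] <- pos
    hdr <- c(.le_bytes(0x04034b50, 4), .le_bytes(20, 2), .le_bytes(0, 2),
             .le_bytes(0, 2), .le_bytes(0, 2), .le_bytes(0x21, 2),
             .le_bytes(crc, 4), .le_bytes(length(data), 4),
             .le_bytes(length(data), 4), .le_bytes(nchar(nm), 2),
             .le_bytes(0, 2))
    writeBin(hdr, con)
    writeBin(charToRaw(nm), con)
    writeBin(data, con)
    pos <- pos + length(hdr) + nchar(nm) + length(data)
    central[[i]] <- c(.le_bytes(0x02014b50, 4), .le_bytes(20, 2),
                      .le_bytes(20, 2), .le_bytes(0, 2), .le_bytes(0, 2),
                      .le_bytes(0, 2), .le_bytes(0x21, 2), .le_bytes(crc, 4),
                      .le_bytes(length(data), 4), .le_bytes(length(data), 4),
                      .le_bytes(nchar(nm), 2), .le_bytes(0, 2),
                      .le_bytes(0, 2), .le_bytes(0, 2), .le_bytes(0, 2),
                      .le_bytes(0, 4), .le_bytes(offsets[i], 4),
                      charToRaw(nm))
  }
  cd_start <- pos
  for (ce in central) { writeBin(ce, con); pos <- pos + length(ce) }
  eocd <- c(.le_bytes(0x06054b50, 4), .le_bytes(0, 2), .le_bytes(0, 2),
            .le_bytes(length(files), 2), .le_bytes(length(files), 2),
            .le_bytes(pos - cd_start, 4), .le_bytes(cd_start, 4),
            .le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

phd_text <- function(id, bases, quals) {
  paste(c(paste("BEGIN_SEQUENCE", id), "", "BEGIN_DNA",
          paste(bases, quals, seq_along(quals)), "END_DNA", "",
          "END_SEQUENCE", ""), collapse = "\n")
}
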
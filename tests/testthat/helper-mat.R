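# Minimal MAT v5 writer used to build binary fixtures at test time,
# implemented directly from the format layout, independently of the reader.

write_mat_v5_fixture <- function(path, vars) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-116s", "MATLAB 5.0 MAT-file, test fixture"))
  writeBin(header, con)
  writeBin(raw(8), con)                                   # subsys offset
  writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100
  writeBin(charToRaw("IM"), con)                          # little-endian
  for (nm in names(vars)) {
    v <- as.numeric(vars[[nm]])
    name_raw <- charToRaw(nm)
    name_pad <- (8 - length(name_raw) %% 8) %% 8
    body_len <- 16 +                                      # array flags
      16 +                                                # dims (2 x int32 + pad)
      8 + length(name_raw) + name_pad +                   # name
      8 + 8 * length(v)                                   # double data
    writeBin(as.integer(c(14L, body_len)), con, size = 4)             # miMATRIX tag
    writeBin(c(6L, 8L), con, size = 4)                    # flags subelement
    writeBin(c(6L, 0L), con, size = 4)                    # mxDOUBLE, nzmax
    writeBin(c(5L, 8L), con, size = 4)                    # dims subelement
    writeBin(as.integer(c(1L, length(v))), con, size = 4)             # 1 x n
    writeBin(as.integer(c(1L, length(name_raw))), con, size = 4)      # name subelement
    writeBin(name_raw, con)
    if (name_pad) writeBin(raw(name_pad), con)
    writeBin(as.integer(c(9L, 8L * length(v))), con, size = 4)        # miDOUBLE data
    writeBin(v, con, size = 8)
  }
  invisible(path)
}
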
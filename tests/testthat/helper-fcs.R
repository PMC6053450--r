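# Independent FCS 3.0 writer used only to build test fixtures, so the
# package's reader is checked against a writer it shares no code with.
# List-mode, float32, little-endian, offsets in the 58-byte HEADER.
writeFcsFixture <- function(path, mat, stainNames = colnames(mat),
                            shortNames = paste0("FL", seq_len(ncol(mat)), "-A")) {
  nPar <- ncol(mat); nTot <- nrow(mat)
  d <- "/"
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", nPar, "$TOT", nTot)
  for (j in seq_len(nPar)) {
    kv <- c(kv, sprintf("$P%dN", j), shortNames[j],
            sprintf("$P%dB", j), 32,
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), 262144)
    if (!is.null(stainNames) && nzchar(stainNames[j]))
      kv <- c(kv, sprintf("$P%dS", j), stainNames[j])
  }
  text <- paste0(d, paste(kv, collapse = d), d)
  textBegin <- 58L
  textEnd <- textBegin + nchar(text) - 1L
  dataBegin <- 1024L
  dataEnd <- dataBegin + 4L * nPar * nTot - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    textBegin, textEnd, dataBegin, dataEnd, 0L, 0L)
  stopifnot(nchar(header) == 58L, textEnd < dataBegin)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(raw(dataBegin - textEnd - 1L), con)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}
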
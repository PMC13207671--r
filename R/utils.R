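# Shared TSV helpers: UTF-8, Unix newlines, NA written as empty field.

write_tsv <- function(df, path, na = "") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = na,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# Deterministic numeric formatting: as.character() round-trips doubles at
# up to 15 significant digits, so write(read(f)) is byte-stable.
fmt_num <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- ""
  out
}
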
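TRANSCRIPTION_COLUMNS <- c("speaker", "modality", "movement", "shape",
                           "size", "sound", "ipa")

validate_records <- function(df) {
  problems <- character(0)
  bad_mod <- which(!(df$modality %in% c("A", "V", "AV")))
  if (length(bad_mod))
    problems <- c(problems, sprintf("row %d: unknown modality '%s'",
                                    bad_mod, df$modality[bad_mod]))
  bad_mov <- which(!(df$movement %in% MOVEMENTS))
  if (length(bad_mov))
    problems <- c(problems, sprintf("row %d: unknown movement '%s'",
                                    bad_mov, df$movement[bad_mov]))
  # modality-specific n/a structure
  a <- df$modality == "A"
  v <- df$modality == "V"
  av <- df$modality == "AV"
  bad_a <- which(a & (!is.na(df$shape) | !is.na(df$size)))
  if (length(bad_a))
    problems <- c(problems,
                  sprintf("row %d: audio record with shape/size set", bad_a))
  bad_v <- which(v & !is.na(df$sound))
  if (length(bad_v))
    problems <- c(problems, sprintf("row %d: video record with sound set", bad_v))
  bad_av <- which(av & (is.na(df$shape) | is.na(df$size) | is.na(df$sound)))
  if (length(bad_av))
    problems <- c(problems,
                  sprintf("row %d: audiovisual record with missing factor", bad_av))
  bad_ipa <- which(is.na(df$ipa) | !nzchar(df$ipa))
  if (length(bad_ipa))
    problems <- c(problems, sprintf("row %d: empty ipa string", bad_ipa))
  problems
}

#' Read a transcription table
#'
#' UTF-8 tab-delimited table with header columns speaker, modality,
#' movement, shape, size, sound, ipa (empty cells for factors that do not
#' apply to a modality). Rows are validated against the modality
#' invariants (audio records carry no shape/size, video records no
#' sound, audiovisual records all factors) and offending rows are
#' reported together in one error.
#'
#' @param path TSV path.
#' @param quiet suppress the per-modality count message.
#' @return validated records data frame.
#' @export
read_transcriptions <- function(path, quiet = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                   na.strings = c("NA", ""))
  miss <- setdiff(TRANSCRIPTION_COLUMNS, names(df))
  if (length(miss))
    stop("transcription table missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, TRANSCRIPTION_COLUMNS]
  df$speaker <- as.character(df$speaker)
  problems <- validate_records(df)
  if (length(problems))
    stop("invalid transcription rows:\n  ",
         paste(head(problems, 20L), collapse = "\n  "))
  if (!quiet) {
    cnt <- table(df$modality)
    message("read ", nrow(df), " records (",
            paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", "), ")")
  }
  df
}

#' Write a transcription table
#'
#' Inverse of [read_transcriptions()]: UTF-8 TSV, `NA` cells written
#' empty, round-trip faithful.
#'
#' @param records records data frame.
#' @param path output path.
#' @export
write_transcriptions <- function(records, path) {
  miss <- setdiff(TRANSCRIPTION_COLUMNS, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  df <- records[, TRANSCRIPTION_COLUMNS]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
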
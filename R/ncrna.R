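#' Read a curated ncRNA differential-expression table
#'
#' Reads a TSV of curated long non-coding RNAs with, per RNA, the mean
#' conservation score, the orientation class relative to the closest
#' coding gene, and three-valued differential-expression codes per stage
#' pair (+1 up, -1 down, 0 no change).  The package ships one such table
#' (transcribed from a published tabulation) at
#' `system.file("extdata", "ncrna_de_table.tsv", package = "tiletx")`.
#'
#' @param path TSV path with columns `symbol`, `location`,
#'   `conservation_mean`, `orientation`, `closest_coding_gene`, and one
#'   `de_<pair>` column per pair.
#' @return data.frame of class `ncrna_records`.
#' @export
read_ncrna_records <- function(path) {
  rec <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  de_cols <- grep("^de_", names(rec), value = TRUE)
  if (length(de_cols) == 0) stop("no de_<pair> columns found")
  for (col in de_cols) {
    bad <- which(!rec[[col]] %in% c(-1L, 0L, 1L))
    if (length(bad))
      stop("invalid differential code in column ", col, ", row ", bad[1])
  }
  class(rec) <- c("ncrna_records", "data.frame")
  rec
}

#' Tabulate ncRNA differential-expression directions
#'
#' For each stage pair, the number of up-regulated (+1) and
#' down-regulated (-1) records, plus the total number of distinct
#' records.
#'
#' @param records a [read_ncrna_records()] result.
#' @return list: `by_pair` (data.frame `pair`, `up`, `down`), `total`.
#' @export
tabulate_ncrna_de <- function(records) {
  de_cols <- grep("^de_", names(records), value = TRUE)
  by_pair <- do.call(rbind, lapply(de_cols, function(col) {
    data.frame(pair = sub("^de_", "", col),
               up = sum(records[[col]] == 1),
               down = sum(records[[col]] == -1),
               stringsAsFactors = FALSE)
  }))
  list(by_pair = by_pair, total = nrow(records))
}

#' Orientation of an ncRNA relative to its closest coding gene
#'
#' `antisense` when the spans overlap on opposite strands; otherwise the
#' class is `<ncRNA end>-to-<gene end>` where each word is `head` (5')
#' or `tail` (3') for the two facing ends.  Divergent promoter pairs are
#' therefore `head-to-head`, adjacent 3' ends on opposite strands
#' `tail-to-tail`.
#'
#' @param ncrna,coding one-row data.frames (or lists) with `chrom`,
#'   `start`, `end`, `strand` (`+` or `-`; unknown strand is an error).
#' @return character scalar orientation class.
#' @export
orientation_classify <- function(ncrna, coding) {
  s1 <- ncrna$strand; s2 <- coding$strand
  if (!s1 %in% c("+", "-") || !s2 %in% c("+", "-"))
    stop("orientation requires known strands")
  if (ncrna$chrom == coding$chrom &&
      ncrna$start < coding$end && coding$start < ncrna$end &&
      s1 != s2)
    return("antisense")
  nc_left <- (ncrna$start + ncrna$end) / 2 < (coding$start + coding$end) / 2
  # facing end of the ncRNA and of the gene, as head (5') or tail (3')
  nc_word <- if (nc_left) {
    if (s1 == "-") "head" else "tail"   # right end faces the gene
  } else {
    if (s1 == "+") "head" else "tail"   # left end faces the gene
  }
  g_word <- if (nc_left) {
    if (s2 == "+") "head" else "tail"   # gene's left end faces the ncRNA
  } else {
    if (s2 == "-") "head" else "tail"
  }
  paste0(nc_word, "-to-", g_word)
}
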
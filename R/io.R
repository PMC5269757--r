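#' Read a FASTA file into a tibble
#'
#' Sequences are returned uppercase; both multi-line and single-line FASTA are
#' accepted. An empty file yields an empty tibble rather than an error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id` (first whitespace-delimited token
#'   of the header) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) {
    return(tibble(contig_id = character(), sequence = character()))
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    abort(paste0("malformed FASTA header at line 1 of ", path,
                 ": expected '>', got '", substr(first, 1, 20), "'"))
  }
  x <- Biostrings::readBStringSet(path, format = "fasta")
  tibble(
    contig_id = vapply(strsplit(names(x), "\\s+"), `[`, "", 1L),
    sequence  = unname(toupper(as.character(x)))
  )
}

#' Write sequences to FASTA
#'
#' @param records A data frame with columns `contig_id` and `sequence`, or a
#'   named character vector.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  if (is.data.frame(records)) {
    seqs <- setNames(records$sequence, records$contig_id)
  } else {
    seqs <- records
  }
  x <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(x, path, format = "fasta", width = wrap)
  invisible(path)
}

#' Read a pair of FASTQ files as a paired read stream
#'
#' Mates are paired by record order. Record counts must agree.
#'
#' @param path1,path2 Paths to mate-1 and mate-2 FASTQ files.
#' @return A tibble with columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- .read_fastq_one(path1)
  r2 <- .read_fastq_one(path2)
  if (nrow(r1) != nrow(r2)) {
    abort(paste0("unequal FASTQ record counts: ", nrow(r1), " in ", path1,
                 " vs ", nrow(r2), " in ", path2))
  }
  tibble(
    read_id = r1$id,
    seq1 = r1$seq, qual1 = r1$qual,
    seq2 = r2$seq, qual2 = r2$qual
  )
}

.read_fastq_one <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  # Biostrings warns about dropping (empty) mcols on the qualities; benign
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
  tibble(
    id   = sub("/[12]$", "", ids),
    seq  = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write a paired read stream to two FASTQ files
#'
#' @param reads A tibble as produced by [read_fastq_pair()] or
#'   [simulate_reads()]: columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param path1,path2 Output paths for mate 1 and mate 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  .write_fastq_one(reads$read_id, reads$seq1, reads$qual1, path1, "/1")
  .write_fastq_one(reads$read_id, reads$seq2, reads$qual2, path2, "/2")
  invisible(c(path1, path2))
}

.write_fastq_one <- function(ids, seqs, quals, path, suffix) {
  if (length(ids) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(quals)
  )
  names(x) <- paste0(ids, suffix)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write a tibble as a TSV report with a commented header
#'
#' Tabular pipeline outputs use plain TSV whose first line is a `#`-prefixed
#' column header, so files diff cleanly and round-trip with [read_report_tsv()].
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t")[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE)
  as_tibble(df)
}
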
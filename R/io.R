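## Plain-text serialization: FASTA/FASTQ via Biostrings, TSV for truth
## tables and reports.

#' Read a FASTA file into a contig data.frame
#'
#' @param path FASTA file path.
#' @param type `"DNA"` or `"AA"`.
#' @return data.frame with `id`, `sequence`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(set)),
             sequence = as.character(set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences to FASTA
#'
#' @param x data.frame with `id`, `sequence` (or `protein` when
#'   `column = "protein"`), or a named character vector.
#' @param path Output path.
#' @param column Sequence column to write when `x` is a data.frame.
#' @param type `"DNA"` or `"AA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, column = "sequence", type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.data.frame(x)) x <- stats::setNames(x[[column]], x$id)
  set <- if (type == "DNA") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write reads to FASTQ with a fixed quality of 'I'
#'
#' Synthetic reads are error-free, so a constant Phred-40 quality line is
#' written.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% sprintf("read_%d", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+",
                           strrep("I", nchar(reads))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic-truth table to TSV
#'
#' One row per emitted contig: `contig_id`, `source_ids`, `identity`,
#' `frag_start`, `frag_end`, `breakpoint`, `partner_id`, `segment_class`.
#' Missing fields are written as `NA`.
#'
#' @param truth List of per-contig truth records (named lists).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  cols <- c("contig_id", "source_ids", "identity", "frag_start", "frag_end",
            "breakpoint", "partner_id", "segment_class")
  rows <- lapply(truth, function(tr) {
    vals <- lapply(cols, function(cn) {
      v <- tr[[cn]]
      if (is.null(v)) NA else paste(v, collapse = ",")
    })
    stats::setNames(as.data.frame(vals, stringsAsFactors = FALSE), cols)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
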
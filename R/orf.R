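## ORF discovery under alternate genetic codes.
##
## Mito- and narna-like viruses replicate in mitochondria or infect
## mollicute-like hosts whose translation uses NCBI table 4 (TGA = Trp
## instead of stop), so ORF calling must be run under both the standard code
## and table 4 and the longer product kept.

genetic_code_table <- function(genetic_code) {
  if (!genetic_code %in% c(1L, 4L)) {
    stop("unsupported genetic code table: ", genetic_code, " (supported: 1, 4)")
  }
  Biostrings::getGeneticCode(as.character(genetic_code))
}

translate_nt <- function(seq, genetic_code = 1L) {
  code <- genetic_code_table(genetic_code)
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  starts <- seq(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

orf_record <- function(contig_id, frame, start, end, protein, genetic_code) {
  list(contig_id = contig_id, frame = as.integer(frame),
       start = as.integer(start), end = as.integer(end),
       length_nt = as.integer(end - start), protein = protein,
       genetic_code = as.integer(genetic_code))
}

orfs_in_frame <- function(seq, offset, genetic_code, min_len_nt, start_codons) {
  n <- nchar(seq)
  n_codons <- (n - offset) %/% 3L
  if (n_codons < 2L) return(list())
  starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  code <- genetic_code_table(genetic_code)
  aa <- unname(code[codons]); aa[is.na(aa)] <- "X"
  is_stop <- aa == "*"
  is_start <- codons %in% start_codons
  out <- list()
  seg_start <- 1L  # codon index opening the current stop-free segment
  for (i in seq_len(n_codons)) {
    if (is_stop[i]) {
      starts_in_seg <- which(is_start[seg_start:i]) + seg_start - 1L
      starts_in_seg <- starts_in_seg[starts_in_seg < i]
      if (length(starts_in_seg)) {
        s <- starts_in_seg[1L]  # maximal ORF: first start after previous stop
        len_nt <- (i - s + 1L) * 3L
        if (len_nt >= min_len_nt) {
          out[[length(out) + 1L]] <- list(
            codon_start = s, codon_stop = i, len_nt = len_nt,
            protein = paste(aa[s:(i - 1L)], collapse = ""))
        }
      }
      seg_start <- i + 1L
    }
  }
  out
}

#' Find open reading frames in all six frames
#'
#' Reports every maximal start-to-stop ORF of at least `min_len_nt`
#' nucleotides across the six reading frames. "Maximal" means the ORF opens
#' at the first start codon following the previous in-frame stop and runs
#' through the next stop codon; the reported nucleotide length includes the
#' stop codon while the protein excludes it. Under genetic code table 4,
#' `TGA` is translated as tryptophan rather than stop, so ORFs interrupted
#' by `TGA` under the standard code read through. Coordinates are always
#' reported on the forward strand as 0-based half-open intervals; negative
#' frames index the reverse complement.
#'
#' @param seq Nucleotide string of length >= 3.
#' @param genetic_code NCBI translation table, 1 (standard) or 4
#'   (mold/protozoan/coelenterate mitochondrial; mycoplasma/spiroplasma).
#' @param min_len_nt Minimum ORF length in nucleotides, stop included
#'   (default 150).
#' @param start_codons Accepted initiation codons (default `"ATG"`; supply
#'   `c("ATG","GTG","TTG")` to adapt initiation codes).
#' @param contig_id Identifier carried into each record.
#' @return A list of ORF records (`contig_id`, `frame`, `start`, `end`,
#'   `length_nt`, `protein`, `genetic_code`), sorted by decreasing length
#'   with ties broken by frame then start.
#' @export
find_orfs <- function(seq, genetic_code = 1L, min_len_nt = 150L,
                      start_codons = "ATG", contig_id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 3L) stop("sequence must be at least 3 nt")
  genetic_code_table(genetic_code)  # validate early
  n <- nchar(seq)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else revcomp(seq)
    for (offset in 0:2) {
      frame <- strand * (offset + 1L)
      for (o in orfs_in_frame(s, offset, genetic_code, min_len_nt, start_codons)) {
        ## nt coordinates on the scanned strand, 0-based half-open
        s0 <- offset + 3L * (o$codon_start - 1L)
        e0 <- offset + 3L * o$codon_stop
        if (strand == 1L) {
          start <- s0; end <- e0
        } else {
          start <- n - e0; end <- n - s0
        }
        out[[length(out) + 1L]] <-
          orf_record(contig_id, frame, start, end, o$protein, genetic_code)
      }
    }
  }
  if (!length(out)) return(out)
  ord <- order(-vapply(out, `[[`, integer(1), "length_nt"),
               vapply(out, `[[`, integer(1), "frame"),
               vapply(out, `[[`, integer(1), "start"))
  out[ord]
}

#' Longest ORF across genetic codes
#'
#' Runs [find_orfs()] under each requested genetic code and returns the
#' single longest ORF, recording which code produced it. Ties between codes
#' favor the code listed first.
#'
#' @inheritParams find_orfs
#' @param codes Genetic code tables to try (default `c(1, 4)`).
#' @return The longest ORF record, or `NULL` when no ORF of at least
#'   `min_len_nt` exists under any requested code.
#' @export
longest_orf <- function(seq, codes = c(1L, 4L), min_len_nt = 150L,
                        start_codons = "ATG", contig_id = "seq") {
  best <- NULL
  for (code in codes) {
    orfs <- find_orfs(seq, genetic_code = code, min_len_nt = min_len_nt,
                      start_codons = start_codons, contig_id = contig_id)
    if (length(orfs) && (is.null(best) || orfs[[1]]$length_nt > best$length_nt)) {
      best <- orfs[[1]]
    }
  }
  best
}

#' Phylogeny-inclusion filter
#'
#' A contig qualifies for phylogenetic reconstruction when it is longer than
#' `min_contig_len` nucleotides and its ORF product exceeds half the length
#' of its nearest known hit's protein, so that partial polymerases too short
#' to align reliably are excluded.
#'
#' @param contig_len Contig length in nucleotides.
#' @param orf_protein_len ORF product length in amino acids.
#' @param best_hit_protein_len Protein length of the nearest known hit (aa).
#' @param min_contig_len Strict lower bound on contig length (default 500).
#' @return `TRUE` or `FALSE`.
#' @export
phylogeny_inclusion <- function(contig_len, orf_protein_len,
                                best_hit_protein_len, min_contig_len = 500L) {
  stopifnot(best_hit_protein_len > 0)
  contig_len > min_contig_len && orf_protein_len > best_hit_protein_len / 2
}

orfs_to_data_frame <- function(orfs) {
  if (!length(orfs)) {
    return(data.frame(contig_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      length_nt = integer(0), genetic_code = integer(0),
                      protein = character(0)))
  }
  data.frame(
    contig_id = vapply(orfs, `[[`, character(1), "contig_id"),
    frame = vapply(orfs, `[[`, integer(1), "frame"),
    start = vapply(orfs, `[[`, integer(1), "start"),
    end = vapply(orfs, `[[`, integer(1), "end"),
    length_nt = vapply(orfs, `[[`, integer(1), "length_nt"),
    genetic_code = vapply(orfs, `[[`, integer(1), "genetic_code"),
    protein = vapply(orfs, `[[`, character(1), "protein"),
    stringsAsFactors = FALSE)
}
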
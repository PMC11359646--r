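#' @importFrom withr with_seed
NULL

#' Fermentation time-point labels
#'
#' The three RNA libraries the pipeline is built around were sampled at 7,
#' 20 and 68 hours of cocoa bean fermentation; every abundance table and
#' presence matrix in the package uses these labels as its column names.
#'
#' @format Character vector of length 3: `c("7h", "20h", "68h")`.
#' @export
TIMEPOINTS <- c("7h", "20h", "68h")

DNA_BASES <- c("A", "C", "G", "T")
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Every generator is a pure function of (args, seed); withr restores the
## caller's RNG state so package code never perturbs the session stream.
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character scalar over `A/C/G/T/N`.
#' @return Character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

substr_safe <- function(x, start, stop) {
  if (stop < start) "" else substr(x, start, stop)
}

## Shared k-mer screen used to skip hopeless alignments: two sequences that
## are >= ~90% identical over the shorter one share many exact k-mers, while
## unrelated sequences of a few kb share essentially none at k = 16.
shares_kmer <- function(a, b, k = 16L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(TRUE)
  if (nb < na) { tmp <- a; a <- b; b <- tmp; na <- nchar(a) }
  starts <- unique(c(seq(1L, na - k + 1L, by = k), na - k + 1L))
  kmers <- substring(a, starts, starts + k - 1L)
  brc <- revcomp(b)
  for (km in kmers) {
    if (grepl(km, b, fixed = TRUE) || grepl(km, brc, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

`%||%` <- function(x, y) if (is.null(x)) y else x
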
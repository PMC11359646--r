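## Pairwise alignment primitives.
##
## Identity/coverage from semiglobal (ends-free) alignment drive redundancy
## clustering and known/novel classification; the two terminal-overlap
## scanners implement the end-alignment rules used for contig extension
## (bounded-mismatch rule) and split-segment association (exact pairing).

nt_substitution_matrix <- function(match = 2, mismatch = -3) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

detect_alphabet <- function(x) {
  if (grepl("^[ACGTN]+$", x)) "nucleotide" else "protein"
}

#' Default alignment scoring schemes
#'
#' Nucleotide alignments use match +2 / mismatch -3 with affine gaps costing
#' -5 to open (first gapped position included) and -2 per additional
#' position. Protein alignments use BLOSUM62 with gap open -11 / extend -1.
#'
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A list with elements `substitution` (matrix), `gap_opening` and
#'   `gap_extension` (non-negative costs in `Biostrings` convention, where a
#'   gap of length L costs `gap_opening + L * gap_extension`).
#' @export
alignment_scoring <- function(alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nucleotide") {
    list(substitution = nt_substitution_matrix(), gap_opening = 3, gap_extension = 2)
  } else {
    list(substitution = blosum62(), gap_opening = 10, gap_extension = 1)
  }
}

#' Semiglobal (ends-free) pairwise alignment with identity and coverage
#'
#' Aligns two sequences end-gap free, the alignment mode under which a
#' fragment aligns to its source without terminal gap penalties. Identity is
#' computed over aligned columns (end gaps excluded); coverage is reported
#' both for the query and for the shorter of the two sequences, because
#' clustering (CD-HIT convention) and translated-search filters consume
#' different denominators.
#'
#' @param a,b Character scalars over a common alphabet (`A/C/G/T/N`
#'   nucleotide, otherwise amino acid).
#' @param query_id,target_id Optional identifiers carried into the result.
#' @param scoring Scoring scheme as returned by [alignment_scoring()];
#'   defaults to the alphabet-appropriate scheme.
#' @return A list of class `"AlignmentResult"`: `query_id`, `target_id`,
#'   `score`, `identity_pct`, `query_cov_pct`, `shorter_cov_pct`,
#'   `query_span` and `target_span` (0-based half-open on the respective
#'   sequences), `n_mismatches`, `n_gaps`, `n_columns`.
#' @export
semiglobal_align <- function(a, b, query_id = "query", target_id = "target",
                             scoring = NULL) {
  pairwise_align(a, b, type = "overlap", query_id = query_id,
                 target_id = target_id, scoring = scoring)
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' Same result contract as [semiglobal_align()] but in local mode: only the
#' highest-scoring sub-alignment is reported. Used where a contig may match
#' a reference over part of its length only — notably when collecting the
#' split hits that betray a chimera.
#'
#' @inheritParams semiglobal_align
#' @return An `"AlignmentResult"`, see [semiglobal_align()].
#' @export
local_align <- function(a, b, query_id = "query", target_id = "target",
                        scoring = NULL) {
  pairwise_align(a, b, type = "local", query_id = query_id,
                 target_id = target_id, scoring = scoring)
}

pairwise_align <- function(a, b, type, query_id, target_id, scoring = NULL) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  alpha_a <- detect_alphabet(a)
  alpha_b <- detect_alphabet(b)
  if (alpha_a != alpha_b) {
    stop("sequences must share an alphabet (got ", alpha_a, " vs ", alpha_b, ")")
  }
  if (is.null(scoring)) scoring <- alignment_scoring(alpha_a)
  if (alpha_a == "nucleotide") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
      substitutionMatrix = scoring$substitution,
      gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = type,
      substitutionMatrix = scoring$substitution,
      gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension)
  }
  pat <- as.character(Biostrings::alignedPattern(pa))
  sub <- as.character(Biostrings::alignedSubject(pa))
  pr <- pa@pattern@range
  sr <- pa@subject@range
  n_cols <- nchar(pat)
  pc <- seq_chars(pat); sc <- seq_chars(sub)
  n_match <- sum(pc == sc & pc != "-")
  n_gaps <- sum(pc == "-") + sum(sc == "-")
  n_mismatch <- n_cols - n_match - n_gaps
  na <- nchar(a); nb <- nchar(b)
  shorter_len <- min(na, nb)
  shorter_width <- if (na <= nb) BiocGenerics::width(pr) else BiocGenerics::width(sr)
  res <- list(
    query_id = query_id, target_id = target_id,
    score = Biostrings::score(pa),
    identity_pct = if (n_cols > 0) 100 * n_match / n_cols else 0,
    query_cov_pct = 100 * BiocGenerics::width(pr) / na,
    shorter_cov_pct = 100 * shorter_width / shorter_len,
    query_span = c(BiocGenerics::start(pr) - 1L, BiocGenerics::end(pr)),
    target_span = c(BiocGenerics::start(sr) - 1L, BiocGenerics::end(sr)),
    n_mismatches = n_mismatch, n_gaps = n_gaps, n_columns = n_cols)
  class(res) <- "AlignmentResult"
  res
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult %s vs %s: score %.1f, identity %.1f%%, query cov %.1f%%\n",
              x$query_id, x$target_id, x$score, x$identity_pct, x$query_cov_pct))
  invisible(x)
}

overlap_result <- function(left_id, right_id, overlap_len, mismatches,
                           accepted, orientation, containment = FALSE) {
  res <- list(left_id = left_id, right_id = right_id,
              overlap_len = as.integer(overlap_len),
              n_mismatches = length(mismatches),
              mismatch_positions = as.integer(mismatches),
              accepted = accepted, orientation = orientation,
              containment = containment)
  class(res) <- "OverlapResult"
  res
}

rule_accepts <- function(mismatch_offsets, max_mismatches, allow_adjacent) {
  n <- length(mismatch_offsets)
  if (n > max_mismatches) return(FALSE)
  if (!allow_adjacent && n >= 2 && any(diff(mismatch_offsets) == 1L)) return(FALSE)
  TRUE
}

## Match counts between suffix_k(a) and prefix_k(b) for every k at once,
## via FFT cross-correlation of per-base indicator vectors (O(L log L)
## instead of O(L^2); counts are integers, recovered by rounding).
terminal_match_counts <- function(ca, cb) {
  na <- length(ca); nb <- length(cb)
  N <- stats::nextn(na + nb)  # highly composite length keeps the FFT fast
  total <- numeric(N)
  for (base in c("A", "C", "G", "T", "N")) {
    ia <- as.numeric(ca == base)
    if (!any(ia > 0)) next
    ib <- as.numeric(cb == base)
    if (!any(ib > 0)) next
    total <- total + Re(stats::fft(stats::fft(c(ia, numeric(N - na))) *
                                   Conj(stats::fft(c(ib, numeric(N - nb)))),
                                   inverse = TRUE)) / N
  }
  kmax <- min(na, nb)
  ## lag d = na - k; circular correlation index d + 1
  round(total[na - seq_len(kmax) + 1L])
}

mismatch_offsets_at <- function(ca, cb, k) {
  na <- length(ca)
  which(ca[(na - k + 1L):na] != cb[seq_len(k)]) - 1L
}

#' Terminal overlap under the bounded-mismatch end-alignment rule
#'
#' Scans all ungapped suffix(`a`)/prefix(`b`) overlaps of length at least
#' `min_len` and accepts an overlap when it carries at most `max_mismatches`
#' mismatches, none of them at adjacent offsets unless `allow_adjacent` is
#' set. The defaults encode the curation rule of at most 2 non-adjacent
#' mismatches within a window of at least 20 nucleotides. The longest
#' accepted overlap is returned; the reverse-complement orientation of `b`
#' is also scanned unless `check_rc = FALSE`, with ties between orientations
#' resolved in favor of forward.
#'
#' @param a,b Nucleotide strings, each at least `min_len` long.
#' @param min_len Minimum overlap window (default 20).
#' @param max_mismatches Mismatch budget over the whole overlap (default 2).
#' @param allow_adjacent Allow two mismatches at adjacent offsets
#'   (default `FALSE`).
#' @param check_rc Also scan `a` against the reverse complement of `b`.
#' @param per_window Stricter sliding interpretation: every `min_len`-wide
#'   sub-window of the overlap must itself respect the mismatch budget.
#' @param left_id,right_id Optional identifiers.
#' @return A list of class `"OverlapResult"`: `overlap_len`,
#'   `n_mismatches`, `mismatch_positions` (0-based offsets within the
#'   overlap), `accepted`, `orientation` (`"forward"` or `"rc"`), and
#'   `containment` (overlap spans the whole shorter sequence). When no
#'   overlap is accepted the fields describe the best-supported candidate
#'   (fewest mismatches, then longest) with `accepted = FALSE`.
#' @export
terminal_overlap <- function(a, b, min_len = 20L, max_mismatches = 2L,
                             allow_adjacent = FALSE, check_rc = TRUE,
                             per_window = FALSE,
                             left_id = "left", right_id = "right") {
  if (min_len < 1L) stop("min_len must be >= 1")
  stopifnot(nchar(a) >= min_len, nchar(b) >= min_len)
  ca <- seq_chars(a)
  orientations <- list(forward = seq_chars(b))
  if (check_rc) orientations$rc <- seq_chars(revcomp(b))
  max_len <- min(length(ca), nchar(b))

  ## per_window replaces the whole-overlap budget by a sliding one: every
  ## min_len-wide sub-window must respect max_mismatches (adjacency is
  ## still judged globally)
  accepts_candidate <- function(k, mm) {
    if (!per_window) return(rule_accepts(mm, max_mismatches, allow_adjacent))
    if (!allow_adjacent && length(mm) >= 2L && any(diff(mm) == 1L)) return(FALSE)
    if (k <= min_len) return(length(mm) <= max_mismatches)
    for (s in 0:(k - min_len)) {
      if (sum(mm >= s & mm < s + min_len) > max_mismatches) return(FALSE)
    }
    TRUE
  }

  best_accepted <- NULL
  best_candidate <- NULL
  for (ori in names(orientations)) {
    cb <- orientations[[ori]]
    counts <- terminal_match_counts(ca, cb)
    ks <- seq(max_len, min_len)
    n_mm <- ks - counts[ks]
    ## candidate overlap lengths within the mismatch budget, longest first,
    ## verified position-by-position for adjacency / sub-window constraints
    budget <- if (per_window) ceiling(ks / min_len) * max_mismatches
              else max_mismatches
    for (k in ks[n_mm <= budget]) {
      mm <- mismatch_offsets_at(ca, cb, k)
      cand <- list(k = k, mm = mm)
      if (accepts_candidate(k, mm)) {
        if (is.null(best_accepted) || k > best_accepted$k) {
          best_accepted <- c(cand, orientation = ori)
        }
        break  # longest-first within orientation
      }
    }
    if (is.null(best_accepted)) {
      ## diagnostic: best-supported window (fewest mismatches, then longest)
      i <- order(n_mm, -ks)[1L]
      cand <- list(k = ks[i], mm = mismatch_offsets_at(ca, cb, ks[i]))
      if (is.null(best_candidate) ||
          length(cand$mm) < length(best_candidate$mm)) {
        best_candidate <- c(cand, orientation = ori)
      }
    }
  }
  pick <- best_accepted %||% best_candidate
  overlap_result(left_id, right_id, pick$k, pick$mm,
                 accepted = !is.null(best_accepted),
                 orientation = pick$orientation,
                 containment = pick$k == max_len)
}

#' Longest exact terminal overlap (perfect pairing)
#'
#' Returns the maximal `k >= min_len` for which the length-`k` suffix of `a`
#' equals the length-`k` prefix of `b` (forward orientation only). Used for
#' split-segment association, where fragments of one RNA segment share a
#' perfect terminal pairing. A match spanning the whole shorter sequence is
#' reported but flagged as containment rather than overlap.
#'
#' @param a,b Nucleotide strings, each at least `min_len` long.
#' @param min_len Minimum accepted pairing length (default 18).
#' @param left_id,right_id Optional identifiers.
#' @return An `"OverlapResult"`; `overlap_len` is 0 with
#'   `accepted = FALSE` when no exact terminal match of at least `min_len`
#'   exists.
#' @export
exact_terminal_overlap <- function(a, b, min_len = 18L,
                                   left_id = "left", right_id = "right") {
  if (min_len < 1L) stop("min_len must be >= 1")
  stopifnot(nchar(a) >= min_len, nchar(b) >= min_len)
  na <- nchar(a)
  max_len <- min(na, nchar(b))
  for (k in seq(max_len, min_len)) {
    if (substr(a, na - k + 1L, na) == substr(b, 1L, k)) {
      containment <- k == max_len
      return(overlap_result(left_id, right_id, k, integer(0),
                            accepted = !containment, orientation = "forward",
                            containment = containment))
    }
  }
  overlap_result(left_id, right_id, 0L, integer(0),
                 accepted = FALSE, orientation = "forward")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult %s/%s: len %d, %d mismatch(es), %s, %s%s\n",
              x$left_id, x$right_id, x$overlap_len, x$n_mismatches,
              x$orientation, if (x$accepted) "accepted" else "rejected",
              if (x$containment) " (containment)" else ""))
  invisible(x)
}
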
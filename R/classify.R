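## Similarity search against a reference virome and known/novel status
## assignment. Nucleotide-level search is exhaustive semiglobal alignment;
## protein-level search translates all six frames (stops split candidate
## peptides) and aligns each peptide against every reference protein.

hit_record <- function(contig_id, reference_id, level, identity_pct,
                       query_cov_pct, family, frame = NA_integer_,
                       score = NA_real_) {
  list(contig_id = contig_id, reference_id = reference_id, level = level,
       identity_pct = identity_pct, query_cov_pct = query_cov_pct,
       family = family, frame = as.integer(frame), score = score)
}

six_frame_peptides <- function(seq, min_len_aa = 20L) {
  ## candidate peptides: stop-free stretches >= min_len_aa in any frame
  out <- list()
  n <- nchar(seq)
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else revcomp(seq)
    for (offset in 0:2) {
      aa <- translate_nt(substr(s, offset + 1L, n), genetic_code = 1L)
      if (!nzchar(aa)) next
      for (pep in strsplit(aa, "*", fixed = TRUE)[[1]]) {
        if (nchar(pep) >= min_len_aa) {
          out[[length(out) + 1L]] <- list(frame = strand * (offset + 1L),
                                          peptide = pep)
        }
      }
    }
  }
  out
}

#' Best reference hit per contig at nucleotide or protein level
#'
#' Desk-scale exhaustive similarity search. At nucleotide level each contig
#' is aligned semiglobally against every reference sequence; at protein
#' level every six-frame candidate peptide (stop-free stretch of at least
#' 20 aa) is aligned against every reference protein (BLOSUM62). The single
#' best-scoring hit per contig is returned, provided it passes the
#' minimal-evidence filters that separate genuine homology from the best
#' random alignment; ties are broken by reference id.
#'
#' @param contigs data.frame with `id`, `sequence`.
#' @param references data.frame with `id`, `family`, and `sequence`
#'   (nucleotide level) or `protein` (protein level).
#' @param level `"nucleotide"` or `"protein"`.
#' @param min_identity Minimum identity over aligned columns for a
#'   reportable hit (default 60 nucleotide, 30 protein).
#' @param min_span Minimum aligned query span for a reportable hit, in
#'   query units (default 100 nt / 30 aa).
#' @param min_score Minimum alignment score at protein level (default 60),
#'   guarding against short spurious BLOSUM62 alignments.
#' @return List of hit records (`contig_id`, `reference_id`, `level`,
#'   `identity_pct`, `query_cov_pct`, `family`, `frame`, `score`); contigs
#'   without a passing hit are absent.
#' @export
best_hits <- function(contigs, references, level = c("nucleotide", "protein"),
                      min_identity = NULL, min_span = NULL, min_score = 60) {
  level <- match.arg(level)
  contigs <- as_contigs(contigs)
  if (is.null(references) || nrow(references) == 0L) stop("references must be non-empty")
  if (level == "protein" && is.null(references$protein)) {
    stop("protein-level search requires reference proteins")
  }
  min_identity <- min_identity %||% if (level == "nucleotide") 60 else 30
  min_span <- min_span %||% if (level == "nucleotide") 100L else 30L
  keep <- nzchar(contigs$sequence)
  for (id in contigs$id[!keep]) message("skipping empty contig ", id)
  contigs <- contigs[keep, , drop = FALSE]
  if (nrow(contigs) == 0L) return(list())

  if (level == "nucleotide") {
    queries <- contigs$sequence
    q_contig <- seq_len(nrow(contigs))
    frames <- rep(NA_integer_, nrow(contigs))
    q_set <- Biostrings::DNAStringSet(queries)
    scoring <- alignment_scoring("nucleotide")
    subjects <- lapply(references$sequence, Biostrings::DNAString)
  } else {
    peps <- lapply(contigs$sequence, six_frame_peptides)
    q_contig <- rep(seq_len(nrow(contigs)), lengths(peps))
    peps <- unlist(peps, recursive = FALSE)
    if (!length(peps)) return(list())
    queries <- vapply(peps, `[[`, "", "peptide")
    frames <- vapply(peps, `[[`, integer(1), "frame")
    q_set <- Biostrings::AAStringSet(queries)
    scoring <- alignment_scoring("protein")
    subjects <- lapply(references$protein, Biostrings::AAString)
  }

  ## one vectorized alignment call per reference: all queries at once
  best <- vector("list", nrow(contigs))
  for (r in seq_len(nrow(references))) {
    pa <- Biostrings::pairwiseAlignment(
      q_set, subjects[[r]], type = "overlap",
      substitutionMatrix = scoring$substitution,
      gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension)
    score <- Biostrings::score(pa)
    n_cols <- Biostrings::nchar(pa)
    ident <- ifelse(n_cols > 0, 100 * Biostrings::nmatch(pa) / n_cols, 0)
    span <- BiocGenerics::width(pa@pattern@range)
    ok <- ident >= min_identity & span >= pmin(min_span, nchar(queries))
    if (level == "protein") ok <- ok & score >= min_score
    for (q in which(ok)) {
      i <- q_contig[q]
      b <- best[[i]]
      if (is.null(b) || score[q] > b$score ||
          (score[q] == b$score && references$id[r] < b$ref_id)) {
        best[[i]] <- list(score = score[q], ref_id = references$id[r],
                          family = references$family[r], frame = frames[q],
                          identity = ident[q],
                          cov = 100 * span[q] / nchar(queries[q]))
      }
    }
  }
  hits <- list()
  for (i in seq_len(nrow(contigs))) {
    b <- best[[i]]
    if (is.null(b)) next
    hits[[length(hits) + 1L]] <- hit_record(
      contigs$id[i], b$ref_id, level, b$identity, b$cov, b$family,
      b$frame, b$score)
  }
  hits
}

#' Known/novel status from nucleotide- and protein-level best hits
#'
#' Encodes the two classification thresholds used for curated fermentation
#' viromes: a contig matching a reference at more than `known_id`% identity
#' with more than `known_cov`% coverage at the nucleotide level is a
#' *known* virus, provided its identity also clears the `novel_bound` so
#' the call is unambiguous; a contig with protein-level support whose
#' nucleotide identity or coverage falls below `novel_bound`% is a *novel*
#' species; the 85-90% identity band, which the known and novelty rules
#' claim simultaneously, is made explicit as `known_like` rather than
#' silently binned; contigs with no support at either level are
#' `unclassified`.
#'
#' @param nuc_hit,prot_hit Hit records from [best_hits()], or `NULL`.
#' @param known_id,known_cov Known-virus thresholds (strict `>`, defaults
#'   85 / 95).
#' @param novel_bound Novelty bound (strict `<`, default 90).
#' @param novel_rule `"or"` (default): novel when identity *or* coverage is
#'   below the bound; `"and"`: both must be below.
#' @return A `StatusCall` list: `contig_id`, `status` (`known`, `novel`,
#'   `known_like`, `unclassified`), `supporting_hit`.
#' @export
assign_status <- function(nuc_hit = NULL, prot_hit = NULL, known_id = 85,
                          known_cov = 95, novel_bound = 90,
                          novel_rule = c("or", "and")) {
  novel_rule <- match.arg(novel_rule)
  contig_id <- (nuc_hit %||% prot_hit)$contig_id %||% NA_character_
  out <- function(status, hit = NULL) {
    structure(list(contig_id = contig_id, status = status,
                   supporting_hit = hit), class = "StatusCall")
  }
  if (is.null(nuc_hit) && is.null(prot_hit)) return(out("unclassified"))
  if (!is.null(nuc_hit) &&
      nuc_hit$identity_pct > known_id && nuc_hit$query_cov_pct > known_cov) {
    ## identities between known_id and novel_bound satisfy the known rule
    ## and the novelty rule at once; that ambiguity is surfaced, not binned
    if (nuc_hit$identity_pct >= novel_bound) return(out("known", nuc_hit))
    return(out("known_like", nuc_hit))
  }
  if (!is.null(prot_hit)) {
    below <- if (is.null(nuc_hit)) TRUE else if (novel_rule == "or") {
      nuc_hit$identity_pct < novel_bound || nuc_hit$query_cov_pct < novel_bound
    } else {
      nuc_hit$identity_pct < novel_bound && nuc_hit$query_cov_pct < novel_bound
    }
    if (below) return(out("novel", prot_hit))
  }
  out("known_like", nuc_hit %||% prot_hit)
}

#' Classify a contig set against a reference virome
#'
#' Convenience wrapper: computes nucleotide- and protein-level best hits
#' and assigns one status per contig.
#'
#' @inheritParams best_hits
#' @param ... Passed to [assign_status()].
#' @return data.frame with `contig_id`, `status`, `family` (from the
#'   supporting hit, `NA` for unclassified), `nuc_identity`, `nuc_cov`,
#'   `prot_identity`.
#' @export
classify_contigs <- function(contigs, references, ...) {
  contigs <- as_contigs(contigs)
  nuc <- best_hits(contigs, references, "nucleotide")
  prot <- best_hits(contigs, references, "protein")
  nuc_by <- stats::setNames(nuc, vapply(nuc, `[[`, "", "contig_id"))
  prot_by <- stats::setNames(prot, vapply(prot, `[[`, "", "contig_id"))
  rows <- lapply(contigs$id, function(id) {
    nh <- nuc_by[[id]]; ph <- prot_by[[id]]
    sc <- assign_status(nh, ph, ...)
    data.frame(contig_id = id, status = sc$status,
               family = sc$supporting_hit$family %||% NA_character_,
               nuc_identity = nh$identity_pct %||% NA_real_,
               nuc_cov = nh$query_cov_pct %||% NA_real_,
               prot_identity = ph$identity_pct %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-library co-occurrence
#'
#' Counts, per contig, the libraries (time points) in which it is detected
#' and flags contigs present in at least two distinct libraries — the
#' support level required to trust a sequence as genuinely part of the
#' community rather than a single-library artifact.
#'
#' @param presence Logical or 0/1 matrix, contigs x libraries (columns
#'   conventionally `TIMEPOINTS`).
#' @param min_libraries Flag threshold (default 2).
#' @return data.frame with `contig_id`, `n_libraries`,
#'   `cooccurring` (`n_libraries >= min_libraries`).
#' @export
cooccurrence <- function(presence, min_libraries = 2L) {
  m <- as.matrix(presence)
  storage.mode(m) <- "logical"
  n <- rowSums(m)
  data.frame(contig_id = rownames(m) %||% as.character(seq_len(nrow(m))),
             n_libraries = as.integer(n),
             cooccurring = n >= min_libraries,
             stringsAsFactors = FALSE, row.names = NULL)
}
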
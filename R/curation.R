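## Post-assembly manual-curation pipeline: length filter, redundancy
## clustering, terminal-overlap merge/extension, chimera removal, with a
## complete audit trail so every input contig is accounted for exactly once.

as_contigs <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    df <- x[, c("id", "sequence")]
  } else if (is.character(x)) {
    df <- data.frame(id = names(x) %||% sprintf("contig_%d", seq_along(x)),
                     sequence = unname(x), stringsAsFactors = FALSE)
  } else {
    stop("contigs must be a data.frame with id/sequence or a named character vector")
  }
  if (anyDuplicated(df$id)) stop("contig ids must be unique")
  rownames(df) <- NULL
  df
}

#' Minimum-length filter
#'
#' Partitions contigs by a length threshold; curated viromes conventionally
#' drop everything below 500 nt, where similarity search and ORF evidence
#' become unreliable.
#'
#' @param contigs data.frame with `id`, `sequence` (or named character
#'   vector).
#' @param min_len Length threshold in nt (default 500).
#' @param strict_gt Require length strictly greater than `min_len` instead
#'   of the default `>=`.
#' @return List with `kept` and `dropped` contig data.frames, input order
#'   preserved.
#' @export
length_filter <- function(contigs, min_len = 500L, strict_gt = FALSE) {
  contigs <- as_contigs(contigs)
  len <- nchar(contigs$sequence)
  keep <- if (strict_gt) len > min_len else len >= min_len
  list(kept = contigs[keep, , drop = FALSE],
       dropped = contigs[!keep, , drop = FALSE])
}

#' Greedy longest-first redundancy clustering
#'
#' CD-HIT-style clustering with documented, deterministic semantics:
#' contigs are visited longest first (ties by id) and each joins the first
#' existing cluster whose representative it matches at
#' `>= identity_thr`% identity with `>= coverage_thr`% coverage of the
#' shorter sequence (semiglobal alignment), otherwise founds a new cluster.
#' Representatives are therefore always the longest member.
#'
#' @param contigs data.frame with `id`, `sequence`; must be non-empty.
#' @param identity_thr,coverage_thr Percent thresholds (default 95 / 95).
#' @return List of clusters, each a list with `representative_id`,
#'   `member_ids` (representative first) and `stats` (per-member identity
#'   and shorter-sequence coverage vs the representative).
#' @export
cluster_redundant <- function(contigs, identity_thr = 95, coverage_thr = 95) {
  contigs <- as_contigs(contigs)
  if (nrow(contigs) == 0L) stop("contigs must be non-empty")
  ord <- order(-nchar(contigs$sequence), contigs$id)
  contigs <- contigs[ord, , drop = FALSE]
  clusters <- list()
  for (i in seq_len(nrow(contigs))) {
    id <- contigs$id[i]; seqn <- contigs$sequence[i]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_seq <- clusters[[ci]]$rep_seq
      if (!shares_kmer(seqn, rep_seq)) next
      al <- semiglobal_align(seqn, rep_seq, query_id = id,
                             target_id = clusters[[ci]]$representative_id)
      if (al$identity_pct >= identity_thr && al$shorter_cov_pct >= coverage_thr) {
        clusters[[ci]]$member_ids <- c(clusters[[ci]]$member_ids, id)
        clusters[[ci]]$stats <- rbind(
          clusters[[ci]]$stats,
          data.frame(member_id = id, identity_pct = al$identity_pct,
                     shorter_cov_pct = al$shorter_cov_pct,
                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        representative_id = id, rep_seq = seqn, member_ids = id,
        stats = data.frame(member_id = id, identity_pct = 100,
                           shorter_cov_pct = 100, stringsAsFactors = FALSE))
    }
  }
  lapply(clusters, function(cl) cl[c("representative_id", "member_ids", "stats")])
}

#' Iterative terminal-overlap merging
#'
#' Repeatedly scans all ordered contig pairs with [terminal_overlap()] and
#' merges the pair with the longest accepted overlap (ties by left then
#' right id) until no accepted overlap remains. The merged sequence takes
#' the left (5'-side) contig's bases at mismatch positions; when the
#' accepted orientation is reverse-complement, the right contig is
#' complemented before joining. Mutual containments are flagged, never
#' merged.
#'
#' @param contigs data.frame with `id`, `sequence`.
#' @param min_len,max_mismatches,allow_adjacent,check_rc Overlap rule
#'   parameters, see [terminal_overlap()].
#' @return List with `contigs` (post-merge set), `merge_records` (one per
#'   merge: `input_ids`, `merged_id`, `overlap`, `merged_length`,
#'   `extension_nt` = merged length minus longest input) and
#'   `containments` (flagged pairs).
#' @export
merge_by_overlap <- function(contigs, min_len = 20L, max_mismatches = 2L,
                             allow_adjacent = FALSE, check_rc = TRUE) {
  contigs <- as_contigs(contigs)
  merge_records <- list()
  containments <- list()
  n_merge <- 0L
  evaluated <- new.env(parent = emptyenv())  # pair results survive rounds
  accepted <- list()
  repeat {
    n <- nrow(contigs)
    if (n < 2L) break
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        key <- paste0(contigs$id[i], "\r", contigs$id[j])
        if (!is.null(evaluated[[key]])) next
        evaluated[[key]] <- TRUE
        a <- contigs$sequence[i]; b <- contigs$sequence[j]
        if (min(nchar(a), nchar(b)) < min_len) next
        ov <- terminal_overlap(a, b, min_len = min_len,
                               max_mismatches = max_mismatches,
                               allow_adjacent = allow_adjacent,
                               check_rc = check_rc,
                               left_id = contigs$id[i], right_id = contigs$id[j])
        if (!ov$accepted) next
        if (ov$containment) {
          containments[[length(containments) + 1L]] <- ov
          next
        }
        accepted[[key]] <- ov
      }
    }
    ## best live accepted overlap (longest, ties by left then right id)
    best <- NULL
    for (ov in accepted) {
      i <- match(ov$left_id, contigs$id)
      j <- match(ov$right_id, contigs$id)
      if (is.na(i) || is.na(j)) next
      if (is.null(best) || ov$overlap_len > best$ov$overlap_len ||
          (ov$overlap_len == best$ov$overlap_len &&
           paste(ov$left_id, ov$right_id) <
           paste(best$ov$left_id, best$ov$right_id))) {
        best <- list(ov = ov, i = i, j = j)
      }
    }
    if (is.null(best)) break
    n_merge <- n_merge + 1L
    left <- contigs$sequence[best$i]
    right <- contigs$sequence[best$j]
    if (best$ov$orientation == "rc") right <- revcomp(right)
    merged_seq <- paste0(left, substr(right, best$ov$overlap_len + 1L,
                                      nchar(right)))
    merged_id <- sprintf("merged_%d", n_merge)
    inputs <- c(contigs$id[best$i], contigs$id[best$j])
    merge_records[[n_merge]] <- list(
      input_ids = inputs, merged_id = merged_id, overlap = best$ov,
      merged_length = nchar(merged_seq),
      extension_nt = nchar(merged_seq) -
        max(nchar(left), nchar(contigs$sequence[best$j])))
    contigs <- rbind(contigs[-c(best$i, best$j), , drop = FALSE],
                     data.frame(id = merged_id, sequence = merged_seq,
                                stringsAsFactors = FALSE))
    rownames(contigs) <- NULL
  }
  list(contigs = contigs, merge_records = merge_records,
       containments = containments)
}

#' Chimera detection from split reference hits and ORF structure
#'
#' A contig is called chimeric when two reference hits from *different*
#' source families cover disjoint regions of it — each at least
#' `min_span_frac` of the contig, separated by a gap (or overlapping) of at
#' most `max_gap` nt — and no single ORF of at least `orf_rescue_len` nt
#' spans the inferred junction. An ORF reading through the junction is
#' evidence for one continuous molecule and rescues the contig.
#'
#' @param contig List or one-row data.frame with `id`, `sequence`.
#' @param hits data.frame of reference hits with columns `reference_id`,
#'   `family`, `q_start`, `q_end` (0-based half-open span on the contig)
#'   and `identity_pct`.
#' @param orfs List of ORF records for the contig (see [find_orfs()]); when
#'   `NULL` they are computed under the standard code at
#'   `min_len_nt = orf_rescue_len`.
#' @param min_span_frac,max_gap,orf_rescue_len Rule parameters (defaults
#'   0.2, 50 nt, 300 nt).
#' @return A `ChimeraCall` list: `contig_id`, `is_chimera`,
#'   `breakpoint_estimate` (0-based, or `NA`), `evidence`.
#' @export
detect_chimera <- function(contig, hits, orfs = NULL, min_span_frac = 0.2,
                           max_gap = 50L, orf_rescue_len = 300L) {
  if (is.data.frame(contig)) contig <- as.list(contig[1L, ])
  len <- nchar(contig$sequence)
  call_out <- function(is_chimera, bp = NA_integer_, evidence = NULL) {
    structure(list(contig_id = contig$id, is_chimera = is_chimera,
                   breakpoint_estimate = bp, evidence = evidence),
              class = "ChimeraCall")
  }
  if (is.null(hits) || nrow(hits) < 2L) return(call_out(FALSE))
  best <- NULL
  for (i in seq_len(nrow(hits) - 1L)) {
    for (j in (i + 1L):nrow(hits)) {
      if (identical(hits$family[i], hits$family[j])) next
      h1 <- hits[i, ]; h2 <- hits[j, ]
      if (h1$q_start > h2$q_start) { tmp <- h1; h1 <- h2; h2 <- tmp }
      span1 <- h1$q_end - h1$q_start
      span2 <- h2$q_end - h2$q_start
      if (span1 < min_span_frac * len || span2 < min_span_frac * len) next
      gap <- h2$q_start - h1$q_end
      if (abs(gap) > max_gap) next
      if (h2$q_end <= h1$q_end) next  # nested, not side-by-side
      total <- span1 + span2
      if (is.null(best) || total > best$total) {
        best <- list(h1 = h1, h2 = h2, total = total,
                     bp = as.integer(round((h1$q_end + h2$q_start) / 2)))
      }
    }
  }
  if (is.null(best)) return(call_out(FALSE))
  if (is.null(orfs)) {
    orfs <- find_orfs(contig$sequence, genetic_code = 1L,
                      min_len_nt = orf_rescue_len, contig_id = contig$id)
  }
  ## an ORF only rescues when it reads well through the junction on both
  ## sides; short read-through past a junction arises by chance (a stop
  ## every ~21 codons), so a margin of half the rescue length is required
  spanning <- any(vapply(orfs, function(o) {
    orf_spans_junction(o, best$bp, orf_rescue_len)
  }, logical(1)))
  evidence <- list(hit_spans = rbind(best$h1, best$h2),
                   orf_rescue = spanning)
  if (spanning) return(call_out(FALSE, evidence = evidence))
  call_out(TRUE, bp = best$bp, evidence = evidence)
}

orf_spans_junction <- function(orf, bp, orf_rescue_len) {
  margin <- orf_rescue_len / 2
  orf$length_nt >= orf_rescue_len &&
    orf$start <= bp - margin && orf$end >= bp + margin
}

default_curation_config <- function(config = list()) {
  defaults <- list(
    min_len = 500L, strict_gt = FALSE, id_thr = 95, cov_thr = 95,
    overlap = list(min_len = 20L, max_mismatches = 2L,
                   allow_adjacent = FALSE, check_rc = TRUE),
    chimera = list(min_span_frac = 0.2, max_gap = 50L, orf_rescue_len = 300L,
                   min_hit_identity = 75, min_hit_span_frac = 0.1))
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      defaults[[nm]][names(config[[nm]])] <- config[[nm]]
    } else defaults[[nm]] <- config[[nm]]
  }
  defaults
}

reference_hits_for <- function(contig, references, min_identity, min_span_frac) {
  rows <- list()
  for (r in seq_len(nrow(references))) {
    if (!shares_kmer(contig$sequence, references$sequence[r])) next
    ## local mode: a chimera matches each parent over part of its length
    al <- local_align(contig$sequence, references$sequence[r],
                      query_id = contig$id,
                      target_id = references$id[r])
    span <- al$query_span[2] - al$query_span[1]
    if (al$identity_pct < min_identity ||
        span < min_span_frac * nchar(contig$sequence)) next
    rows[[length(rows) + 1L]] <- data.frame(
      reference_id = references$id[r], family = references$family[r],
      q_start = al$query_span[1], q_end = al$query_span[2],
      identity_pct = al$identity_pct, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Full curation pipeline with audit trail
#'
#' Applies, in order: length filter, redundancy clustering (keeping
#' representatives), terminal-overlap merging, re-clustering of the merged
#' set, and chimera removal against the supplied references. Every input
#' contig receives exactly one terminal action in the audit trail
#' (`length_dropped`, `clustered_away`, `merged_into`, `chimera_dropped`,
#' or `kept`); contigs created by merging are audited under their new ids.
#'
#' @param contigs data.frame with `id`, `sequence`.
#' @param references Optional reference data.frame (`id`, `family`,
#'   `sequence`); when `NULL` the chimera stage is skipped with a notice.
#' @param config Named list overriding [default_curation_config()] entries
#'   (`min_len`, `strict_gt`, `id_thr`, `cov_thr`, `overlap$...`,
#'   `chimera$...`).
#' @return List with `contigs` (curated set), `audit` (data.frame `stage`,
#'   `contig_id`, `action`, `detail`), `counts` (contigs surviving each
#'   stage), `clusters`, `merge_records`, `chimera_calls`.
#' @export
curate <- function(contigs, references = NULL, config = list()) {
  cfg <- default_curation_config(config)
  contigs <- as_contigs(contigs)
  audit <- list()
  note <- function(stage, id, action, detail = "") {
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = stage, contig_id = id, action = action, detail = detail,
      stringsAsFactors = FALSE)
  }
  counts <- list(input = nrow(contigs))

  lf <- length_filter(contigs, cfg$min_len, cfg$strict_gt)
  for (id in lf$dropped$id) note("length_filter", id, "length_dropped",
                                 sprintf("min_len=%d", cfg$min_len))
  current <- lf$kept
  counts$length_filter <- nrow(current)

  clusters <- list()
  if (nrow(current) > 0L) {
    clusters <- cluster_redundant(current, cfg$id_thr, cfg$cov_thr)
    for (cl in clusters) {
      for (m in setdiff(cl$member_ids, cl$representative_id)) {
        note("cluster", m, "clustered_away", cl$representative_id)
      }
    }
    reps <- vapply(clusters, `[[`, "", "representative_id")
    current <- current[current$id %in% reps, , drop = FALSE]
  }
  counts$cluster <- nrow(current)

  merge_records <- list()
  if (nrow(current) > 1L) {
    mg <- merge_by_overlap(current, min_len = cfg$overlap$min_len,
                           max_mismatches = cfg$overlap$max_mismatches,
                           allow_adjacent = cfg$overlap$allow_adjacent,
                           check_rc = cfg$overlap$check_rc)
    merge_records <- mg$merge_records
    for (mr in merge_records) {
      for (id in mr$input_ids) note("merge", id, "merged_into", mr$merged_id)
    }
    for (cv in mg$containments) {
      note("merge", cv$left_id, "containment_flagged", cv$right_id)
    }
    current <- mg$contigs
  }
  counts$merge <- nrow(current)

  if (nrow(current) > 1L) {
    reclusters <- cluster_redundant(current, cfg$id_thr, cfg$cov_thr)
    for (cl in reclusters) {
      for (m in setdiff(cl$member_ids, cl$representative_id)) {
        note("recluster", m, "clustered_away", cl$representative_id)
      }
    }
    reps <- vapply(reclusters, `[[`, "", "representative_id")
    current <- current[current$id %in% reps, , drop = FALSE]
  }
  counts$recluster <- nrow(current)

  chimera_calls <- list()
  if (is.null(references)) {
    message("no references supplied; chimera stage skipped")
    note("chimera", "*", "skipped", "no references supplied")
  } else if (nrow(current) > 0L) {
    references <- references[, c("id", "family", "sequence")]
    keep <- logical(nrow(current))
    for (i in seq_len(nrow(current))) {
      contig <- as.list(current[i, ])
      hits <- reference_hits_for(contig, references,
                                 cfg$chimera$min_hit_identity,
                                 cfg$chimera$min_hit_span_frac)
      cc <- detect_chimera(contig, hits,
                           min_span_frac = cfg$chimera$min_span_frac,
                           max_gap = cfg$chimera$max_gap,
                           orf_rescue_len = cfg$chimera$orf_rescue_len)
      chimera_calls[[length(chimera_calls) + 1L]] <- cc
      keep[i] <- !cc$is_chimera
      if (cc$is_chimera) {
        note("chimera", contig$id, "chimera_dropped",
             sprintf("breakpoint~%d", cc$breakpoint_estimate))
      }
    }
    current <- current[keep, , drop = FALSE]
  }
  counts$chimera <- nrow(current)

  if (nrow(current) == 0L) warning("curation left no surviving contigs")
  for (id in current$id) note("final", id, "kept")
  rownames(current) <- NULL
  list(contigs = current,
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(stage = character(0), contig_id = character(0),
                    action = character(0), detail = character(0)),
       counts = counts, clusters = clusters,
       merge_records = merge_records, chimera_calls = chimera_calls)
}
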
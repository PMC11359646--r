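## Multi-segmented narnavirus characterization: per-segment profile HMMs
## (RNA1 = RdRp, RNA2/RNA3 = hypothetical proteins), Viterbi log-odds
## scoring, split-segment merging by exact terminal pairing, 3' stem-loop
## detection and terminal conservation.

#' Build a profile HMM from an aligned amino-acid training set
#'
#' Columns with fewer than `match_gap_fraction` gaps become match states;
#' emission probabilities are pseudocount-smoothed column counts, and
#' match/insert/delete transition probabilities are estimated from each
#' row's path through the model (Durbin-style profile construction). The
#' background distribution is the pseudocount-smoothed residue composition
#' of the whole alignment; insert states emit the background, so inserts
#' are neutral in log-odds.
#'
#' @param msa Character vector of equal-length aligned rows (gap `-`).
#' @param name Model name (conventionally the segment class).
#' @param pseudocount Added to every emission and transition count
#'   (default 1).
#' @param match_gap_fraction Gap-fraction threshold below which a column is
#'   a match state (default 0.5).
#' @return A `ProfileHMM` list: `name`, `n_match_states`,
#'   `match_emissions` (states x 20), `insert_emissions`, `background`,
#'   `transitions` ((n+1) x 7 matrix over `MM, MI, MD, IM, II, DM, DD`;
#'   row k holds transitions out of node k-1, node 0 being begin), and
#'   `match_columns`.
#' @export
build_profile_hmm <- function(msa, name = "model", pseudocount = 1,
                              match_gap_fraction = 0.5) {
  if (length(msa) < 2L) stop("MSA needs at least 2 rows")
  if (length(unique(nchar(msa))) != 1L) stop("MSA rows must have equal length")
  rows <- do.call(rbind, strsplit(toupper(msa), ""))
  is_gap <- rows == "-" | rows == "."
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac < match_gap_fraction)
  M <- length(match_cols)
  if (M < 1L) stop("no match columns at this gap threshold")
  aa <- AA_ALPHABET20

  bg_counts <- table(factor(rows[!is_gap], levels = aa))
  background <- (as.numeric(bg_counts) + pseudocount) /
    (sum(bg_counts) + 20 * pseudocount)
  names(background) <- aa

  match_emissions <- t(vapply(match_cols, function(cc) {
    cnt <- table(factor(rows[!is_gap[, cc], cc], levels = aa))
    (as.numeric(cnt) + pseudocount) / (sum(cnt) + 20 * pseudocount)
  }, numeric(20)))
  colnames(match_emissions) <- aa

  ## per-row state paths over nodes 0..M (0 = begin), counting transitions
  trans_names <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  counts <- matrix(0, M + 1L, 7L, dimnames = list(NULL, trans_names))
  col_node <- integer(ncol(rows))  # node whose insert track owns the column
  node_of_match_col <- stats::setNames(seq_len(M), match_cols)
  for (r in seq_len(nrow(rows))) {
    state <- "M"; node <- 0L
    for (cc in seq_len(ncol(rows))) {
      if (cc %in% match_cols) {
        new_state <- if (is_gap[r, cc]) "D" else "M"
        counts[node + 1L, paste0(state, new_state)] <-
          counts[node + 1L, paste0(state, new_state)] + 1
        state <- new_state
        node <- node_of_match_col[[as.character(cc)]]
      } else if (!is_gap[r, cc]) {
        ## insert column residue: I state at current node
        if (state != "I") {
          counts[node + 1L, paste0(state, "I")] <-
            counts[node + 1L, paste0(state, "I")] + 1
        } else {
          counts[node + 1L, "II"] <- counts[node + 1L, "II"] + 1
        }
        state <- "I"
      }
    }
    ## exit to END counts as a *M transition out of node M
    counts[node + 1L, paste0(state, "M")] <-
      counts[node + 1L, paste0(state, "M")] + 1
  }

  transitions <- counts + pseudocount
  ## no delete beyond the last node
  transitions[M + 1L, c("MD", "DD")] <- 0
  for (grp in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
    s <- rowSums(transitions[, grp, drop = FALSE])
    transitions[, grp] <- transitions[, grp] / s
  }

  structure(list(name = name, n_match_states = M,
                 match_emissions = match_emissions,
                 insert_emissions = background, background = background,
                 transitions = transitions,
                 match_columns = match_cols),
            class = "ProfileHMM")
}

#' @export
print.ProfileHMM <- function(x, ...) {
  cat(sprintf("ProfileHMM '%s': %d match states\n", x$name, x$n_match_states))
  invisible(x)
}

#' Viterbi log-odds score of a protein against a profile HMM
#'
#' Global alignment of the full sequence to the full model by dynamic
#' programming, scored in bits against the background null model (which
#' emits every residue from the background with no transition cost).
#' Insert states emit the background, so their emission log-odds is zero;
#' residues outside the 20-letter alphabet (e.g. `X`) are emitted as
#' background in both models and contribute zero bits.
#'
#' @param model A `ProfileHMM` from [build_profile_hmm()].
#' @param protein Non-empty amino-acid string.
#' @param return_path Also compute the Viterbi state path (default FALSE).
#' @return List with `score_bits` and, when requested, `path` (character
#'   vector like `"M1"`, `"I3"`, `"D4"`). `score_bits` is `-Inf` when no
#'   path exists.
#' @export
hmm_score <- function(model, protein, return_path = FALSE) {
  stopifnot(inherits(model, "ProfileHMM"))
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein)) {
    stop("protein must be a non-empty string")
  }
  aa <- AA_ALPHABET20
  M <- model$n_match_states
  x <- seq_chars(toupper(protein))
  n <- length(x)
  idx <- match(x, aa)  # NA -> background emission, 0 bits

  logE <- log2(sweep(model$match_emissions, 2, model$background, "/"))
  lt <- log2(model$transitions)  # (M+1) x 7; log2(0) = -Inf for last-node D
  tMM <- lt[, "MM"]; tMI <- lt[, "MI"]; tMD <- lt[, "MD"]
  tIM <- lt[, "IM"]; tII <- lt[, "II"]
  tDM <- lt[, "DM"]; tDD <- lt[, "DD"]

  neg <- -Inf
  ## rows: sequence positions 0..n; cols: nodes 0..M
  Vm <- matrix(neg, n + 1L, M + 1L)
  Vi <- matrix(neg, n + 1L, M + 1L)
  Vd <- matrix(neg, n + 1L, M + 1L)
  Vm[1L, 1L] <- 0  # begin

  ## delete-chain helper: D[k] = max(M[k-1]+tMD[k-1], D[k-1]+tDD[k-1]),
  ## solved for all k via prefix sums of tDD and a cummax
  ## S[k] = sum of tDD out of nodes 1..k-1; D[k] = S[k] + cummax over
  ## j = 0..k-1 of (M[j] + tMD[j] - S[j+1])
  dS <- cumsum(c(0, if (M >= 2L) tDD[2:M] else numeric(0)))
  d_chain <- function(m_row) {
    cand <- m_row[1:M] + tMD[1:M] - dS
    dS + cummax(cand)
  }
  Vd[1L, 2:(M + 1L)] <- d_chain(Vm[1L, ])

  for (i in seq_len(n)) {
    e <- if (is.na(idx[i])) numeric(M) else logE[, idx[i]]
    prevM <- Vm[i, ]; prevI <- Vi[i, ]; prevD <- Vd[i, ]
    ## M_k (k = 1..M) from node k-1 at previous position
    k <- 1:M
    Vm[i + 1L, k + 1L] <- e +
      pmax(prevM[k] + tMM[k], prevI[k] + tIM[k], prevD[k] + tDM[k])
    ## I_k (k = 0..M) at current node
    Vi[i + 1L, ] <- pmax(prevM + tMI, prevI + tII)
    ## D chain within current position
    Vd[i + 1L, 2:(M + 1L)] <- d_chain(Vm[i + 1L, ])
  }
  last <- M + 1L
  ends <- c(M = Vm[n + 1L, last] + tMM[last],
            I = Vi[n + 1L, last] + tIM[last],
            D = Vd[n + 1L, last] + tDM[last])
  score <- max(ends)
  out <- list(score_bits = score)
  if (return_path && is.finite(score)) {
    out$path <- viterbi_traceback(Vm, Vi, Vd, ends, n, M, idx, logE,
                                  list(tMM = tMM, tMI = tMI, tMD = tMD,
                                       tIM = tIM, tII = tII,
                                       tDM = tDM, tDD = tDD))
  }
  out
}

viterbi_traceback <- function(Vm, Vi, Vd, ends, n, M, idx, logE, tr) {
  eps <- 1e-9
  state <- c("M", "I", "D")[which.max(ends)]  # ties prefer M > I > D
  i <- n; k <- M
  path <- character(0)
  while (!(i == 0L && k == 0L)) {
    path <- c(paste0(state, k), path)
    if (state == "M") {
      e <- if (is.na(idx[i + 0L])) 0 else logE[k, idx[i]]
      target <- Vm[i + 1L, k + 1L] - e
      cand <- c(M = Vm[i, k] + tr$tMM[k], I = Vi[i, k] + tr$tIM[k],
                D = Vd[i, k] + tr$tDM[k])
      i <- i - 1L; k <- k - 1L
    } else if (state == "I") {
      target <- Vi[i + 1L, k + 1L]
      cand <- c(M = Vm[i, k + 1L] + tr$tMI[k + 1L],
                I = Vi[i, k + 1L] + tr$tII[k + 1L])
      i <- i - 1L
    } else {
      target <- Vd[i + 1L, k + 1L]
      cand <- c(M = Vm[i + 1L, k] + tr$tMD[k],
                D = Vd[i + 1L, k] + tr$tDD[k])
      k <- k - 1L
    }
    state <- names(cand)[which(abs(cand - target) < eps)][1L]
    if (state == "M" && k == 0L && i == 0L) break
  }
  path
}

#' Assign ORFs to segment classes by competing profile HMMs
#'
#' Scores every ORF protein against every model and assigns the
#' best-scoring class when the best score reaches `threshold_bits`,
#' otherwise `none`.
#'
#' @param proteins Named character vector of ORF proteins.
#' @param models Named list of `ProfileHMM` objects (conventionally
#'   `RNA1`, `RNA2`, `RNA3`).
#' @param threshold_bits Minimum winning score (default 10).
#' @return data.frame with `orf_id`, `best_class`, `score_bits`, one
#'   `score_<class>` column per model, and `threshold_used`.
#' @export
assign_segment <- function(proteins, models, threshold_bits = 10) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  ids <- names(proteins) %||% sprintf("orf_%d", seq_along(proteins))
  scores <- vapply(models, function(m) {
    vapply(proteins, function(p) hmm_score(m, p)$score_bits, numeric(1))
  }, numeric(length(proteins)))
  scores <- matrix(scores, nrow = length(proteins),
                   dimnames = list(ids, names(models)))
  best_i <- apply(scores, 1L, which.max)
  best_s <- scores[cbind(seq_along(ids), best_i)]
  out <- data.frame(
    orf_id = ids,
    best_class = ifelse(best_s >= threshold_bits,
                        colnames(scores)[best_i], "none"),
    score_bits = best_s, stringsAsFactors = FALSE, row.names = NULL)
  for (cl in colnames(scores)) out[[paste0("score_", cl)]] <- scores[, cl]
  out$threshold_used <- threshold_bits
  out
}

#' Merge split segment candidates by exact terminal pairing
#'
#' Applies [exact_terminal_overlap()] across all ordered pairs of
#' candidates assigned to the same segment class, merges the pair with the
#' longest accepted perfect pairing (ties by left then right id), and
#' re-runs [longest_orf()] on the merged sequence — fragments of one
#' molecule yield a merged ORF longer than either input's.
#'
#' @param candidates data.frame with `id`, `sequence` (>= 2 rows).
#' @param min_overlap Minimum exact pairing length (default 18).
#' @return `NULL` when no pair shares a terminus; otherwise a list with
#'   `input_ids` (left, right), `merged_id`, `sequence`, `overlap`
#'   (the `OverlapResult`), `merged_length`, `extension_nt` and `orf` (the
#'   merged sequence's longest ORF record).
#' @export
merge_split_segments <- function(candidates, min_overlap = 18L) {
  candidates <- as_contigs(candidates)
  if (nrow(candidates) < 2L) stop("need at least 2 candidates")
  best <- NULL
  n <- nrow(candidates)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ov <- exact_terminal_overlap(candidates$sequence[i],
                                   candidates$sequence[j],
                                   min_len = min_overlap,
                                   left_id = candidates$id[i],
                                   right_id = candidates$id[j])
      if (!ov$accepted) next
      if (is.null(best) || ov$overlap_len > best$ov$overlap_len ||
          (ov$overlap_len == best$ov$overlap_len &&
           paste(ov$left_id, ov$right_id) <
           paste(best$ov$left_id, best$ov$right_id))) {
        best <- list(ov = ov, i = i, j = j)
      }
    }
  }
  if (is.null(best)) return(NULL)
  left <- candidates$sequence[best$i]
  right <- candidates$sequence[best$j]
  merged_seq <- paste0(left, substr(right, best$ov$overlap_len + 1L,
                                    nchar(right)))
  merged_id <- paste0(candidates$id[best$i], "+", candidates$id[best$j])
  list(input_ids = c(candidates$id[best$i], candidates$id[best$j]),
       merged_id = merged_id, sequence = merged_seq, overlap = best$ov,
       merged_length = nchar(merged_seq),
       extension_nt = nchar(merged_seq) - max(nchar(left), nchar(right)),
       orf = longest_orf(merged_seq, contig_id = merged_id))
}

#' Minimum read depth around a merge junction
#'
#' Places each read on the merged contig by exact substring matching (both
#' strands, every occurrence) and returns the minimum per-base depth within
#' `junction` plus/minus `window`. A strictly positive minimum certifies
#' continuous read support across the junction.
#'
#' @param merged List or one-row data.frame with `id`, `sequence`, or a
#'   plain nucleotide string.
#' @param reads Character vector of read sequences.
#' @param junction 0-based junction position on the merged sequence.
#' @param window Half-width of the inspected window in nt (default 25).
#' @return The minimum depth (integer >= 0) within the window.
#' @export
junction_coverage <- function(merged, reads, junction, window = 25L) {
  if (is.list(merged) || is.data.frame(merged)) merged <- merged$sequence[[1]]
  n <- nchar(merged)
  if (junction < 1L || junction >= n) stop("junction outside contig")
  depth <- integer(n)
  for (rd in reads) {
    rl <- nchar(rd)
    for (pat in unique(c(rd, revcomp(rd)))) {
      hits <- gregexpr(pat, merged, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (h in hits) depth[h:(h + rl - 1L)] <- depth[h:(h + rl - 1L)] + 1L
    }
  }
  lo <- max(1L, junction + 1L - window)
  hi <- min(n, junction + 1L + window)
  min(depth[lo:hi])
}

hairpin_pair_score <- function(b1, b2, allow_gu) {
  wc <- (b1 == "A" & b2 == "T") | (b1 == "T" & b2 == "A") |
        (b1 == "G" & b2 == "C") | (b1 == "C" & b2 == "G")
  gu <- allow_gu & ((b1 == "G" & b2 == "T") | (b1 == "T" & b2 == "G"))
  ifelse(wc, 1, ifelse(gu, 0.5, NA_real_))
}

#' Exhaustive stem-loop search in the 3'-terminal window
#'
#' Scans every (start, stem, loop) geometry within the terminal
#' `window_3prime` nucleotides, requiring all stem positions to pair
#' (Watson-Crick, or GU wobble at half weight when `allow_gu`). Returns
#' the maximum-score hairpin; ties prefer the longer stem, then the
#' 3'-most placement.
#'
#' @param seq Nucleotide string of length >= `window_3prime`.
#' @param seq_id Identifier carried into the call.
#' @param window_3prime Terminal window examined (default 50 nt).
#' @param min_stem Minimum stem length in bp (default 3).
#' @param loop_range Inclusive loop length range in nt (default 3 to 8).
#' @param allow_gu Count GU wobble pairs at weight 0.5 (default TRUE).
#' @return `NULL` when no hairpin satisfies the geometry, else a
#'   `HairpinCall` list: `seq_id`, `window` (0-based half-open interval on
#'   the full sequence), `stem_len`, `loop_len`, `pairs` (list of 0-based
#'   paired positions), `score`, `start` (0-based hairpin start).
#' @export
find_terminal_hairpin <- function(seq, seq_id = "seq", window_3prime = 50L,
                                  min_stem = 3L, loop_range = c(3L, 8L),
                                  allow_gu = TRUE) {
  n <- nchar(seq)
  stopifnot(n >= window_3prime)
  w0 <- n - window_3prime  # 0-based window start
  win <- seq_chars(substr(seq, w0 + 1L, n))
  W <- length(win)
  best <- NULL
  for (p in seq_len(W)) {
    for (l in loop_range[1]:loop_range[2]) {
      s_max <- (W - p + 1L - l) %/% 2L
      if (s_max < min_stem) next
      for (s in min_stem:s_max) {
        left <- win[p:(p + s - 1L)]
        right <- win[(p + 2L * s + l - 1L):(p + s + l)]  # reversed
        sc <- hairpin_pair_score(left, right, allow_gu)
        if (anyNA(sc)) next
        total <- sum(sc)
        better <- is.null(best) || total > best$score ||
          (total == best$score && (s > best$stem_len ||
            (s == best$stem_len && p > best$p)))
        if (better) {
          pairs <- lapply(seq_len(s) - 1L, function(k) {
            c(w0 + p - 1L + k, w0 + p - 1L + 2L * s + l - 1L - k)
          })
          best <- list(seq_id = seq_id, window = c(w0, n),
                       stem_len = s, loop_len = l, pairs = pairs,
                       score = total, p = p, start = w0 + p - 1L)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(best[c("seq_id", "window", "stem_len", "loop_len", "pairs",
                   "score", "start")], class = "HairpinCall")
}

#' 3'-anchored terminal conservation profile
#'
#' Gapless alignment of the terminal `end_len` nucleotides of each segment,
#' anchored at the 3' ends; column identity is the frequency of the modal
#' base. Segments of one multi-segment virus share conserved termini, so a
#' high mean over the terminal columns against a ~25% upstream baseline is
#' the expected signature.
#'
#' @param segments Character vector (>= 2) of sequences, each at least
#'   `end_len` nt.
#' @param end_len Terminal window length (default 30).
#' @return List with `profile` (per-column modal-base fraction, 5' to 3'
#'   over the window), `mean_pct`, and `columns` (the stacked terminal
#'   characters).
#' @export
terminal_conservation <- function(segments, end_len = 30L) {
  stopifnot(length(segments) >= 2, all(nchar(segments) >= end_len))
  mat <- do.call(rbind, lapply(segments, function(s) {
    seq_chars(substr(s, nchar(s) - end_len + 1L, nchar(s)))
  }))
  profile <- apply(mat, 2L, function(col) max(table(col)) / length(col))
  list(profile = as.numeric(profile), mean_pct = 100 * mean(profile),
       columns = mat)
}

#' Serialize a profile HMM to a plain-text key-value file
#'
#' Full-precision text representation with a round-trip guarantee via
#' [read_profile_hmm()].
#'
#' @param model A `ProfileHMM`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_hmm <- function(model, path) {
  stopifnot(inherits(model, "ProfileHMM"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    paste0("name\t", model$name),
    paste0("n_match_states\t", model$n_match_states),
    paste0("alphabet\t", paste(AA_ALPHABET20, collapse = "")),
    paste0("background\t", num(model$background)),
    paste0("insert_emissions\t", num(model$insert_emissions)),
    paste0("match_columns\t", paste(model$match_columns, collapse = " ")),
    vapply(seq_len(model$n_match_states), function(k) {
      paste0("match_emission\t", k, "\t", num(model$match_emissions[k, ]))
    }, ""),
    vapply(seq_len(model$n_match_states + 1L), function(k) {
      paste0("transition\t", k - 1L, "\t", num(model$transitions[k, ]))
    }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile HMM written by [write_profile_hmm()]
#'
#' @param path File path.
#' @return A `ProfileHMM`.
#' @export
read_profile_hmm <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[[`, "", 1L)
  get1 <- function(k) fields[[which(key == k)[1]]][2]
  nums <- function(x) as.numeric(strsplit(x, " ", fixed = TRUE)[[1]])
  M <- as.integer(get1("n_match_states"))
  me <- matrix(0, M, 20L, dimnames = list(NULL, AA_ALPHABET20))
  for (f in fields[key == "match_emission"]) {
    me[as.integer(f[2]), ] <- nums(f[3])
  }
  tr <- matrix(0, M + 1L, 7L,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (f in fields[key == "transition"]) {
    tr[as.integer(f[2]) + 1L, ] <- nums(f[3])
  }
  structure(list(name = get1("name"), n_match_states = M,
                 match_emissions = me,
                 insert_emissions = stats::setNames(nums(get1("insert_emissions")),
                                                    AA_ALPHABET20),
                 background = stats::setNames(nums(get1("background")),
                                              AA_ALPHABET20),
                 transitions = tr,
                 match_columns = as.integer(strsplit(get1("match_columns"),
                                                     " ")[[1]])),
            class = "ProfileHMM")
}
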
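# Independent brute-force oracles. Each re-derives an expected result by
# exhaustive enumeration or naive scanning, never by calling the package
# path it checks.

rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

rand_aa <- function(n, seed) {
  withr::with_seed(seed, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      n, TRUE), collapse = ""))
}

# --- ends-free alignment score by exhaustive enumeration -------------------
# Clip a free prefix of one sequence and a free suffix of one sequence,
# then enumerate every global alignment (affine gaps: open 5 incl. first
# position, extend 2) of the remaining substrings by DFS over move strings.
brute_global_affine <- function(a, b, match = 2, mismatch = -3,
                                open = 5, extend = 2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i == na && j == nb) { best <<- max(best, sc); return(invisible()) }
    if (i < na && j < nb) {
      rec(i + 1, j + 1, sc + if (ca[i + 1] == cb[j + 1]) match else mismatch, "M")
    }
    if (i < na) rec(i + 1, j, sc - if (last == "D") extend else open, "D")
    if (j < nb) rec(i, j + 1, sc - if (last == "I") extend else open, "I")
  }
  rec(0, 0, 0, "M")
  best
}

brute_endsfree_score <- function(a, b, ...) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0  # empty alignment is always available
  for (i0 in 0:na) for (j0 in 0:nb) {
    if (i0 > 0 && j0 > 0) next  # free leading clip in one sequence only
    for (i1 in i0:na) for (j1 in j0:nb) {
      if (i1 < na && j1 < nb) next  # free trailing clip in one sequence only
      if (i1 == i0 && j1 == j0) next
      best <- max(best, brute_global_affine(substr(a, i0 + 1, i1),
                                            substr(b, j0 + 1, j1), ...))
    }
  }
  best
}

# --- terminal overlaps by naive scanning -----------------------------------
brute_terminal_overlap <- function(a, b, min_len = 20, max_mismatches = 2,
                                   allow_adjacent = FALSE, check_rc = TRUE) {
  scan_one <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    nx <- length(cx)
    hits <- list()
    for (k in min_len:min(nx, length(cy))) {
      mm <- which(cx[(nx - k + 1):nx] != cy[1:k]) - 1L
      ok <- length(mm) <= max_mismatches &&
        (allow_adjacent || length(mm) < 2 || all(diff(mm) > 1))
      if (ok) hits[[length(hits) + 1L]] <- list(k = k, mm = mm)
    }
    hits
  }
  res <- lapply(scan_one(a, b), c, orientation = "forward")
  if (check_rc) {
    brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    res <- c(res, lapply(scan_one(a, brc), c, orientation = "rc"))
  }
  if (!length(res)) return(NULL)
  ks <- vapply(res, `[[`, numeric(1), "k")
  fw <- vapply(res, function(x) x$orientation == "forward", logical(1))
  res[[order(-ks, !fw)[1]]]  # longest, forward preferred on ties
}

brute_exact_overlap <- function(a, b, min_len = 18) {
  na <- nchar(a)
  best <- 0L
  for (k in min_len:min(na, nchar(b))) {
    if (substr(a, na - k + 1, na) == substr(b, 1, k)) best <- k
  }
  best
}

# --- ORFs by enumeration of every start/stop pair --------------------------
brute_orfs <- function(seq, genetic_code = 1, min_len_nt = 150,
                       start_codons = "ATG") {
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  n <- nchar(seq)
  out <- list()
  for (strand in c(1, -1)) {
    s <- if (strand == 1) seq else rc
    for (offset in 0:2) {
      n_codons <- (nchar(s) - offset) %/% 3
      if (n_codons < 2) next
      starts <- offset + 1 + 3 * (seq_len(n_codons) - 1)
      codons <- substring(s, starts, starts + 2)
      aa <- unname(code[codons]); aa[is.na(aa)] <- "X"
      for (j in which(aa == "*")) {
        prev_stops <- which(aa[seq_len(j - 1)] == "*")
        seg_start <- if (length(prev_stops)) max(prev_stops) + 1 else 1
        cand <- which(codons[seg_start:(j - 1)] %in% start_codons) +
          seg_start - 1
        if (!length(cand)) next
        i <- min(cand)
        len <- (j - i + 1) * 3
        if (len < min_len_nt) next
        s0 <- offset + 3 * (i - 1); e0 <- offset + 3 * j
        if (strand == 1) { st <- s0; en <- e0 } else { st <- n - e0; en <- n - s0 }
        out[[length(out) + 1L]] <- list(frame = strand * (offset + 1),
                                        start = st, end = en, length_nt = len,
                                        protein = paste(aa[i:(j - 1)],
                                                        collapse = ""))
      }
    }
  }
  out
}

orf_key <- function(o) paste(o$frame, o$start, o$end, o$length_nt, o$protein)

# --- Viterbi score by DFS over every state path ----------------------------
brute_hmm_best_path <- function(model, protein) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  x <- strsplit(protein, "")[[1]]
  n <- length(x)
  M <- model$n_match_states
  tr <- model$transitions
  lo <- function(p) log2(p)
  em <- function(k, i) {
    j <- match(x[i], aa)
    if (is.na(j)) 0 else log2(model$match_emissions[k, j] / model$background[j])
  }
  best <- -Inf
  # state: node k (0..M), consumed i, type in M/I/D; transitions to END from
  # node M are the *M column
  rec <- function(type, k, i, sc) {
    if (!is.finite(sc)) return(invisible())
    if (k == M) {
      done <- sc + lo(tr[M + 1, paste0(type, "M")])
      if (i == n) best <<- max(best, done)
    }
    if (k < M && i < n) {  # -> M_{k+1}
      rec("M", k + 1, i + 1,
          sc + lo(tr[k + 1, paste0(type, "M")]) + em(k + 1, i + 1))
    }
    if (i < n && type != "D") {  # -> I_k
      rec("I", k, i + 1, sc + lo(tr[k + 1, paste0(type, "I")]))
    }
    if (k < M && type != "I") {  # -> D_{k+1}
      rec("D", k + 1, i, sc + lo(tr[k + 1, paste0(type, "D")]))
    }
  }
  rec("M", 0, 0, 0)
  best
}

# --- single-linkage clustering oracle --------------------------------------
brute_single_linkage <- function(contigs, identity_thr = 95,
                                 coverage_thr = 95) {
  n <- nrow(contigs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # k-mer screen: pairs sharing no exact 16-mer on either strand cannot
      # reach 95% identity over the shorter sequence at these lengths
      if (!viromerge:::shares_kmer(contigs$sequence[i], contigs$sequence[j])) next
      al <- semiglobal_align(contigs$sequence[i], contigs$sequence[j])
      if (al$identity_pct >= identity_thr &&
          al$shorter_cov_pct >= coverage_thr) {
        parent[find(j)] <- find(i)
      }
    }
  }
  split(contigs$id, vapply(seq_len(n), find, integer(1)))
}

canonical_partition <- function(groups) {
  unname(sort(vapply(lapply(groups, sort),
                     paste, character(1), collapse = "|")))
}
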
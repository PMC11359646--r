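## Seeded synthetic-data generators.
##
## Every structure the pipeline is built to detect — planted ORFs, terminal
## overlaps obeying or violating the bounded-mismatch rule, chimeric joins,
## tri-segmented genomes with shared 3' motifs and hairpins, reads with
## controlled per-time-point abundance — is planted here with ground truth
## attached, so each downstream stage can be tested end to end offline.

#' Virus families emulated by the reference generator
#' @format Character vector of seven family names.
#' @export
VIRUS_FAMILIES <- c("Botourmiaviridae", "Narnaviridae", "Mitoviridae",
                    "Fiersviridae", "Totiviridae", "Partitiviridae",
                    "Nodaviridae")

NONSTOP_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

## ORF of exactly orf_len nt (incl. TAA stop), free of internal stop codons
## under both code 1 and code 4 so it is recovered identically under either.
plant_orf <- function(orf_len) {
  stopifnot(orf_len %% 3 == 0, orf_len >= 9)
  n_interior <- orf_len / 3 - 2L
  paste0("ATG",
         paste(sample(setdiff(NONSTOP_CODONS, "ATG"), n_interior, replace = TRUE),
               collapse = ""),
         "TAA")
}

## random flank + in-frame TAA cap so the planted ATG is the segment's first
## start codon and the ORF cannot extend upstream
orf_with_flanks <- function(orf, upstream, downstream) {
  up <- if (upstream >= 3L) paste0(random_dna(upstream - 3L), "TAA")
        else random_dna(upstream)
  paste0(up, orf, random_dna(downstream))
}

#' Generate a synthetic multi-family reference virome
#'
#' Emits `n_families * per_family` nucleotide references, each labeled with
#' a virus family, with one long ORF planted (about 60% of the sequence,
#' never below 300 nt) and its translation attached. Stands in for a viral
#' reference database in tests and simulations.
#'
#' @param n_families Number of families (>= 1); the first seven use real
#'   RNA-virus family names, further ones are labeled `FamilyN`.
#' @param per_family References per family (>= 1).
#' @param length_range Integer pair, inclusive genome length range in nt
#'   (minimum >= 600).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return A `data.frame` with columns `id`, `family`, `sequence`,
#'   `protein`, `orf_start`, `orf_end` (0-based half-open).
#' @export
generate_reference_set <- function(n_families, per_family, length_range, seed) {
  stopifnot(n_families >= 1, per_family >= 1)
  if (length(length_range) != 2L || length_range[1] < 600 ||
      length_range[2] < length_range[1]) {
    stop("length_range must be (min, max) with min >= 600 and max >= min")
  }
  fams <- c(VIRUS_FAMILIES, paste0("Family", seq_len(max(0, n_families - 7)) + 7L))
  fams <- fams[seq_len(n_families)]
  with_rng(seed, {
    rows <- list()
    for (fam in fams) {
      for (j in seq_len(per_family)) {
        len <- if (length_range[1] == length_range[2]) length_range[1]
               else sample(length_range[1]:length_range[2], 1L)
        orf_len <- max(300L, (floor(0.6 * len) %/% 3L) * 3L)
        flank <- len - orf_len
        upstream <- sample(0:flank, 1L)
        orf <- plant_orf(orf_len)
        seqn <- orf_with_flanks(orf, upstream, flank - upstream)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("ref_%s_%d", fam, j), family = fam, sequence = seqn,
          protein = substr(translate_nt(orf), 1L, orf_len / 3 - 1L),
          orf_start = upstream, orf_end = upstream + orf_len,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Substitution-only sequence mutation to a target identity
#'
#' Applies exactly `round((1 - target_identity) * nchar(seq))` base
#' substitutions at distinct positions, so the realized Hamming identity
#' equals the target up to rounding.
#'
#' @param seq Non-empty nucleotide string.
#' @param target_identity Fraction in (0, 1]; 1 returns the input unchanged.
#' @param seed Integer seed.
#' @return Mutated nucleotide string of the same length.
#' @export
mutate_sequence <- function(seq, target_identity, seed) {
  stopifnot(is.character(seq), nzchar(seq))
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be in (0, 1]")
  }
  n <- nchar(seq)
  n_mut <- round((1 - target_identity) * n)
  if (n_mut == 0L) return(seq)
  with_rng(seed, {
    pos <- sample(n, n_mut)
    chars <- seq_chars(seq)
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    paste(chars, collapse = "")
  })
}

#' Codon-aware mutation preserving a target amino-acid identity
#'
#' Rewrites a coding sequence codon by codon: a fraction `1 - aa_identity`
#' of codons are replaced by codons of a different amino acid, the rest by a
#' random synonymous codon. Nucleotide identity falls far below amino-acid
#' identity, emulating the diverged-at-nucleotide / conserved-at-protein
#' signature of novel viruses.
#'
#' @param seq Coding nucleotide string, length divisible by 3, beginning at
#'   the first codon.
#' @param aa_identity Target fraction of codons kept synonymous, in (0, 1].
#' @param seed Integer seed.
#' @return Mutated coding sequence of the same length.
#' @export
mutate_coding_sequence <- function(seq, aa_identity, seed) {
  stopifnot(nchar(seq) %% 3 == 0, nchar(seq) >= 3)
  if (aa_identity <= 0 || aa_identity > 1) stop("aa_identity must be in (0, 1]")
  code <- genetic_code_table(1L)
  by_aa <- split(names(code), unname(code))
  starts <- seq(1L, nchar(seq) - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  with_rng(seed, {
    out <- vapply(codons, function(cd) {
      aa <- unname(code[cd])
      if (is.na(aa) || aa == "*") return(cd)
      if (stats::runif(1) <= aa_identity) {
        sample(by_aa[[aa]], 1L)  # synonymous
      } else {
        other <- setdiff(names(by_aa), c(aa, "*"))
        sample(by_aa[[sample(other, 1L)]], 1L)
      }
    }, "", USE.NAMES = FALSE)
    paste(out, collapse = "")
  })
}

sample_nonadjacent_offsets <- function(n, k) {
  ## k 0-based offsets in [0, n) with no two adjacent
  stopifnot(k <= ceiling(n / 2))
  repeat {
    off <- sort(sample.int(n, k) - 1L)
    if (k < 2L || all(diff(off) > 1L)) return(off)
  }
}

#' Split a reference into two fragments with a controlled terminal overlap
#'
#' Cuts the reference into a left and a right fragment sharing a terminal
#' overlap of `overlap_len` nucleotides, then plants exactly `n_mismatches`
#' substitutions inside the right fragment's copy of the overlap —
#' adjacently placed when `adjacent = TRUE`. The attached truth states
#' whether the pair satisfies the merge rule of at most 2 non-adjacent
#' mismatches within a window of at least 20 nt.
#'
#' @param ref A reference row (list or one-row data.frame with `id`,
#'   `sequence`) or a plain nucleotide string.
#' @param overlap_len Overlap length (>= 1 and < reference length - 1).
#' @param n_mismatches Substitutions planted inside the overlap
#'   (<= `overlap_len`).
#' @param adjacent Place two of the mismatches at adjacent offsets
#'   (requires `n_mismatches >= 2`).
#' @param seed Integer seed.
#' @param min_fragment Lower bound on both fragment lengths (default 0, no
#'   constraint beyond the split geometry).
#' @return List with `left` and `right` contig records (`id`, `sequence`)
#'   and `truth` (`source_id`, `overlap_len`, `mismatch_offsets`,
#'   `adjacent`, `mergeable`, `merged_length`).
#' @export
make_overlap_pair <- function(ref, overlap_len, n_mismatches = 0L,
                              adjacent = FALSE, seed = 1L, min_fragment = 0L) {
  if (is.character(ref)) ref <- list(id = "ref", sequence = ref)
  seqn <- ref$sequence
  L <- nchar(seqn)
  if (overlap_len < 1L || overlap_len + 1L >= L) stop("invalid overlap_len")
  if (n_mismatches > overlap_len) stop("n_mismatches exceeds overlap_len")
  if (adjacent && n_mismatches < 2L) stop("adjacent placement needs >= 2 mismatches")
  with_rng(seed, {
    lo <- max(1L, ceiling(0.3 * L), min_fragment - overlap_len)
    hi <- min(L - overlap_len - 1L, floor(0.7 * L), L - min_fragment)
    if (hi < lo) {
      lo <- max(1L, min_fragment - overlap_len)
      hi <- min(L - overlap_len - 1L, L - min_fragment)
    }
    if (hi < lo) stop("reference too short for the requested fragment sizes")
    p <- sample(lo:hi, 1L)
    left <- substr(seqn, 1L, p + overlap_len)
    right <- substr(seqn, p + 1L, L)
    off <- integer(0)
    if (n_mismatches > 0L) {
      off <- if (adjacent) {
        a0 <- sample.int(overlap_len - 1L, 1L) - 1L
        extra <- if (n_mismatches > 2L) {
          pool <- setdiff(0:(overlap_len - 1L), c(a0 - 1L, a0, a0 + 1L, a0 + 2L))
          sort(sample(pool, n_mismatches - 2L))
        } else integer(0)
        sort(c(a0, a0 + 1L, extra))
      } else sample_nonadjacent_offsets(overlap_len, n_mismatches)
      rc <- seq_chars(right)
      rc[off + 1L] <- vapply(rc[off + 1L],
                             function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      right <- paste(rc, collapse = "")
    }
    mergeable <- overlap_len >= 20L && rule_accepts(off, 2L, FALSE)
    list(
      left = list(id = paste0(ref$id, "_left"), sequence = left),
      right = list(id = paste0(ref$id, "_right"), sequence = right),
      truth = list(source_id = ref$id, overlap_len = overlap_len,
                   mismatch_offsets = off, adjacent = adjacent,
                   mergeable = mergeable,
                   merged_length = nchar(left) + nchar(right) - overlap_len))
  })
}

#' Join fragments of two references into an assembly chimera
#'
#' Concatenates a prefix of `ref_a` with a suffix of `ref_b`, with the join
#' fraction drawn uniformly so the breakpoint lands in the middle half of
#' the chimera (for comparable reference lengths).
#'
#' @param ref_a,ref_b Reference rows (with `id`, `family`, `sequence`) from
#'   different families.
#' @param seed Integer seed.
#' @return List with `contig` (`id`, `sequence`) and `truth` (`source_ids`,
#'   `families`, `breakpoint` — 0-based position of the join on the
#'   chimera).
#' @export
make_chimera <- function(ref_a, ref_b, seed = 1L) {
  if (identical(ref_a$id, ref_b$id)) stop("chimera requires two distinct references")
  if (!is.null(ref_a$family) && !is.null(ref_b$family) &&
      identical(ref_a$family, ref_b$family)) {
    stop("chimera requires references from different families")
  }
  with_rng(seed, {
    la <- nchar(ref_a$sequence); lb <- nchar(ref_b$sequence)
    ## rejection-sample the breakpoint so no ORF >= 300 nt reads well
    ## through the junction: a join rescued by its own ORF structure would
    ## not be a detectable chimera, hence not a valid planted artifact
    for (attempt in 1:50) {
      f <- stats::runif(1, 0.3, 0.7)
      bp <- round(f * la)
      contig_seq <- paste0(substr(ref_a$sequence, 1L, bp),
                           substr(ref_b$sequence, round(f * lb) + 1L, lb))
      orfs <- find_orfs(contig_seq, genetic_code = 1L, min_len_nt = 300L)
      clean <- !any(vapply(orfs, orf_spans_junction, logical(1),
                           bp = bp, orf_rescue_len = 300L))
      if (clean) break
    }
    if (!clean) stop("could not place a clean chimeric junction in 50 attempts")
    list(contig = list(id = paste0("chimera_", ref_a$id, "_", ref_b$id),
                       sequence = contig_seq),
         truth = list(source_ids = c(ref_a$id, ref_b$id),
                      families = c(ref_a$family %||% NA_character_,
                                   ref_b$family %||% NA_character_),
                      breakpoint = bp))
  })
}

## 3' block shared by all segments: A-spacer | G^s stem | A-loop | C^s stem |
## terminal motif over {A, C} with no CC runs and a leading A. The alphabet
## is chosen so the planted hairpin is the unique maximal stem-loop in the
## terminal window: A/C cannot pair with each other, isolated Cs cannot seed
## an alternative stem against the G run, and without T no GU pair exists.
make_terminal_block <- function(motif, stem, loop, window = 50L) {
  content <- 2L * stem + loop + nchar(motif)
  if (content > window) stop("3' block exceeds the ", window, "-nt terminal window")
  paste0(strrep("A", window - content),
         strrep("G", stem), strrep("A", loop), strrep("C", stem), motif)
}

sample_terminal_motif <- function(len) {
  out <- character(len)
  out[1] <- "A"
  for (i in seq_len(len)[-1]) {
    out[i] <- if (out[i - 1L] == "C") "A" else sample(c("A", "C"), 1L)
  }
  paste(out, collapse = "")
}

#' Generate a tri-segmented narnavirus-like genome with ground truth
#'
#' Builds RNA1 (long, RdRp-like ORF), RNA2 and RNA3 (shorter, distinct
#' hypothetical-protein ORFs). All three segments end in the same 3'
#' terminal block: a conserved motif of `terminal_motif_len` nt immediately
#' preceded by a planted stem-loop of the requested geometry, inside the
#' terminal 50-nt window. RNA2 defaults to 2163 nt carrying a 2055-nt ORF
#' and, when `split_rna2 = TRUE`, is additionally emitted as two fragments
#' whose facing termini share an exact overlap of `split_overlap`
#' nucleotides — the split-segment situation the association stage is built
#' to resolve.
#'
#' @param terminal_motif_len Conserved 3' motif length (>= 10, default 18).
#' @param hairpin_stem Stem length in base pairs (>= 3, default 5).
#' @param hairpin_loop Loop length in nt (3 to 8, default 4).
#' @param seed Integer seed.
#' @param split_rna2 Emit RNA2 as two overlapping fragments (default TRUE).
#' @param split_overlap Length of the exact shared terminus (default 18).
#' @param rna2_len,rna2_orf_len RNA2 geometry (defaults 2163 / 2055 nt).
#' @return List with `segments` (data.frame `id`, `class`, `sequence`),
#'   `contigs` (emitted contigs; RNA2 replaced by its fragments when
#'   split), `proteins` (named RNA1/RNA2/RNA3 prototype translations),
#'   `motif`, and `truth` (per-segment ORF coordinates, hairpin geometry,
#'   and the split record with fragment ids, overlap and merged length).
#' @export
make_segmented_genome <- function(terminal_motif_len = 18L, hairpin_stem = 5L,
                                  hairpin_loop = 4L, seed = 1L,
                                  split_rna2 = TRUE, split_overlap = 18L,
                                  rna2_len = 2163L, rna2_orf_len = 2055L) {
  if (terminal_motif_len < 10L) stop("terminal_motif_len must be >= 10")
  if (hairpin_stem < 3L) stop("hairpin_stem must be >= 3")
  if (hairpin_loop < 3L || hairpin_loop > 8L) stop("hairpin_loop must be in [3, 8]")
  stopifnot(rna2_orf_len %% 3 == 0, rna2_len > rna2_orf_len + 53L)
  with_rng(seed, {
    motif <- sample_terminal_motif(terminal_motif_len)
    tail_block <- make_terminal_block(motif, hairpin_stem, hairpin_loop)
    tw <- nchar(tail_block)

    build_segment <- function(id, class, total_len, orf_len) {
      upstream <- total_len - orf_len - tw
      stopifnot(upstream >= 3L)
      orf <- plant_orf(orf_len)
      seqn <- paste0(orf_with_flanks(orf, upstream, 0L), tail_block)
      list(id = id, class = class, sequence = seqn,
           orf_start = upstream, orf_end = upstream + orf_len,
           protein = substr(translate_nt(orf), 1L, orf_len / 3 - 1L))
    }

    rna1 <- build_segment("seg_RNA1", "RNA1", 2510L, 2400L)
    rna2 <- build_segment("seg_RNA2", "RNA2", rna2_len, rna2_orf_len)
    rna3 <- build_segment("seg_RNA3", "RNA3", 540L, 420L)
    segs <- list(rna1, rna2, rna3)

    segments <- data.frame(
      id = vapply(segs, `[[`, "", "id"),
      class = vapply(segs, `[[`, "", "class"),
      sequence = vapply(segs, `[[`, "", "sequence"),
      stringsAsFactors = FALSE)

    split_truth <- NULL
    contigs <- segments[, c("id", "sequence")]
    if (split_rna2) {
      L2 <- nchar(rna2$sequence)
      p <- round((L2 - split_overlap) / 2)
      frag_5p <- substr(rna2$sequence, 1L, p + split_overlap)  # 3' end pairs...
      frag_3p <- substr(rna2$sequence, p + 1L, L2)             # ...this 5' end
      contigs <- rbind(
        contigs[contigs$id != "seg_RNA2", ],
        data.frame(id = c("seg_RNA2.2", "seg_RNA2.1"),
                   sequence = c(frag_5p, frag_3p), stringsAsFactors = FALSE))
      split_truth <- list(left_id = "seg_RNA2.2", right_id = "seg_RNA2.1",
                          overlap_len = split_overlap,
                          merged_length = L2, merged_orf_nt = rna2_orf_len)
    }

    list(segments = segments, contigs = contigs,
         proteins = stats::setNames(vapply(segs, `[[`, "", "protein"),
                                    vapply(segs, `[[`, "", "class")),
         motif = motif,
         truth = list(
           orfs = lapply(segs, function(s)
             s[c("id", "class", "orf_start", "orf_end")]),
           hairpin = list(stem = hairpin_stem, loop = hairpin_loop),
           split = split_truth))
  })
}

#' Build a per-contig abundance profile across the three time points
#'
#' Assigns each contig a trajectory shape — `declining` (the dominant
#' pattern during fermentation), `peaked` (maximum at 20 h) or `rising`
#' (nearly doubling by 68 h) — and converts the shaped weights into
#' per-time-point fractions summing to 1.
#'
#' @param contig_ids Character vector of contig ids.
#' @param trajectories Optional character vector (recycled) of shapes; when
#'   `NULL`, roughly 70% declining, 15% peaked, 15% rising.
#' @param seed Integer seed (per-contig scale jitter and shape assignment).
#' @return List with `fractions` (matrix contigs x `TIMEPOINTS`, columns
#'   summing to 1) and `trajectories` (named character vector).
#' @export
make_abundance_profile <- function(contig_ids, trajectories = NULL, seed = 1L) {
  stopifnot(length(contig_ids) >= 1)
  shapes <- list(declining = c(1, 0.45, 0.08),
                 peaked = c(0.5, 1, 0.1),
                 rising = c(0.28, 0.55, 1))
  n <- length(contig_ids)
  with_rng(seed, {
    if (is.null(trajectories)) {
      trajectories <- sample(c("declining", "peaked", "rising"), n,
                             replace = TRUE, prob = c(0.7, 0.15, 0.15))
    } else {
      trajectories <- rep_len(trajectories, n)
    }
    stopifnot(all(trajectories %in% names(shapes)))
    w <- t(vapply(seq_len(n), function(i) {
      shapes[[trajectories[i]]] * stats::runif(1, 0.5, 2)
    }, numeric(3)))
    fr <- sweep(w, 2, colSums(w), "/")
    dimnames(fr) <- list(contig_ids, TIMEPOINTS)
    list(fractions = fr,
         trajectories = stats::setNames(trajectories, contig_ids))
  })
}

#' Simulate error-free reads per fermentation time point
#'
#' Draws multinomial read counts per contig per time point from the
#' abundance fractions, then samples each read as an exact forward-strand
#' substring at a uniform position within its contig.
#'
#' @param contigs data.frame with `id` and `sequence`.
#' @param fractions Matrix contigs x `TIMEPOINTS` of expected read
#'   fractions; columns must sum to 1 (tolerance 1e-9).
#' @param read_length Read length in nt (<= shortest contig).
#' @param n_reads_per_timepoint Reads drawn per library.
#' @param seed Integer seed.
#' @return List with `reads` (named list over `TIMEPOINTS`, each a named
#'   character vector of read sequences) and `truth_counts` (matrix contigs
#'   x `TIMEPOINTS` of realized counts).
#' @export
simulate_reads <- function(contigs, fractions, read_length = 100L,
                           n_reads_per_timepoint = 10000L, seed = 1L) {
  if (nrow(contigs) == 0L) stop("contig set must be non-empty")
  lens <- nchar(contigs$sequence)
  if (read_length > min(lens)) stop("read_length exceeds the shortest contig")
  fractions <- as.matrix(fractions)[contigs$id, TIMEPOINTS, drop = FALSE]
  if (any(fractions < 0) || any(abs(colSums(fractions) - 1) > 1e-9)) {
    stop("fractions must be non-negative with columns summing to 1")
  }
  with_rng(seed, {
    truth <- matrix(0L, nrow(contigs), 3L,
                    dimnames = list(contigs$id, TIMEPOINTS))
    reads <- stats::setNames(vector("list", 3L), TIMEPOINTS)
    for (tp in TIMEPOINTS) {
      if (n_reads_per_timepoint == 0L) {
        reads[[tp]] <- stats::setNames(character(0), character(0))
        next
      }
      counts <- as.vector(stats::rmultinom(1, n_reads_per_timepoint,
                                           fractions[, tp]))
      truth[, tp] <- counts
      rs <- character(0)
      for (i in seq_len(nrow(contigs))) {
        if (counts[i] == 0L) next
        starts <- sample.int(lens[i] - read_length + 1L, counts[i],
                             replace = TRUE)
        rs <- c(rs, substring(contigs$sequence[i], starts,
                              starts + read_length - 1L))
      }
      rs <- sample(rs)  # shuffle library order
      names(rs) <- sprintf("%s_read_%d", tp, seq_along(rs))
      reads[[tp]] <- rs
    }
    list(reads = reads, truth_counts = truth)
  })
}

#' Truth-labeled contig suite exercising the whole curation pipeline
#'
#' Builds a 50-contig set from a fresh synthetic reference virome:
#' 25 singleton mutants of distinct references, 10 near-duplicates (96%
#' identity to the first 10 singletons), 4 fragment pairs with terminal
#' overlaps obeying the merge rule, 2 pairs violating it (3 mismatches;
#' 2 adjacent mismatches), and 3 cross-family chimeras. The attached truth
#' states the audit counts [curate()] must report.
#'
#' @param seed Integer seed.
#' @param length_range Reference length range (default 1100-1400 nt: short
#'   enough for quick all-pairs oracles, long enough that both halves of a
#'   split pair survive the 500-nt filter).
#' @return List with `contigs`, `references`, and `truth` (per-category id
#'   lists plus `expected` audit counts: `clustered_away = 10`,
#'   `merged_into = 8`, `chimera_dropped = 3`, `kept = 33`).
#' @export
make_curation_suite <- function(seed = 1L, length_range = c(1100L, 1400L)) {
  refs <- generate_reference_set(7, 6, length_range, seed = seed)
  with_rng(seed + 1L, {
    sub_seeds <- sample.int(10000L, 60L)
  })
  contigs <- list()
  add <- function(id, sequence) {
    contigs[[length(contigs) + 1L]] <<- data.frame(
      id = id, sequence = sequence, stringsAsFactors = FALSE)
  }
  singles <- sprintf("single_%02d", 1:25)
  for (i in 1:25) {
    add(singles[i], mutate_sequence(refs$sequence[i], 0.98, sub_seeds[i]))
  }
  dups <- sprintf("dup_%02d", 1:10)
  for (i in 1:10) {
    add(dups[i], mutate_sequence(contigs[[i]]$sequence, 0.96, sub_seeds[25 + i]))
  }
  merge_specs <- list(c(30, 0, 0), c(30, 0, 0), c(20, 2, 0), c(25, 1, 0))
  bad_specs <- list(c(20, 3, 0), c(20, 2, 1))
  pair_ids <- list()
  for (p in seq_along(c(merge_specs, bad_specs))) {
    sp <- c(merge_specs, bad_specs)[[p]]
    pr <- make_overlap_pair(as.list(refs[25 + p, ]), sp[1], sp[2],
                            adjacent = sp[3] == 1, seed = sub_seeds[40 + p],
                            min_fragment = 520L)
    add(pr$left$id, pr$left$sequence)
    add(pr$right$id, pr$right$sequence)
    pair_ids[[p]] <- c(pr$left$id, pr$right$id)
  }
  chim_parents <- list(c(32, 38), c(33, 39), c(34, 40))  # cross-family rows
  chim_ids <- character(3)
  for (p in 1:3) {
    pr <- chim_parents[[p]]
    ch <- make_chimera(as.list(refs[pr[1], ]), as.list(refs[pr[2], ]),
                       seed = sub_seeds[50 + p])
    chim_ids[p] <- ch$contig$id
    add(ch$contig$id, ch$contig$sequence)
  }
  contigs <- do.call(rbind, contigs)
  list(contigs = contigs, references = refs,
       truth = list(
         singleton_ids = singles, duplicate_ids = dups,
         merge_pair_ids = pair_ids[1:4], bad_pair_ids = pair_ids[5:6],
         chimera_ids = chim_ids,
         expected = list(input = 50L, length_dropped = 0L,
                         clustered_away = 10L, merged_into = 8L,
                         chimera_dropped = 3L, kept = 33L)))
}

mutate_protein <- function(protein, frac, alphabet = AA_ALPHABET20) {
  n <- nchar(protein)
  n_mut <- round(frac * n)
  if (n_mut == 0L) return(protein)
  pos <- sample(n, n_mut)
  chars <- seq_chars(protein)
  chars[pos] <- vapply(chars[pos],
                       function(a) sample(setdiff(alphabet, a), 1L), "")
  paste(chars, collapse = "")
}

#' Generate an aligned training set around a protein prototype
#'
#' Emits `n_seqs` substitution-only mutants of the prototype as an
#' equal-length (gap-free) alignment. The per-row mutation rate is solved so
#' the *mean pairwise* identity among rows matches `identity`: with each row
#' mutated at rate q at uniform positions, two rows agree at a position with
#' probability (1-q)^2 + q^2/19.
#'
#' @param prototype Amino-acid string.
#' @param n_seqs Number of rows (>= 2).
#' @param identity Target mean pairwise identity, in (0.1, 1].
#' @param seed Integer seed.
#' @return Named character vector of aligned rows, all `nchar(prototype)`
#'   long.
#' @export
make_training_msa <- function(prototype, n_seqs, identity = 0.7, seed = 1L) {
  if (n_seqs < 2L) stop("n_seqs must be >= 2")
  if (identity <= 0.1 || identity > 1) stop("identity must be in (0.1, 1]")
  a <- 20 / 19
  q <- (1 - sqrt(max(0, 1 - a * (1 - identity)))) / a
  with_rng(seed, {
    rows <- vapply(seq_len(n_seqs), function(i) mutate_protein(prototype, q), "")
    stats::setNames(rows, sprintf("train_%03d", seq_len(n_seqs)))
  })
}
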
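toy_model <- function() {
  # gapless identical rows: 3 match states, near-deterministic emissions
  build_profile_hmm(rep("MKL", 4), name = "toy")
}

test_that("profile construction follows the gap-fraction and pseudocount rules", {
  m <- toy_model()
  expect_equal(m$n_match_states, 3L)
  # each match state emits its column residue with maximal probability
  expect_equal(unname(colnames(m$match_emissions)[apply(m$match_emissions,
                                                        1, which.max)]),
               c("M", "K", "L"))
  # pseudocount-smoothed: column of 4 'M' + 1 per residue over 24 total
  expect_equal(unname(m$match_emissions[1, "M"]), 5 / 24)
  expect_equal(unname(m$match_emissions[1, "K"]), 1 / 24)
  # probability groups sum to 1
  expect_true(all(abs(rowSums(m$match_emissions) - 1) < 1e-9))
  expect_true(all(abs(rowSums(m$transitions[, c("MM", "MI", "MD")]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(m$transitions[, c("IM", "II")]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(m$transitions[1:m$n_match_states,
                                            c("DM", "DD")]) - 1) < 1e-9))
  expect_equal(abs(sum(m$background) - 1) < 1e-9, TRUE)

  # a 60%-gap column is not a match state at the default threshold
  msa <- c("MK-L", "M--L", "MA-L", "MKYL", "MK-L")
  m2 <- build_profile_hmm(msa)
  expect_equal(m2$n_match_states, 3L)
  expect_equal(m2$match_columns, c(1L, 2L, 4L))

  expect_error(build_profile_hmm(c("MK", "MKL")), "equal length")
  expect_error(build_profile_hmm("MKL"), "at least 2")
})

test_that("Viterbi score equals exhaustive path enumeration on toy models", {
  models <- list(
    toy_model(),
    build_profile_hmm(c("MK-L", "M--L", "MAYL", "MKYL"), name = "gappy"),
    build_profile_hmm(c("AC", "AC", "AD", "CC"), name = "two"))
  seqs <- c("MKL", "ML", "MKYL", "A", "ACDE", "KK", "MKLAA")
  for (m in models) {
    for (s in seqs) {
      expect_equal(hmm_score(m, s)$score_bits, brute_hmm_best_path(m, s),
                   tolerance = 1e-9,
                   info = sprintf("%s vs %s", m$name, s))
    }
  }
})

test_that("hand-set two-state model scores a two-residue sequence as the log-odds sum", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bg <- rep(1 / 20, 20)
  em <- matrix(1 / 40, 2, 20, dimnames = list(NULL, aa))
  em[1, "M"] <- em[1, "M"] + 19 / 40  # p(M) = 0.5 at state 1
  em[2, "K"] <- em[2, "K"] + 19 / 40
  tr <- matrix(0, 3, 7, dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                                "DM", "DD")))
  tr[, "MM"] <- 0.8; tr[, "MI"] <- 0.1; tr[, "MD"] <- 0.1
  tr[, "IM"] <- 0.6; tr[, "II"] <- 0.4
  tr[, "DM"] <- 0.7; tr[, "DD"] <- 0.3
  tr[3, "MM"] <- 0.9; tr[3, "MI"] <- 0.1; tr[3, c("MD", "DD")] <- 0
  model <- structure(list(name = "hand", n_match_states = 2L,
                          match_emissions = em, insert_emissions = bg,
                          background = stats::setNames(bg, aa),
                          transitions = tr, match_columns = 1:2),
                     class = "ProfileHMM")
  got <- hmm_score(model, "MK", return_path = TRUE)
  # begin -M1 ("M") -M2 ("K") -end, all through MM transitions
  expected <- log2(0.8) + log2(0.5 / 0.05) + log2(0.8) + log2(0.5 / 0.05) +
    log2(0.9)
  expect_equal(got$score_bits, expected, tolerance = 1e-12)
  expect_equal(got$path, c("M1", "M2"))
  expect_equal(got$score_bits, brute_hmm_best_path(model, "MK"),
               tolerance = 1e-12)
})

test_that("scoring treats unknown residues as background and rejects empty input", {
  m <- toy_model()
  base <- hmm_score(m, "MKL")$score_bits
  with_x <- hmm_score(m, "MKLXX")$score_bits
  # trailing Xs emit as background through the final insert state; only the
  # insert transitions change the score, never the emissions
  tr <- m$transitions
  delta <- unname(log2(tr[4, "MI"]) + log2(tr[4, "II"]) + log2(tr[4, "IM"]) -
                    log2(tr[4, "MM"]))
  expect_equal(with_x - base, delta, tolerance = 1e-9)
  expect_error(hmm_score(m, ""), "non-empty")
})

test_that("models round-trip through plain-text serialization", {
  sg <- make_segmented_genome(seed = 19)
  msa <- make_training_msa(sg$proteins[["RNA3"]], 12, 0.7, seed = 3)
  m <- build_profile_hmm(msa, name = "RNA3")
  path <- tempfile(fileext = ".hmm")
  write_profile_hmm(m, path)
  m2 <- read_profile_hmm(path)
  expect_equal(m2$match_emissions, m$match_emissions)
  expect_equal(m2$transitions, m$transitions)
  expect_equal(m2$background, m$background)
  expect_equal(m2$n_match_states, m$n_match_states)
  expect_equal(m2$name, m$name)
  expect_equal(hmm_score(m2, sg$proteins[["RNA3"]])$score_bits,
               hmm_score(m, sg$proteins[["RNA3"]])$score_bits)
})

test_that("segment assignment recovers planted classes and thresholds apply", {
  sg <- make_segmented_genome(seed = 19)
  models <- lapply(c(RNA1 = "RNA1", RNA2 = "RNA2", RNA3 = "RNA3"), function(cl) {
    build_profile_hmm(make_training_msa(sg$proteins[[cl]], 20, 0.7,
                                        seed = 100 + nchar(cl)), name = cl)
  })
  test_prots <- vapply(sg$proteins, function(p) {
    withr::with_seed(7, viromerge:::mutate_protein(p, 0.4))
  }, "")
  asg <- assign_segment(test_prots, models, threshold_bits = 10)
  expect_equal(asg$best_class, c("RNA1", "RNA2", "RNA3"))

  rand <- rand_aa(200, seed = 5)
  expect_equal(assign_segment(c(r = rand), models)$best_class, "none")
  expect_equal(assign_segment(test_prots, models,
                              threshold_bits = Inf)$best_class,
               rep("none", 3))
})

test_that("split segments merge on their exact terminus and extend the ORF", {
  sg <- make_segmented_genome(seed = 23)
  frags <- sg$contigs[sg$contigs$id %in% c("seg_RNA2.1", "seg_RNA2.2"), ]
  mr <- merge_split_segments(frags)
  tr <- sg$truth$split
  expect_equal(mr$input_ids, c(tr$left_id, tr$right_id))
  expect_equal(mr$overlap$overlap_len, tr$overlap_len)
  expect_equal(mr$merged_length, tr$merged_length)
  expect_equal(mr$orf$length_nt, tr$merged_orf_nt)
  expect_equal(mr$sequence,
               sg$segments$sequence[sg$segments$class == "RNA2"])
  # merged ORF strictly longer than either fragment's longest ORF
  for (i in 1:2) {
    frag_orf <- longest_orf(frags$sequence[i])
    expect_lt(if (is.null(frag_orf)) 0L else frag_orf$length_nt,
              mr$orf$length_nt)
  }
  # no shared terminus -> no merge
  expect_null(merge_split_segments(data.frame(
    id = c("x", "y"),
    sequence = c(rand_dna(400, 1), rand_dna(400, 2)))))
})

test_that("split-segment merging is orientation-safe", {
  sg <- make_segmented_genome(seed = 29)
  frags <- sg$contigs[sg$contigs$id %in% c("seg_RNA2.1", "seg_RNA2.2"), ]
  mr <- merge_split_segments(frags)
  flipped <- data.frame(id = frags$id,
                        sequence = vapply(frags$sequence, revcomp, ""))
  mr_rc <- merge_split_segments(flipped)
  expect_equal(mr_rc$sequence, revcomp(mr$sequence))
})

test_that("junction coverage certifies continuity from junction-spanning reads", {
  sg <- make_segmented_genome(seed = 31)
  merged <- sg$segments$sequence[sg$segments$class == "RNA2"]
  junction <- nchar(sg$contigs$sequence[sg$contigs$id == "seg_RNA2.2"])
  reads <- simulate_reads(
    data.frame(id = "m", sequence = merged),
    matrix(1, 1, 3, dimnames = list("m", TIMEPOINTS)),
    100, 400, seed = 2)$reads[["7h"]]
  expect_gt(junction_coverage(merged, reads, junction), 0)

  # reads that never span the junction leave a zero-depth window
  window_free <- c(
    substring(merged, 1, junction - 130),
    substring(merged, junction + 130, nchar(merged)))
  starts <- unlist(lapply(nchar(window_free) - 99, function(n) 1:n))
  piece <- rep(seq_along(window_free), nchar(window_free) - 99)
  nonspan <- substring(window_free[piece], starts, starts + 99)
  expect_equal(junction_coverage(merged, nonspan[seq(1, length(nonspan), 10)],
                                 junction), 0)
  expect_equal(junction_coverage(merged, character(0), junction), 0)
  expect_error(junction_coverage(merged, character(0), nchar(merged) + 5),
               "junction")
})

test_that("terminal hairpin search recovers planted geometry and handles nulls", {
  hp <- find_terminal_hairpin(paste0(rand_dna(60, 1), "GGGGAAAACCCC"),
                              window_3prime = 50)
  expect_equal(hp$stem_len, 4L)
  expect_equal(hp$loop_len, 4L)
  expect_equal(hp$score, 4)

  expect_null(find_terminal_hairpin(strrep("A", 80)))

  sg <- make_segmented_genome(hairpin_stem = 5, hairpin_loop = 4, seed = 37)
  for (s in sg$segments$sequence) {
    hp <- find_terminal_hairpin(s)
    expect_equal(hp$stem_len, 5L)
    expect_equal(hp$loop_len, 4L)
    expect_equal(hp$score, 5)
    # planted pairs are G-C: stem positions pair across the loop
    chars <- strsplit(s, "")[[1]]
    for (pr in hp$pairs) {
      expect_equal(sort(c(chars[pr[1] + 1], chars[pr[2] + 1])), c("C", "G"))
    }
  }
})

test_that("GU wobble counts half and can be disabled", {
  # stem GGGG / TCCC gives 3 WC pairs + 1 GU; the C loop cannot pair with
  # the T-side arm, so no shifted all-Watson-Crick geometry outscores it
  seqn <- paste0(strrep("A", 68), "GGGGCCCCTCCC")
  hp <- find_terminal_hairpin(seqn, window_3prime = 30)
  expect_equal(hp$score, 3.5)
  expect_equal(hp$stem_len, 4L)
  expect_equal(sum(vapply(hp$pairs, function(pr) {
    substr(seqn, pr[1] + 1, pr[1] + 1) == "G" &&
      substr(seqn, pr[2] + 1, pr[2] + 1) == "T"
  }, logical(1))), 1L)  # exactly one wobble pair in the stem
  hp_strict <- find_terminal_hairpin(seqn, window_3prime = 30,
                                     allow_gu = FALSE)
  expect_equal(hp_strict$stem_len, 3L)
  expect_equal(hp_strict$score, 3)
})

test_that("terminal conservation separates shared termini from divergent upstream", {
  shared <- rand_dna(18, seed = 55)
  seqs <- vapply(1:6, function(i) paste0(rand_dna(120, 60 + i), shared), "")
  tc <- terminal_conservation(seqs, end_len = 40)
  expect_equal(tc$profile[23:40], rep(1, 18))
  upstream <- mean(tc$profile[1:22])
  expect_lt(upstream, 0.65)  # modal-base fraction of 6 random draws
  ident <- terminal_conservation(rep(shared, 3), end_len = 18)
  expect_equal(ident$mean_pct, 100)
})
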
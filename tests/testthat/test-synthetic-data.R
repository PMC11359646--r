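test_that("reference generator is deterministic and respects its contract", {
  one <- generate_reference_set(1, 1, c(1000, 1000), seed = 7)
  expect_equal(nrow(one), 1L)
  expect_equal(nchar(one$sequence), 1000L)
  expect_identical(one, generate_reference_set(1, 1, c(1000, 1000), seed = 7))

  refs <- generate_reference_set(3, 5, c(2000, 5000), seed = 1)
  expect_equal(nrow(refs), 15L)
  expect_true(all(nchar(refs$sequence) >= 2000 & nchar(refs$sequence) <= 5000))
  expect_false(anyDuplicated(refs$id) > 0)
  expect_equal(length(unique(refs$family)), 3L)

  # planted ORF >= 300 nt, protein is the translation of the ORF substring
  for (i in c(1, 8, 15)) {
    orf_seq <- substr(refs$sequence[i], refs$orf_start[i] + 1, refs$orf_end[i])
    expect_gte(nchar(orf_seq), 300)
    aa <- unname(Biostrings::getGeneticCode("1")[
      substring(orf_seq, seq(1, nchar(orf_seq) - 2, 3),
                seq(3, nchar(orf_seq), 3))])
    expect_equal(paste(head(aa, -1), collapse = ""), refs$protein[i])
    expect_equal(tail(aa, 1), "*")
  }

  expect_error(generate_reference_set(1, 1, c(100, 200), seed = 1), "length_range")
})

test_that("mutate_sequence hits the identity target exactly up to rounding", {
  a <- rand_dna(1000, seed = 5)
  expect_identical(mutate_sequence(a, 1.0, seed = 1), a)
  b <- mutate_sequence(a, 0.95, seed = 3)
  ham <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  expect_gte(ham, 0.94); expect_lte(ham, 0.96)
  expect_error(mutate_sequence("ACGT", 0), "target_identity")
  expect_identical(mutate_sequence(a, 0.95, seed = 3), b)
})

test_that("codon-aware mutation diverges nucleotides while conserving protein", {
  refs <- generate_reference_set(1, 1, c(1500, 1500), seed = 40)
  orf <- substr(refs$sequence[1], refs$orf_start[1] + 1, refs$orf_end[1])
  mut <- mutate_coding_sequence(orf, 0.85, seed = 2)
  expect_equal(nchar(mut), nchar(orf))
  nt_id <- mean(strsplit(orf, "")[[1]] == strsplit(mut, "")[[1]])
  expect_lt(nt_id, 0.70)
  code <- Biostrings::getGeneticCode("1")
  tr <- function(s) unname(code[substring(s, seq(1, nchar(s) - 2, 3),
                                          seq(3, nchar(s), 3))])
  aa_id <- mean(tr(orf) == tr(mut))
  expect_gte(aa_id, 0.80)
})

test_that("overlap pairs carry exactly the requested mismatch structure", {
  ref <- rand_dna(800, seed = 9)
  p <- make_overlap_pair(ref, 20, 2, adjacent = FALSE, seed = 4)
  left <- p$left$sequence; right <- p$right$sequence
  ov_left <- substr(left, nchar(left) - 19, nchar(left))
  ov_right <- substr(right, 1, 20)
  mm <- which(strsplit(ov_left, "")[[1]] != strsplit(ov_right, "")[[1]]) - 1
  expect_equal(mm, p$truth$mismatch_offsets)
  expect_equal(length(mm), 2L)
  expect_true(all(diff(mm) > 1))
  expect_true(p$truth$mergeable)

  padj <- make_overlap_pair(ref, 20, 2, adjacent = TRUE, seed = 5)
  expect_false(padj$truth$mergeable)
  expect_false(make_overlap_pair(ref, 20, 3, seed = 6)$truth$mergeable)
  expect_error(make_overlap_pair(ref, 10, 11, seed = 1), "n_mismatches")
})

test_that("chimeras join two families with a mid-contig breakpoint", {
  refs <- generate_reference_set(2, 1, c(2000, 2000), seed = 13)
  ch <- make_chimera(as.list(refs[1, ]), as.list(refs[2, ]), seed = 1)
  bp <- ch$truth$breakpoint
  expect_gt(bp, 0); expect_lt(bp, nchar(ch$contig$sequence))
  expect_identical(substr(ch$contig$sequence, 1, bp),
                   substr(refs$sequence[1], 1, bp))
  # breakpoint falls in the middle half of the contig across seeds
  fracs <- vapply(1:40, function(s) {
    chs <- make_chimera(as.list(refs[1, ]), as.list(refs[2, ]), seed = s)
    chs$truth$breakpoint / nchar(chs$contig$sequence)
  }, numeric(1))
  expect_true(all(fracs > 0.25 & fracs < 0.75))
  expect_error(make_chimera(as.list(refs[1, ]), as.list(refs[1, ])), "distinct")
})

test_that("segmented genomes plant motif, hairpin, ORFs and split exactly", {
  sg <- make_segmented_genome(terminal_motif_len = 18, hairpin_stem = 5,
                              hairpin_loop = 4, seed = 3)
  seqs <- sg$segments$sequence
  # identical terminal motif across all three segments
  tails <- substr(seqs, nchar(seqs) - 17, nchar(seqs))
  expect_equal(length(unique(tails)), 1L)
  expect_equal(unique(tails), sg$motif)
  # hairpin planted in each 3' window with the requested geometry
  for (s in seqs) {
    win <- substr(s, nchar(s) - 49, nchar(s))
    expect_match(win, "GGGGGAAAACCCCC")
  }
  # RNA2 split fragments share an exact 18-nt terminus and reassemble
  frag_l <- sg$contigs$sequence[sg$contigs$id == "seg_RNA2.2"]
  frag_r <- sg$contigs$sequence[sg$contigs$id == "seg_RNA2.1"]
  expect_equal(substr(frag_l, nchar(frag_l) - 17, nchar(frag_l)),
               substr(frag_r, 1, 18))
  expect_equal(nchar(frag_l) + nchar(frag_r) - 18,
               nchar(seqs[sg$segments$class == "RNA2"]))
  expect_error(make_segmented_genome(hairpin_loop = 2), "hairpin_loop")
})

test_that("abundance profiles are valid and reads are exact substrings", {
  sg <- make_segmented_genome(seed = 3, split_rna2 = FALSE)
  prof <- make_abundance_profile(sg$segments$id, seed = 5)
  expect_true(all(abs(colSums(prof$fractions) - 1) < 1e-9))
  expect_true(all(prof$fractions >= 0))

  sim0 <- simulate_reads(sg$segments, prof$fractions, 100, 0, seed = 1)
  expect_true(all(lengths(sim0$reads) == 0))

  sim <- simulate_reads(sg$segments, prof$fractions, 100, 500, seed = 2)
  expect_equal(unname(colSums(sim$truth_counts)), rep(500, 3))
  one <- sg$segments$sequence[1]
  single <- simulate_reads(sg$segments[1, ],
                           matrix(1, 1, 3, dimnames = list(sg$segments$id[1],
                                                           TIMEPOINTS)),
                           100, 200, seed = 3)
  expect_true(all(vapply(single$reads[["7h"]], grepl, logical(1),
                         x = one, fixed = TRUE)))

  # two contigs at 0.9/0.1: realized counts within 3 binomial s.d.
  two <- sg$segments[1:2, ]
  fr <- matrix(c(0.9, 0.1), 2, 3, dimnames = list(two$id, TIMEPOINTS))
  simb <- simulate_reads(two, fr, 100, 10000, seed = 4)
  sd3 <- 3 * sqrt(10000 * 0.9 * 0.1)
  expect_true(all(abs(simb$truth_counts[1, ] - 9000) <= sd3))
  expect_error(simulate_reads(sg$segments[0, ], prof$fractions, 100, 10),
               "non-empty")
})

test_that("training MSAs hit the target mean pairwise identity", {
  proto <- rand_aa(250, seed = 8)
  msa1 <- make_training_msa(proto, 5, 1.0, seed = 1)
  expect_true(all(msa1 == proto))
  msa <- make_training_msa(proto, 20, 0.7, seed = 2)
  expect_true(all(nchar(msa) == nchar(proto)))
  rows <- do.call(rbind, strsplit(msa, ""))
  pids <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    pids <- c(pids, mean(rows[i, ] == rows[j, ]))
  }
  expect_gte(mean(pids), 0.68); expect_lte(mean(pids), 0.72)
  expect_error(make_training_msa(proto, 1, 0.7), "n_seqs")
})

test_that("curation suite truth is internally consistent", {
  suite <- make_curation_suite(seed = 5)
  expect_equal(nrow(suite$contigs), 50L)
  expect_false(anyDuplicated(suite$contigs$id) > 0)
  with_ids <- c(suite$truth$singleton_ids, suite$truth$duplicate_ids,
                unlist(suite$truth$merge_pair_ids),
                unlist(suite$truth$bad_pair_ids), suite$truth$chimera_ids)
  expect_setequal(with_ids, suite$contigs$id)
  expect_true(all(nchar(suite$contigs$sequence) >= 500))
})
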
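test_that("length filter partitions exactly at the boundary", {
  contigs <- data.frame(id = c("a", "b", "c"),
                        sequence = c(rand_dna(499, 1), rand_dna(500, 2),
                                     rand_dna(501, 3)))
  lf <- length_filter(contigs, 500)
  expect_equal(lf$kept$id, c("b", "c"))
  expect_equal(lf$dropped$id, "a")
  strict <- length_filter(contigs, 500, strict_gt = TRUE)
  expect_equal(strict$kept$id, "c")
  empty <- length_filter(contigs[0, ])
  expect_equal(nrow(empty$kept) + nrow(empty$dropped), 0L)
})

test_that("redundancy clustering joins near-duplicates and separates diverged pairs", {
  base <- rand_dna(800, seed = 31)
  contigs <- data.frame(
    id = c("orig", "twin", "near", "far"),
    sequence = c(base, base, mutate_sequence(base, 0.96, seed = 1),
                 mutate_sequence(base, 0.80, seed = 2)))
  cl <- cluster_redundant(contigs)
  sizes <- sort(lengths(lapply(cl, `[[`, "member_ids")))
  expect_equal(sizes, c(1L, 3L))
  reps <- vapply(cl, `[[`, "", "representative_id")
  expect_true("far" %in% reps)
})

test_that("clustering agrees with the single-linkage oracle on separated clusters", {
  withr::with_seed(60, {
    bases <- replicate(6, paste(sample(c("A", "C", "G", "T"), 700, TRUE),
                                collapse = ""))
  })
  rows <- list()
  for (i in seq_along(bases)) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("base_%d", i), sequence = bases[i])
    for (j in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("mut_%d_%d", i, j),
        sequence = mutate_sequence(bases[i], 0.97, seed = 10 * i + j))
    }
  }
  contigs <- do.call(rbind, rows)
  got <- canonical_partition(lapply(cluster_redundant(contigs), `[[`,
                                    "member_ids"))
  exp <- canonical_partition(brute_single_linkage(contigs))
  expect_equal(got, exp)
  expect_length(got, 6L)
})

test_that("merging respects the length identity and chains transitively", {
  ref <- rand_dna(1500, seed = 41)
  p <- make_overlap_pair(ref, 30, 0, seed = 1)
  mg <- merge_by_overlap(data.frame(id = c(p$left$id, p$right$id),
                                    sequence = c(p$left$sequence,
                                                 p$right$sequence)))
  expect_equal(nrow(mg$contigs), 1L)
  expect_length(mg$merge_records, 1L)
  mr <- mg$merge_records[[1]]
  expect_equal(mr$merged_length,
               nchar(p$left$sequence) + nchar(p$right$sequence) - 30)
  expect_equal(mr$merged_length, p$truth$merged_length)
  expect_gte(mr$extension_nt, 0)

  # rejected pair stays split
  bad <- make_overlap_pair(ref, 20, 3, seed = 2)
  mg_bad <- merge_by_overlap(data.frame(
    id = c(bad$left$id, bad$right$id),
    sequence = c(bad$left$sequence, bad$right$sequence)))
  expect_equal(nrow(mg_bad$contigs), 2L)

  # three-way chain with exact overlaps collapses to one contig
  a <- substr(ref, 1, 620); b <- substr(ref, 601, 1120)
  cc <- substr(ref, 1101, 1500)
  mg3 <- merge_by_overlap(data.frame(id = c("a", "b", "c"),
                                     sequence = c(a, b, cc)))
  expect_equal(nrow(mg3$contigs), 1L)
  expect_equal(nchar(mg3$contigs$sequence), 1500L)
  expect_equal(mg3$contigs$sequence, ref)
  # merging never decreases the maximum contig length
  expect_gte(nchar(mg3$contigs$sequence), 620L)
})

test_that("merge uses the left contig's bases at overlap mismatches", {
  ref <- rand_dna(1200, seed = 43)
  p <- make_overlap_pair(ref, 24, 2, seed = 3)
  mg <- merge_by_overlap(data.frame(id = c("L", "R"),
                                    sequence = c(p$left$sequence,
                                                 p$right$sequence)))
  merged <- mg$contigs$sequence
  nl <- nchar(p$left$sequence)
  expect_equal(substr(merged, 1, nl), p$left$sequence)
})

test_that("reverse-complement overlaps are detected and merged", {
  ref <- rand_dna(1300, seed = 44)
  p <- make_overlap_pair(ref, 30, 0, seed = 4)
  flipped <- revcomp(p$right$sequence)
  mg <- merge_by_overlap(data.frame(id = c("L", "Rrc"),
                                    sequence = c(p$left$sequence, flipped)))
  expect_equal(nrow(mg$contigs), 1L)
  expect_equal(nchar(mg$contigs$sequence), p$truth$merged_length)
})

test_that("chimera calls require split families and honor ORF rescue", {
  refs <- generate_reference_set(4, 1, c(1600, 2000), seed = 51)
  ch <- make_chimera(as.list(refs[1, ]), as.list(refs[2, ]), seed = 5)
  hits <- viromerge:::reference_hits_for(ch$contig, refs, 75, 0.1)
  call <- detect_chimera(ch$contig, hits)
  expect_true(call$is_chimera)
  expect_lte(abs(call$breakpoint_estimate - ch$truth$breakpoint), 100)

  frag <- list(id = "frag", sequence = substr(refs$sequence[3], 101, 1500))
  hf <- viromerge:::reference_hits_for(frag, refs, 75, 0.1)
  expect_false(detect_chimera(frag, hf)$is_chimera)

  # a long planted ORF reading through the junction rescues the contig
  orf600 <- withr::with_seed(9, paste0(
    "ATG", paste(sample(setdiff(viromerge:::NONSTOP_CODONS, "ATG"), 198,
                        TRUE), collapse = ""), "TAA"))
  seqn <- ch$contig$sequence
  bp <- ch$truth$breakpoint
  planted <- paste0(substr(seqn, 1, bp - 300), orf600,
                    substr(seqn, bp + 301, nchar(seqn)))
  rescue <- detect_chimera(list(id = "resc", sequence = planted), hits)
  expect_false(rescue$is_chimera)
})

test_that("curate audits the 50-contig truth suite exactly and is idempotent", {
  suite <- make_curation_suite(seed = 2)
  res <- curate(suite$contigs, suite$references)
  acts <- table(factor(res$audit$action,
                       levels = c("length_dropped", "clustered_away",
                                  "merged_into", "chimera_dropped", "kept")))
  exp <- suite$truth$expected
  expect_equal(unname(acts["length_dropped"]), exp$length_dropped)
  expect_equal(unname(acts["clustered_away"]), exp$clustered_away)
  expect_equal(unname(acts["merged_into"]), exp$merged_into)
  expect_equal(unname(acts["chimera_dropped"]), exp$chimera_dropped)
  expect_equal(unname(acts["kept"]), exp$kept)

  # exactly one member of every duplicate pair is clustered away (the
  # representative is picked by id among equal-length members)
  away <- res$audit$contig_id[res$audit$action == "clustered_away"]
  for (i in 1:10) {
    pair <- c(suite$truth$duplicate_ids[i], suite$truth$singleton_ids[i])
    expect_equal(sum(pair %in% away), 1L, info = paste(pair, collapse = "/"))
  }
  # dropped chimeras are exactly the planted ones
  dropped <- res$audit$contig_id[res$audit$action == "chimera_dropped"]
  expect_setequal(dropped, suite$truth$chimera_ids)

  # conservation: every input contig has exactly one terminal action
  terminal <- res$audit[res$audit$action %in%
                          c("length_dropped", "clustered_away",
                            "merged_into", "chimera_dropped", "kept"), ]
  input_terminal <- terminal$contig_id[terminal$contig_id %in%
                                         suite$contigs$id]
  expect_setequal(input_terminal, suite$contigs$id)
  expect_false(anyDuplicated(input_terminal) > 0)

  # curation is a fixed point
  res2 <- curate(res$contigs, suite$references)
  expect_setequal(res2$contigs$sequence, res$contigs$sequence)
})

test_that("curate without references skips the chimera stage with a notice", {
  contigs <- data.frame(id = c("a", "b"),
                        sequence = c(rand_dna(600, 1), rand_dna(700, 2)))
  expect_message(res <- curate(contigs), "chimera stage skipped")
  expect_equal(nrow(res$contigs), 2L)
  expect_true(any(res$audit$action == "skipped"))
})
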
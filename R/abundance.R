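## Desk-scale quantification and dynamics: exact-match read assignment
## (equal-split multimapping), TPM normalization, alpha diversity,
## family-level trajectories and the rank-sum time-point comparison.

#' Assign reads to contigs by exact substring matching
#'
#' A read is assigned to every contig containing it as an exact substring
#' on either strand; a uniquely matching read counts 1, a read matching n
#' contigs contributes 1/n to each (equal-split multimapping). Reads
#' matching no contig are tallied separately.
#'
#' @param reads Character vector of read sequences.
#' @param contigs data.frame with `id`, `sequence`.
#' @param k Minimum read length accepted (default 31); shorter reads are a
#'   parameter error, mirroring k-mer-based quantifiers.
#' @return Named numeric vector of (possibly fractional) counts per contig,
#'   with attribute `unassigned` (number of unplaced reads).
#' @export
assign_reads <- function(reads, contigs, k = 31L) {
  contigs <- as_contigs(contigs)
  counts <- stats::setNames(numeric(nrow(contigs)), contigs$id)
  if (length(reads) == 0L) return(structure(counts, unassigned = 0L))
  if (any(nchar(reads) < k)) stop("reads shorter than k = ", k)
  fwd <- contigs$sequence
  rev <- vapply(fwd, revcomp, "", USE.NAMES = FALSE)
  tab <- table(reads)
  uniq <- names(tab)
  unassigned <- 0L
  for (u in seq_along(uniq)) {
    rd <- uniq[u]
    hit <- grepl(rd, fwd, fixed = TRUE) | grepl(rd, rev, fixed = TRUE)
    n_hit <- sum(hit)
    if (n_hit == 0L) {
      unassigned <- unassigned + as.integer(tab[u])
    } else {
      counts[hit] <- counts[hit] + as.numeric(tab[u]) / n_hit
    }
  }
  structure(counts, unassigned = unassigned)
}

#' Transcripts-per-million normalization
#'
#' Length-normalized abundance: `rate_i = count_i / length_i`,
#' `TPM_i = 1e6 * rate_i / sum(rate)`. An all-zero count vector yields
#' all-zero TPM rather than a division error.
#'
#' @param counts Non-negative numeric vector of per-contig read counts.
#' @param lengths Positive contig lengths in nt, parallel to `counts`.
#' @return Numeric vector of TPM values (summing to 1e6 unless all zero).
#' @export
tpm <- function(counts, lengths) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(lengths <= 0)) stop("lengths must be positive")
  stopifnot(length(counts) == length(lengths))
  rate <- counts / lengths
  total <- sum(rate)
  if (total == 0) return(counts * 0)
  1e6 * rate / total
}

#' Quantify read libraries into an abundance table
#'
#' Runs [assign_reads()] per time-point library and converts counts to TPM
#' per column.
#'
#' @param read_sets Named list of read vectors; names must cover
#'   `TIMEPOINTS`.
#' @param contigs data.frame with `id`, `sequence`.
#' @param k Passed to [assign_reads()].
#' @return An `AbundanceTable` list: `counts` and `tpm` (matrices contigs x
#'   `TIMEPOINTS`), `lengths`, `unassigned` (per time point).
#' @export
quantify <- function(read_sets, contigs, k = 31L) {
  contigs <- as_contigs(contigs)
  stopifnot(all(TIMEPOINTS %in% names(read_sets)))
  lens <- stats::setNames(nchar(contigs$sequence), contigs$id)
  counts <- matrix(0, nrow(contigs), 3L,
                   dimnames = list(contigs$id, TIMEPOINTS))
  unassigned <- stats::setNames(integer(3L), TIMEPOINTS)
  for (tp in TIMEPOINTS) {
    a <- assign_reads(read_sets[[tp]], contigs, k = k)
    counts[, tp] <- a
    unassigned[tp] <- attr(a, "unassigned")
  }
  tpm_mat <- apply(counts, 2L, tpm, lengths = lens)
  dimnames(tpm_mat) <- list(contigs$id, TIMEPOINTS)
  structure(list(counts = counts, tpm = tpm_mat, lengths = lens,
                 unassigned = unassigned),
            class = "AbundanceTable")
}

tpm_matrix <- function(table) {
  if (inherits(table, "AbundanceTable")) table$tpm else as.matrix(table)
}

#' Per-time-point richness and Shannon diversity
#'
#' Richness counts contigs detected above `detection_threshold` TPM;
#' Shannon entropy (nats) is computed over the detected contigs' TPM
#' proportions via `vegan`.
#'
#' @param table An `AbundanceTable` or a TPM matrix (contigs x
#'   `TIMEPOINTS`).
#' @param detection_threshold TPM detection cutoff (default 0, i.e. any
#'   signal).
#' @return data.frame with `timepoint`, `richness`, `shannon`,
#'   `detection_threshold`.
#' @export
alpha_diversity <- function(table, detection_threshold = 0) {
  m <- tpm_matrix(table)
  rows <- lapply(colnames(m), function(tp) {
    v <- m[, tp]
    det <- v[v > detection_threshold]
    data.frame(timepoint = tp, richness = length(det),
               shannon = if (length(det)) unname(vegan::diversity(det)) else 0,
               detection_threshold = detection_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

trajectory_label <- function(v) {
  d1 <- v[2] - v[1]; d2 <- v[3] - v[2]
  if (d1 == 0 && d2 == 0) return("flat")
  if (d1 <= 0 && d2 <= 0) return("declining")
  if (d1 >= 0 && d2 >= 0) return("rising")
  if (d1 > 0 && d2 < 0) return("peaked")
  "dipped"
}

#' Family-level abundance dynamics
#'
#' Sums TPM per family per time point and labels each family's trajectory
#' from the sign pattern of successive differences: `declining` (the
#' dominant fermentation pattern), `peaked` (maximum at 20 h), `rising`
#' (still increasing at 68 h), plus `dipped`/`flat` for the remaining
#' patterns.
#'
#' @param table An `AbundanceTable` or TPM matrix.
#' @param taxonomy Named character vector contig id -> family; contigs
#'   absent from it are grouped as `"unclassified"`.
#' @return data.frame with `family`, one column per time point, and
#'   `trajectory`.
#' @export
family_dynamics <- function(table, taxonomy) {
  m <- tpm_matrix(table)
  fam <- taxonomy[rownames(m)]
  fam[is.na(fam)] <- "unclassified"
  sums <- rowsum(m, group = fam)
  out <- data.frame(family = rownames(sums), stringsAsFactors = FALSE)
  for (tp in colnames(sums)) out[[tp]] <- sums[, tp]
  out$trajectory <- apply(sums, 1L, trajectory_label)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum (Mann-Whitney U) test with exact small-sample p
#'
#' Computes U with midranks for ties. For samples with both sizes at most
#' `exact_max`, the two-sided p-value is exact by full enumeration of all
#' group assignments of the observed ranks (valid under ties, unlike the
#' classical no-tie tables); larger samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Enumeration limit on each sample size (default 10).
#' @return List with `U` (statistic for `x`), `p_value`, `method`.
#' @export
ranksum_test <- function(x, y, exact_max = 10L) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n <= exact_max && m <= exact_max) {
    sel <- utils::combn(n + m, n)
    u_dist <- colSums(matrix(r[sel], nrow = n)) - n * (n + 1) / 2
    lo <- min(U, n * m - U); hi <- max(U, n * m - U)
    p <- mean(u_dist <= lo + 1e-9 | u_dist >= hi - 1e-9)
    return(list(U = U, p_value = min(1, p), method = "exact enumeration"))
  }
  mu <- n * m / 2
  ties <- table(r)
  N <- n + m
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 == 0) return(list(U = U, p_value = 1, method = "normal approximation"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-max(0, z))),
       method = "normal approximation")
}

#' Abundance-profile row clustering (optional report)
#'
#' Average-linkage clustering of contigs on 1 - Pearson correlation of
#' their TPM trajectories, the grouping conventionally used to order
#' abundance heatmap rows.
#'
#' @param table An `AbundanceTable` or TPM matrix with >= 3 rows.
#' @return An `hclust` object.
#' @export
abundance_row_clusters <- function(table) {
  m <- tpm_matrix(table)
  stopifnot(nrow(m) >= 3)
  d <- stats::as.dist(1 - stats::cor(t(m)))
  d[is.na(d)] <- 1
  stats::hclust(d, method = "average")
}
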
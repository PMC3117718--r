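#' Simulation parameters for the duplication null model
#'
#' The null model asks: if fragmentation were perfectly random, how
#' often would two reads start at the same genomic position on the same
#' strand by chance alone? Defaults reproduce the study conditions of a
#' whole-genome E. coli K12 Titanium run: a 4.6 Mb genome, 671,856 reads
#' of 500 bp drawn uniformly from both strands. A uniform random genome
#' stands in for the real one (the null depends only on its length, and
#' a random genome avoids repeat-family artifacts).
#'
#' @param genome_len genome length in bases (default 4,600,000).
#' @param n_reads number of reads to draw (default 671,856).
#' @param read_len read length in bases (default 500).
#' @param error_rate per-base substitution probability (default 0).
#' @param homopolymer_indel_rate per-homopolymer-run probability of a
#'   +/-1 length error, the dominant 454 error mode (default 0).
#' @param linker optional `list(id, seq)` used when building paired-end
#'   fixtures.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 4600000L, n_reads = 671856L,
                       read_len = 500L, error_rate = 0,
                       homopolymer_indel_rate = 0, linker = NULL) {
  stopifnot(read_len < genome_len, n_reads >= 1, error_rate >= 0,
            error_rate <= 1, homopolymer_indel_rate >= 0,
            homopolymer_indel_rate <= 1)
  structure(list(genome_len = as.integer(genome_len),
                 n_reads = as.integer(n_reads),
                 read_len = as.integer(read_len),
                 error_rate = error_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 linker = linker),
            class = "sim_config")
}

#' Generate a uniform random genome
#'
#' Seeded i.i.d. uniform sequence over `{A,C,G,T}`. Set the RNG seed
#' with [set.seed()] before calling for reproducibility.
#'
#' @param genome_len genome length, or a [sim_config()].
#' @return A single character string.
#' @export
random_genome <- function(genome_len) {
  if (inherits(genome_len, "sim_config")) genome_len <- genome_len$genome_len
  paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
        collapse = "")
}

# substitution errors: each base independently replaced by one of the
# three other bases with probability `rate`
mutate_substitutions <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# homopolymer +/-1 indels: each maximal run of identical bases is,
# with probability `rate`, lengthened or shortened by one base.
# Runs beginning within the first `protect_prefix` bases are left
# intact (co-start duplicates share their start by definition).
mutate_homopolymer_indels <- function(s, rate, protect_prefix = 0L) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  hit <- stats::runif(length(r$lengths)) < rate & starts > protect_prefix
  grow <- stats::runif(length(r$lengths)) < 0.5
  lens <- r$lengths
  lens[hit & grow] <- lens[hit & grow] + 1L
  lens[hit & !grow] <- pmax(lens[hit & !grow] - 1L, 0L)
  paste(rep(r$values, lens), collapse = "")
}

#' Simulate shotgun reads from a genome
#'
#' Read start positions are uniform over the valid range and strands
#' are uniform over +/-; minus-strand reads are reverse-complemented.
#' Substitution and homopolymer-indel errors are applied per the
#' configuration. The ground truth (start, strand) of every read is
#' returned for downstream evaluation: two error-free reads are exact
#' duplicates iff they share (start, strand).
#'
#' @param genome genome string from [random_genome()].
#' @param cfg a [sim_config()].
#' @param n_reads,read_len optional overrides of the configuration.
#' @return A list with `reads` (a `ReadSet` with ids `sim_1..sim_n`,
#'   constant quality 30) and `truth` (data frame `id`, `start`
#'   (1-based), `strand`).
#' @export
simulate_shotgun_reads <- function(genome, cfg = sim_config(),
                                   n_reads = cfg$n_reads,
                                   read_len = cfg$read_len) {
  glen <- nchar(genome)
  stopifnot(read_len <= glen)
  m0 <- glen - read_len + 1L
  starts <- sample.int(m0, n_reads, replace = TRUE)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(genome, starts, starts + read_len - 1L)
  minus <- strands == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  if (cfg$error_rate > 0)
    seqs <- vapply(seqs, mutate_substitutions, character(1),
                   rate = cfg$error_rate, USE.NAMES = FALSE)
  if (cfg$homopolymer_indel_rate > 0)
    seqs <- vapply(seqs, mutate_homopolymer_indels, character(1),
                   rate = cfg$homopolymer_indel_rate, USE.NAMES = FALSE)
  ids <- paste0("sim_", seq_len(n_reads))
  qual <- lapply(nchar(seqs), function(l) rep(30L, l))
  list(reads = read_set(ids, seqs, qual = qual, origin = "simulated"),
       truth = data.frame(id = ids, start = starts, strand = strands,
                          stringsAsFactors = FALSE))
}

#' Inject artificial duplicate clusters into a read set
#'
#' Emulates the 454 duplication artifact: chosen template reads are
#' copied with 454-style perturbations (homopolymer +/-1 indels outside
#' a protected read prefix, substitutions, and 3' truncations) and the
#' copies are appended with fresh ids. The intended clusters (template
#' plus its copies) are returned as ground truth.
#'
#' @param rs a `ReadSet` of template candidates.
#' @param sizes integer vector of intended cluster sizes (each >= 2);
#'   the first `length(sizes)` reads of `rs` serve as templates.
#' @param error_rate per-base substitution probability for copies.
#' @param homopolymer_indel_rate per-run indel probability for copies.
#' @param max_truncation maximum 3' truncation of a copy in bases
#'   (actual truncation uniform on `0..max_truncation`).
#' @param protect_prefix leading bases never perturbed (default 16,
#'   the duplicate-seeding prefix length: co-start duplicates share
#'   their start).
#' @return A list with `reads` (templates + copies appended after the
#'   originals) and `truth_clusters` (list of character vectors of ids).
#' @export
inject_duplicates <- function(rs, sizes, error_rate = 0,
                              homopolymer_indel_rate = 0,
                              max_truncation = 0L, protect_prefix = 16L) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 2))
  if (length(sizes) > length(rs))
    stop("more clusters requested than template reads available")
  copies_id <- character(0); copies_seq <- character(0)
  copies_qual <- list()
  truth <- vector("list", length(sizes))
  k <- 0L
  for (ci in seq_along(sizes)) {
    tpl_i <- ci
    members <- rs$id[tpl_i]
    for (j in seq_len(sizes[ci] - 1L)) {
      k <- k + 1L
      s <- rs$seq[tpl_i]
      if (max_truncation > 0) {
        tr <- sample.int(max_truncation + 1L, 1L) - 1L
        if (tr > 0) s <- substr(s, 1L, nchar(s) - tr)
      }
      if (error_rate > 0) {
        body <- mutate_substitutions(substr(s, protect_prefix + 1L, nchar(s)),
                                     error_rate)
        s <- paste0(substr(s, 1L, protect_prefix), body)
      }
      if (homopolymer_indel_rate > 0)
        s <- mutate_homopolymer_indels(s, homopolymer_indel_rate,
                                       protect_prefix)
      id <- paste0(rs$id[tpl_i], "_dup", j)
      copies_id <- c(copies_id, id)
      copies_seq <- c(copies_seq, s)
      copies_qual[[k]] <- rep(30L, nchar(s))
      members <- c(members, id)
    }
    truth[[ci]] <- members
  }
  copies <- read_set(copies_id, copies_seq,
                     qual = if (is.null(rs$qual)) NULL else copies_qual,
                     origin = rs$origin)
  list(reads = bind_read_sets(list(rs, copies)), truth_clusters = truth)
}

#' Run the random-fragmentation replication experiment
#'
#' Measures how much duplication pure chance produces: reads are drawn
#' uniformly (start, strand) from both strands of a genome and
#' clustered as duplicates. Error-free reads sharing (start, strand)
#' are exact co-start copies, so clustering reduces to exact grouping
#' on the (start, strand) key — a fast path that avoids materialising
#' all sequences. Its equivalence with the full alignment-based
#' [deduplicate()] path is verified on a read subsample at every run.
#'
#' Under this null the cluster-size distribution is Poisson-like with
#' rate `lambda = (n-1)/M`, `M = 2 * (genome_len - read_len + 1)`, and
#' the expected membership (replication) rate is `1 - exp(-lambda)`.
#'
#' @param cfg a [sim_config()] (error rates must be 0).
#' @param verify_n subsample size for the hash-vs-alignment
#'   equivalence check (default 10,000; 0 disables it).
#' @param dedup_cfg a [dedup_config()] for the verification subsample.
#' @return A list: `dup_membership_rate` (fraction of reads in clusters
#'   of size >= 2), `removal_rate`, `max_cluster_size`, `histogram`
#'   (cluster size -> count, sizes >= 1), `expected_membership_rate`
#'   (birthday closed form), `n_reads`, `verified` (logical).
#' @export
replication_experiment <- function(cfg = sim_config(), verify_n = 10000L,
                                   dedup_cfg = dedup_config()) {
  if (cfg$error_rate > 0 || cfg$homopolymer_indel_rate > 0)
    stop("the replication null model is defined for error-free reads")
  n <- cfg$n_reads
  m0 <- cfg$genome_len - cfg$read_len + 1L
  genome <- random_genome(cfg$genome_len)
  starts <- sample.int(m0, n, replace = TRUE)
  strands <- sample.int(2L, n, replace = TRUE)  # 1 = +, 2 = -
  key <- (starts - 1L) * 2L + strands
  counts <- tabulate(key, nbins = 2L * m0)
  sizes <- counts[counts > 0L]
  tab <- table(sizes)
  hist <- stats::setNames(as.integer(tab), names(tab))
  membership <- sum(sizes[sizes >= 2]) / n
  removal <- (n - length(sizes)) / n

  verified <- NA
  if (verify_n > 0) {
    vi <- if (n <= verify_n) seq_len(n)
          else sample.int(n, verify_n)
    seqs <- substring(genome, starts[vi], starts[vi] + cfg$read_len - 1L)
    minus <- strands[vi] == 2L
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    sub_rs <- read_set(paste0("v_", seq_along(vi)), seqs)
    dd <- deduplicate(sub_rs, dedup_cfg)
    align_part <- partition_labels(lapply(dd$clusters, `[[`, "member_ids"),
                                   sub_rs$id)
    hash_part <- as.integer(factor(key[vi]))
    verified <- same_partition(align_part, hash_part)
    if (!verified)
      warning("hash fast path disagreed with the alignment path ",
              "on the verification subsample")
  }

  lambda <- (n - 1) / (2 * m0)
  list(dup_membership_rate = membership,
       removal_rate = removal,
       max_cluster_size = max(sizes),
       histogram = hist,
       expected_membership_rate = 1 - exp(-lambda),
       n_reads = n,
       verified = verified)
}

# cluster list -> integer partition labels over `ids`
partition_labels <- function(cluster_ids, ids) {
  lab <- integer(length(ids))
  for (ci in seq_along(cluster_ids))
    lab[match(cluster_ids[[ci]], ids)] <- ci
  lab
}

# do two label vectors induce the same set partition?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
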
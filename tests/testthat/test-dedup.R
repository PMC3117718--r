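test_that("candidate pairs are exactly the shared-prefix pairs", {
  set.seed(21)
  pre <- rnd_seq(16)
  rs <- read_set(c("a", "b", "c"),
                 c(paste0(pre, rnd_seq(100)), paste0(pre, rnd_seq(80)),
                   paste0("T", substr(pre, 2, 16), rnd_seq(90))))
  pairs <- find_candidate_pairs(rs)
  expect_equal(nrow(pairs), 1)
  expect_setequal(as.vector(pairs), c("a", "b"))

  # distinct first bases -> nothing
  rs2 <- read_set(c("x", "y"), c(paste0("A", rnd_seq(60)),
                                 paste0("C", rnd_seq(60))))
  expect_equal(nrow(find_candidate_pairs(rs2)), 0)
  expect_equal(nrow(find_candidate_pairs(read_set(character(0),
                                                  character(0)))), 0)
})

test_that("seeded candidates match a brute-force all-pairs prefix scan", {
  set.seed(22)
  base <- replicate(100, rnd_seq(120))
  # 10 injected duplicate pairs: copy with errors strictly after base 16
  for (i in 1:10) base[100 - i + 1] <- with_subs(base[i], c(40, 80))
  rs <- read_set(sprintf("r%03d", 1:100), base)
  pairs <- find_candidate_pairs(rs)
  got <- sort(paste(pmin(pairs[, 1], pairs[, 2]),
                    pmax(pairs[, 1], pairs[, 2]), sep = "|"))
  want <- character(0)
  for (i in 1:99) for (j in (i + 1):100)
    if (substr(rs$seq[i], 1, 16) == substr(rs$seq[j], 1, 16))
      want <- c(want, paste(rs$id[i], rs$id[j], sep = "|"))
  expect_identical(got, sort(want))
  expect_true(length(want) >= 10)
})

test_that("co-start alignment scores match the unbanded DP oracle", {
  set.seed(23)
  a <- rnd_seq(200)
  expect_equal(score_co_start_alignment(a, a)$score, 200)
  expect_equal(score_co_start_alignment(a, a)$mismatches, 0)

  s90 <- rnd_seq(90)  # shorter than the threshold: can never be a duplicate
  expect_equal(score_co_start_alignment(s90, s90)$score, 90)

  b <- with_subs(a, c(30, 60, 90, 120, 150))
  h <- score_co_start_alignment(a, b)
  expect_equal(h$score, 185)  # 195 matches - 5 mismatches * 2
  expect_equal(h$mismatches, 5)

  # random perturbations: banded path equals the full-DP oracle
  for (rep in 1:20) {
    x <- rnd_seq(sample(120:300, 1))
    y <- x
    if (runif(1) < 0.7) y <- with_subs(y, sample(nchar(y), 3))
    if (runif(1) < 0.5) {  # one small indel
      p <- sample(nchar(y) - 1, 1)
      y <- paste0(substr(y, 1, p), "A", substr(y, p + 1, nchar(y)))
    }
    if (runif(1) < 0.5) y <- substr(y, 1, nchar(y) - sample(0:40, 1))
    expect_equal(score_co_start_alignment(x, y)$score,
                 pyroclean:::costart_score_full(x, y, 1L, -2L, -3L))
  }
})

test_that("equal-length co-start scores agree with an independent global aligner", {
  set.seed(24)
  submat <- matrix(-2L, 5, 5,
                   dimnames = list(c("A", "C", "G", "T", "N"),
                                   c("A", "C", "G", "T", "N")))
  diag(submat) <- 1L; submat["N", "N"] <- -2L
  for (rep in 1:10) {
    x <- rnd_seq(150)
    # interior substitutions only, so the free-tail option cannot win
    y <- with_subs(x, sample(10:130, sample(0:6, 1)))
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(x), Biostrings::DNAString(y), type = "global",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 3))
    expect_equal(score_co_start_alignment(x, y)$score, ref)
  }
})

test_that("edge criteria follow the strict score and length boundaries", {
  mk_hit <- function(score, len_a, len_b)
    structure(list(id_a = "a", id_b = "b", co_start = TRUE,
                   same_strand = TRUE, score = score, aligned_len = len_b,
                   mismatches = 0, gaps = 0, len_a = len_a, len_b = len_b),
              class = "alignment_hit")
  rs <- read_set(c("a", "b"), c(strrep("A", 10), strrep("C", 10)))
  cfg <- dedup_config()
  expect_equal(nrow(build_duplicate_graph(list(mk_hit(100, 400, 395)),
                                          rs, cfg)), 0)
  expect_equal(nrow(build_duplicate_graph(list(mk_hit(101, 400, 395)),
                                          rs, cfg)), 1)
  # length difference: 70 is out (not < 70), 69 is in
  expect_equal(nrow(build_duplicate_graph(list(mk_hit(150, 400, 330)),
                                          rs, cfg)), 0)
  expect_equal(nrow(build_duplicate_graph(list(mk_hit(150, 400, 331)),
                                          rs, cfg)), 1)
  # aggressive disregards length
  expect_equal(nrow(build_duplicate_graph(
    list(mk_hit(150, 400, 200)), rs, dedup_config(aggressive = TRUE))), 1)
})

test_that("clusters are connected components with the longest read kept", {
  rs <- read_set(c("A", "B", "C"),
                 c(strrep("G", 400), strrep("G", 450), strrep("G", 420)))
  cl <- extract_clusters(cbind(c("A", "B"), c("B", "C")), rs)
  expect_equal(length(cl), 1)
  expect_setequal(cl[[1]]$member_ids, c("A", "B", "C"))
  expect_equal(cl[[1]]$representative_id, "B")

  rs5 <- read_set(letters[1:5], replicate(5, rnd_seq(60)))
  cl5 <- extract_clusters(matrix(character(0), ncol = 2), rs5)
  expect_equal(length(cl5), 5)
  expect_equal(vapply(cl5, `[[`, character(1), "representative_id"),
               letters[1:5])

  # equal lengths: representative is the lexicographically smallest id
  rs2 <- read_set(c("z9", "a1"), c(strrep("A", 50), strrep("A", 50)))
  cl2 <- extract_clusters(cbind("z9", "a1"), rs2)
  expect_equal(cl2[[1]]$representative_id, "a1")
})

test_that("component extraction agrees with brute-force reachability", {
  set.seed(26)
  for (rep in 1:5) {
    n <- sample(20:120, 1)
    rs <- read_set(sprintf("v%03d", 1:n),
                   vapply(rep(30, n), rnd_seq, character(1)))
    m <- sample(0:(2 * n), 1)
    eidx <- cbind(sample(n, m, TRUE), sample(n, m, TRUE))
    eidx <- eidx[eidx[, 1] != eidx[, 2], , drop = FALSE]
    edges <- cbind(rs$id[eidx[, 1]], rs$id[eidx[, 2]])
    cl <- extract_clusters(edges, rs)
    lab_pkg <- integer(n)
    for (ci in seq_along(cl)) lab_pkg[match(cl[[ci]]$member_ids, rs$id)] <- ci
    lab_ora <- warshall_components(n, eidx)
    expect_identical(as.integer(factor(lab_pkg, unique(lab_pkg))),
                     as.integer(factor(lab_ora, unique(lab_ora))))
  }
})

test_that("deduplicate keeps one representative per cluster, in input order", {
  set.seed(27)
  tpl <- rnd_seq(300)
  rs <- read_set(c("d1", "u1", "d2", "u2", "d3"),
                 c(tpl, rnd_seq(250), tpl, rnd_seq(260), tpl))
  dd <- deduplicate(rs)
  expect_equal(length(dd$kept), 3)
  expect_equal(nrow(dd$removed), 2)
  expect_equal(dd$kept$id, c("d1", "u1", "u2"))
  # partition: kept + removed = input, disjoint
  expect_setequal(c(dd$kept$id, dd$removed$id), rs$id)
  expect_equal(sum(vapply(dd$clusters, function(x) length(x$member_ids),
                          integer(1))), length(rs))

  empty <- deduplicate(read_set(character(0), character(0)))
  expect_equal(length(empty$kept), 0)
  expect_equal(nrow(empty$removed), 0)
})

test_that("deduplication is idempotent and deterministic", {
  set.seed(28)
  rs <- simulate_shotgun_reads(random_genome(20000),
                               sim_config(genome_len = 20000,
                                          n_reads = 60, read_len = 150))$reads
  inj <- inject_duplicates(rs, sizes = c(3, 2, 2))
  dd1 <- deduplicate(inj$reads)
  dd2 <- deduplicate(dd1$kept)
  expect_equal(nrow(dd2$removed), 0)
  expect_identical(dd2$kept$id, dd1$kept$id)
  dd3 <- deduplicate(inj$reads)
  expect_identical(dd3$kept$seq, dd1$kept$seq)
  expect_identical(dd3$removed, dd1$removed)
})

test_that("loosening any gate never increases the number of kept reads", {
  set.seed(29)
  rs <- simulate_shotgun_reads(random_genome(30000),
                               sim_config(genome_len = 30000,
                                          n_reads = 50, read_len = 200))$reads
  inj <- inject_duplicates(rs, sizes = c(4, 3, 2, 2),
                           error_rate = 0.01, max_truncation = 100)
  base_kept <- length(deduplicate(inj$reads)$kept)
  lower_score <- length(deduplicate(inj$reads,
                                    dedup_config(score_threshold = 50))$kept)
  wider_len <- length(deduplicate(inj$reads,
                                  dedup_config(length_diff_max = 150))$kept)
  aggr <- length(deduplicate(inj$reads,
                             dedup_config(aggressive = TRUE))$kept)
  expect_lte(lower_score, base_kept)
  expect_lte(wider_len, base_kept)
  expect_lte(aggr, base_kept)
})

test_that("truncation interacts with the length gate at the 70-base boundary", {
  set.seed(30)
  tpl <- rnd_seq(500)
  mk <- function(trunc) read_set(c("t", "c"),
                                 c(tpl, substr(tpl, 1, 500 - trunc)))
  dd69 <- deduplicate(mk(69))
  expect_equal(length(dd69$kept), 1)
  dd71 <- deduplicate(mk(71))
  expect_equal(length(dd71$kept), 2)
  dd71a <- deduplicate(mk(71), dedup_config(aggressive = TRUE))
  expect_equal(length(dd71a$kept), 1)
})

test_that("duplication profile arithmetic is conserved", {
  mk_cl <- function(ids) list(member_ids = ids, representative_id = ids[1])
  prof <- duplication_profile(list(mk_cl("a"), mk_cl("b"),
                                   mk_cl(c("c", "d")),
                                   mk_cl(c("e", "f", "g"))))
  expect_equal(prof$histogram, c(`1` = 2L, `2` = 1L, `3` = 1L))
  expect_equal(prof$dup_membership_rate, 5 / 7)
  expect_equal(prof$removal_rate, 3 / 7)
  expect_equal(sum(as.integer(names(prof$histogram)) * prof$histogram), 7)

  singletons <- duplication_profile(list(mk_cl("a"), mk_cl("b")))
  expect_equal(singletons$dup_membership_rate, 0)
  expect_equal(singletons$removal_rate, 0)

  one_pair <- duplication_profile(list(mk_cl(c("a", "b"))))
  expect_equal(one_pair$dup_membership_rate, 1.0)
  expect_equal(one_pair$removal_rate, 0.5)
})
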
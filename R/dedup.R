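#' Configuration for artificial-duplicate removal
#'
#' Artificial duplicates are multiple reads emitted for a single DNA
#' fragment: they start at the same position on the same strand and are
#' near-identical, apart from homopolymer indels, substitutions and
#' different stop positions. Detection compares read starts: two reads
#' are joined when a co-start alignment (anchored at the first base of
#' both) scores above `score_threshold` and, unless `aggressive`, their
#' length difference is strictly below `length_diff_max` bases.
#'
#' @param score_threshold alignment score a pair must strictly exceed to
#'   be joined (default 100; with unit match reward this demands roughly
#'   100+ matching bases, so reads shorter than 101 bases can never be
#'   flagged as duplicates at defaults).
#' @param length_diff_max length-difference gate in bases (default 70);
#'   a pair is joined only if `|len_a - len_b|` is strictly below it.
#' @param aggressive if `TRUE`, join pairs disregarding read length.
#' @param seed_k prefix k-mer length used for candidate generation
#'   (default 16, minimum 8): only pairs sharing their first `seed_k`
#'   bases are aligned. An error within the first `seed_k` bases makes a
#'   pair invisible.
#' @param match_reward,mismatch_penalty,gap_penalty alignment weights
#'   (+1, -2, -3 per gapped base) chosen so the score threshold retains
#'   its meaning of ~100 matching bases.
#' @param band half-width of the alignment band (default 8); duplicates
#'   differ by few indels.
#' @return A list of class `dedup_config`.
#' @export
dedup_config <- function(score_threshold = 100L, length_diff_max = 70L,
                         aggressive = FALSE, seed_k = 16L,
                         match_reward = 1L, mismatch_penalty = -2L,
                         gap_penalty = -3L, band = 8L) {
  stopifnot(score_threshold > 0, length_diff_max >= 0, seed_k >= 8,
            match_reward > 0, mismatch_penalty < 0, gap_penalty < 0,
            band >= 1)
  structure(list(score_threshold = as.integer(score_threshold),
                 length_diff_max = as.integer(length_diff_max),
                 aggressive = isTRUE(aggressive),
                 seed_k = as.integer(seed_k),
                 match_reward = as.integer(match_reward),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_penalty = as.integer(gap_penalty),
                 band = as.integer(band)),
            class = "dedup_config")
}

#' Candidate duplicate pairs by shared prefix k-mer
#'
#' Returns every unordered pair of distinct reads whose first `seed_k`
#' bases are identical (forward strand). This is a superset of all pairs
#' any same-strand co-start alignment with an error-free first `seed_k`
#' bases could join. Reads shorter than `seed_k` are never candidates.
#'
#' @param rs a `ReadSet`.
#' @param cfg a [dedup_config()].
#' @return A two-column character matrix of read id pairs (`id_a`,
#'   `id_b`), zero rows if none.
#' @export
find_candidate_pairs <- function(rs, cfg = dedup_config()) {
  empty <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("id_a", "id_b")))
  if (length(rs) < 2) return(empty)
  lens <- read_lengths(rs)
  ok <- lens >= cfg$seed_k
  if (any(!ok))
    message(sum(!ok), " read(s) shorter than seed_k=", cfg$seed_k,
            " excluded from duplicate seeding")
  idx <- which(ok)
  if (length(idx) < 2) return(empty)
  pref <- substr(rs$seq[idx], 1L, cfg$seed_k)
  groups <- split(idx, pref)
  groups <- groups[lengths(groups) > 1]
  if (length(groups) == 0) return(empty)
  pairs <- do.call(rbind, lapply(groups, function(g) t(utils::combn(g, 2))))
  cbind(id_a = rs$id[pairs[, 1]], id_b = rs$id[pairs[, 2]])
}

#' Score the co-start alignment of two reads
#'
#' Banded global-prefix alignment anchored at offset 0 of both reads,
#' extending to the end of the shorter read (the longer read's tail is
#' free). Both co-start and same-strand hold by construction: seeding is
#' forward-only, so reverse-complement pairs are never compared.
#'
#' @param a,b single-read `ReadSet`s or plain character sequences.
#' @param cfg a [dedup_config()].
#' @param id_a,id_b identifiers recorded in the hit (defaults taken from
#'   `a`/`b` when they are `ReadSet`s).
#' @return A list of class `alignment_hit` with fields `id_a`, `id_b`,
#'   `co_start`, `same_strand`, `score`, `aligned_len`, `mismatches`,
#'   `gaps`, `len_a`, `len_b`.
#' @export
score_co_start_alignment <- function(a, b, cfg = dedup_config(),
                                     id_a = NULL, id_b = NULL) {
  if (inherits(a, "ReadSet")) { if (is.null(id_a)) id_a <- a$id[1]; a <- a$seq[1] }
  if (inherits(b, "ReadSet")) { if (is.null(id_b)) id_b <- b$id[1]; b <- b$seq[1] }
  if (!is.null(id_a) && identical(id_a, id_b))
    stop("cannot align a read against itself")
  al <- costart_align_banded(a, b, cfg$match_reward, cfg$mismatch_penalty,
                             cfg$gap_penalty, cfg$band)
  structure(list(id_a = id_a %||% "a", id_b = id_b %||% "b",
                 co_start = TRUE, same_strand = TRUE,
                 score = al$score, aligned_len = al$aligned_len,
                 mismatches = al$mismatches, gaps = al$gaps,
                 len_a = nchar(a), len_b = nchar(b)),
            class = "alignment_hit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build the duplicate similarity graph
#'
#' An edge joins a scored pair iff the co-start, same-strand alignment
#' score is strictly greater than `score_threshold` and (unless
#' `aggressive`) the read length difference is strictly lower than
#' `length_diff_max`.
#'
#' @param hits list of `alignment_hit` objects.
#' @param rs the `ReadSet` the hits refer to.
#' @param cfg a [dedup_config()].
#' @return A two-column character matrix of edges (read id pairs).
#' @export
build_duplicate_graph <- function(hits, rs, cfg = dedup_config()) {
  keep <- vapply(hits, function(h) {
    if (!all(c(h$id_a, h$id_b) %in% rs$id))
      stop("alignment hit references unknown read id")
    isTRUE(h$co_start) && isTRUE(h$same_strand) &&
      !is.na(h$score) && h$score > cfg$score_threshold &&
      (cfg$aggressive || abs(h$len_a - h$len_b) < cfg$length_diff_max)
  }, logical(1))
  hits <- hits[keep]
  m <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("id_a", "id_b")))
  if (length(hits) > 0)
    m <- cbind(id_a = vapply(hits, `[[`, character(1), "id_a"),
               id_b = vapply(hits, `[[`, character(1), "id_b"))
  m
}

#' Extract duplication clusters
#'
#' Connected components of the undirected graph whose vertices are all
#' reads of the set (edge-less reads form singleton clusters). The
#' representative of each cluster is its longest member; ties are broken
#' by the lexicographically smallest id, so the output is deterministic.
#'
#' @param edges two-column matrix of read id pairs.
#' @param rs the `ReadSet` (supplies the vertex set and read lengths).
#' @return A list of clusters, each `list(member_ids, representative_id)`,
#'   ordered by first appearance of a member in `rs`. Clusters partition
#'   the read set.
#' @export
extract_clusters <- function(edges, rs) {
  g <- igraph::make_empty_graph(n = length(rs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rs$id)
  if (NROW(edges) > 0)
    g <- igraph::add_edges(g, t(matrix(match(edges, rs$id), ncol = 2)))
  comp <- igraph::components(g)$membership
  lens <- read_lengths(rs)
  clusters <- lapply(split(seq_along(comp), comp), function(members) {
    ids <- rs$id[members]
    best <- members[order(-lens[members], rs$id[members])][1]
    list(member_ids = ids, representative_id = rs$id[best])
  })
  # order clusters by first member appearance in the input
  first <- vapply(clusters, function(cl) min(match(cl$member_ids, rs$id)),
                  numeric(1))
  unname(clusters[order(first)])
}

#' Remove artificial duplicate reads
#'
#' Full duplicate-removal pipeline: prefix-seeded candidate generation,
#' banded co-start scoring, edge filtering, connected-component
#' clustering, and selection of the longest read per cluster.
#'
#' @param rs a `ReadSet`.
#' @param cfg a [dedup_config()].
#' @return A list with `kept` (a `ReadSet` of cluster representatives, in
#'   original input order), `removed` (data frame of discarded read ids
#'   and their cluster id), and `clusters` (see [extract_clusters()]).
#' @export
deduplicate <- function(rs, cfg = dedup_config()) {
  if (length(rs) == 0)
    return(list(kept = rs,
                removed = data.frame(id = character(0),
                                     cluster_id = integer(0)),
                clusters = list()))
  pairs <- find_candidate_pairs(rs, cfg)
  hits <- lapply(seq_len(NROW(pairs)), function(i) {
    ia <- match(pairs[i, 1], rs$id); ib <- match(pairs[i, 2], rs$id)
    score_co_start_alignment(rs$seq[ia], rs$seq[ib], cfg,
                             id_a = pairs[i, 1], id_b = pairs[i, 2])
  })
  edges <- build_duplicate_graph(hits, rs, cfg)
  clusters <- extract_clusters(edges, rs)
  rep_ids <- vapply(clusters, `[[`, character(1), "representative_id")
  keep_idx <- sort(match(rep_ids, rs$id))
  cluster_of <- integer(length(rs))
  for (ci in seq_along(clusters))
    cluster_of[match(clusters[[ci]]$member_ids, rs$id)] <- ci
  removed_idx <- setdiff(seq_along(rs$id), keep_idx)
  list(kept = rs[keep_idx],
       removed = data.frame(id = rs$id[removed_idx],
                            cluster_id = cluster_of[removed_idx],
                            stringsAsFactors = FALSE),
       clusters = clusters)
}

#' Duplication profile of a clustering
#'
#' @param clusters list of clusters from [extract_clusters()].
#' @return A list with `histogram` (named integer vector mapping cluster
#'   size to number of clusters), `dup_membership_rate` (fraction of
#'   reads lying in clusters of size >= 2 — the replication rate),
#'   `removal_rate` (fraction of reads discarded, `(N - #clusters)/N`),
#'   and `max_cluster_size`.
#' @export
duplication_profile <- function(clusters) {
  sizes <- vapply(clusters, function(cl) length(cl$member_ids), integer(1))
  n <- sum(sizes)
  tab <- table(sizes)
  hist <- stats::setNames(as.integer(tab), names(tab))
  list(histogram = hist,
       dup_membership_rate = if (n == 0) 0 else sum(sizes[sizes >= 2]) / n,
       removal_rate = if (n == 0) 0 else (n - length(sizes)) / n,
       max_cluster_size = if (n == 0) 0L else max(sizes))
}
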
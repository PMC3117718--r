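# independent oracles for the duplicate-clustering pipeline

# plain union-find over 1..n
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i); rj <- uf_find(p, j)
  if (ri != rj) p[ri] <- rj
  p
}

# brute-force duplicate clustering: all read pairs, unbanded full-DP
# co-start score, identical edge criteria, union-find components.
brute_force_clusters <- function(rs, cfg = dedup_config()) {
  n <- length(rs)
  lens <- read_lengths(rs)
  p <- uf_new(n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      sc <- pyroclean:::costart_score_full(rs$seq[i], rs$seq[j],
                                           cfg$match_reward,
                                           cfg$mismatch_penalty,
                                           cfg$gap_penalty)
      if (sc > cfg$score_threshold &&
          (cfg$aggressive || abs(lens[i] - lens[j]) < cfg$length_diff_max))
        p <- uf_union(p, i, j)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(p, i), integer(1))
  unname(split(rs$id, roots))
}

# canonical form of a clustering for comparison
canon_clusters <- function(cluster_ids) {
  cl <- lapply(cluster_ids, sort)
  cl[order(vapply(cl, `[[`, character(1), 1))]
}

# Floyd-Warshall-style boolean reachability for component extraction
warshall_components <- function(n, edges_idx) {
  reach <- diag(TRUE, n)
  if (NROW(edges_idx) > 0) for (r in seq_len(NROW(edges_idx))) {
    reach[edges_idx[r, 1], edges_idx[r, 2]] <- TRUE
    reach[edges_idx[r, 2], edges_idx[r, 1]] <- TRUE
  }
  for (k in seq_len(n))
    reach <- reach | (reach[, k] %o% reach[k, ])
  labels <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) if (labels[i] == 0L) {
    nxt <- nxt + 1L
    labels[which(reach[i, ])] <- nxt
  }
  labels
}

# duplicate-pair set implied by a clustering (sorted "a|b" strings)
cluster_pairs <- function(cluster_ids) {
  out <- unlist(lapply(cluster_ids, function(ids) {
    if (length(ids) < 2) return(character(0))
    ids <- sort(ids)
    cb <- utils::combn(ids, 2)
    paste(cb[1, ], cb[2, ], sep = "|")
  }))
  sort(out)
}
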
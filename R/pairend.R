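#' Configuration for paired-end linker cleaning
#'
#' A 454 paired-end read is (end A) + linker + (end B) of a circularised
#' fragment; splitting it at the linker yields the mate pair. These
#' thresholds drive the decision tree of [classify_pairend()].
#'
#' @param min_end_len minimum usable flank length in bases (default 50):
#'   a flank shorter than this is too short to bridge contigs.
#' @param full_mismatch_max maximum mismatches + gapped bases for a
#'   linker hit to count as the entire linker (default 2).
#' @param partial_min_completeness fraction of the linker that must be
#'   covered for a hit to be reported at all (default 0.5); weaker hits
#'   are treated as noise.
#' @param end_margin distance in bases from a read end within which a
#'   partial linker hit counts as terminal (default 5).
#' @return A list of class `pairend_config`.
#' @export
pairend_config <- function(min_end_len = 50L, full_mismatch_max = 2L,
                           partial_min_completeness = 0.5, end_margin = 5L) {
  stopifnot(min_end_len >= 0, full_mismatch_max >= 0,
            partial_min_completeness > 0, partial_min_completeness <= 1,
            end_margin >= 0)
  structure(list(min_end_len = as.integer(min_end_len),
                 full_mismatch_max = as.integer(full_mismatch_max),
                 partial_min_completeness = partial_min_completeness,
                 end_margin = as.integer(end_margin)),
            class = "pairend_config")
}

#' Load linker sequences from a FASTA file
#'
#' The Roche chemistries use different linkers (one for GS FLX, two for
#' Titanium); they are supplied by the user. An example file ships at
#' `system.file("extdata", "linkers_example.fasta", package = "pyroclean")`
#' — verify its sequences against your chemistry before use.
#'
#' @param path FASTA file of linker sequences.
#' @return A list of linkers, each `list(id, seq)`.
#' @export
load_linkers <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0) stop("no linker sequences in ", path)
  lapply(seq_along(x), function(i)
    list(id = sub("\\s.*$", "", names(x)[i]),
         seq = toupper(as.character(x[[i]]))))
}

# local alignment scoring for linker search: +1/-2/-3 per gapped base;
# N never matches
linker_submat <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-2L, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 1L
  m["N", "N"] <- -2L
  m
}

# best local hit of any linker (either strand) inside read_seq[lo..hi]
# (1-based inclusive); returns NULL or a linker_match with read coords
best_local_hit <- function(read_seq, lo, hi, linkers, submat) {
  if (hi - lo + 1 < 4) return(NULL)
  region <- Biostrings::DNAString(substr(read_seq, lo, hi))
  best <- NULL
  for (lk in linkers) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") lk$seq else revcomp(lk$seq)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(pat), region, type = "local",
        substitutionMatrix = submat, gapOpening = 0, gapExtension = 3)
      sc <- Biostrings::score(al)
      if (sc <= 0) next
      pspan <- Biostrings::end(Biostrings::pattern(al)) -
        Biostrings::start(Biostrings::pattern(al)) + 1L
      hit <- list(
        linker_id = lk$id,
        start = lo - 1L + Biostrings::start(Biostrings::subject(al)) - 1L,
        end = lo - 1L + Biostrings::end(Biostrings::subject(al)),
        strand = strand,
        matches = Biostrings::nmatch(al),
        mismatches = Biostrings::nmismatch(al),
        gapped_bases = sum(Biostrings::width(Biostrings::insertion(al)[[1]])) +
          sum(Biostrings::width(Biostrings::deletion(al)[[1]])),
        completeness = pspan / nchar(lk$seq),
        score = sc)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && hit$start < best$start))
        best <- hit
    }
  }
  best
}

#' Locate linker occurrences inside a read
#'
#' Local similarity search (Smith-Waterman, match +1, mismatch -2, gap
#' -3 per base) of every linker, on both strands, against the read.
#' Hits covering less than `partial_min_completeness` of the linker are
#' discarded as noise. Multiple hits are reported non-overlapping,
#' greedily by score (the best hit is taken, then the flanking regions
#' are searched recursively), and returned sorted by read position.
#'
#' Match intervals are 0-based half-open `[start, end)` on the read.
#'
#' @param r a single-read `ReadSet` or a plain character sequence.
#' @param linkers list of linkers from [load_linkers()].
#' @param cfg a [pairend_config()].
#' @return A list of `linker_match` records: `linker_id`, `start`, `end`,
#'   `strand`, `matches`, `mismatches`, `gapped_bases`, `completeness`,
#'   `score`.
#' @export
find_linker_matches <- function(r, linkers, cfg = pairend_config()) {
  seq <- if (inherits(r, "ReadSet")) r$seq[1] else r
  submat <- linker_submat()
  hits <- list()
  recurse <- function(lo, hi) {
    h <- best_local_hit(seq, lo, hi, linkers, submat)
    if (is.null(h) || h$completeness < cfg$partial_min_completeness) return()
    hits[[length(hits) + 1]] <<- h
    recurse(lo, h$start)        # [lo, start] 1-based: bases before the hit
    recurse(h$end + 1L, hi)
  }
  recurse(1L, nchar(seq))
  if (length(hits) == 0) return(list())
  hits[order(vapply(hits, `[[`, numeric(1), "start"))]
}

#' Classify a read by its linker content
#'
#' The paired-end decision tree. With the read's linker matches in hand,
#' the read is assigned one of seven cases:
#' \describe{
#'   \item{a}{no linker: retained whole as a single read (`SINGLE_WHOLE`).}
#'   \item{b}{two or more linker hits: discarded (`DISCARD`).}
#'   \item{c}{one partial hit (incomplete linker span, or more than
#'     `full_mismatch_max` mismatches+gaps) terminal within `end_margin`
#'     of a read end: linker span removed, longest remainder kept
#'     (`SINGLE_CLIPPED`).}
#'   \item{d}{one partial hit, internal: discarded.}
#'   \item{e}{one full hit with both flanks at least `min_end_len`:
#'     split into a validated mate pair (`PAIR`).}
#'   \item{f}{one full hit with neither flank long enough: discarded.}
#'   \item{g}{one full hit with exactly one flank long enough: that
#'     flank kept as a single read (`SINGLE_CLIPPED`).}
#' }
#'
#' @param r a single-read `ReadSet` or character sequence.
#' @param matches output of [find_linker_matches()] for `r`.
#' @param cfg a [pairend_config()].
#' @return A list of class `pairend_decision`: `case_label` (a-g),
#'   `action` (`SINGLE_WHOLE`, `DISCARD`, `SINGLE_CLIPPED`, `PAIR`),
#'   and `intervals` (0-based half-open kept intervals: none for
#'   `DISCARD`, one for the single cases, two for `PAIR`).
#' @export
classify_pairend <- function(r, matches, cfg = pairend_config()) {
  seq <- if (inherits(r, "ReadSet")) r$seq[1] else r
  len <- nchar(seq)
  bad <- vapply(matches, function(m) m$start < 0 || m$end > len ||
                  m$start >= m$end, logical(1))
  if (any(bad)) stop("linker match outside the read")
  decision <- function(case_label, action, intervals = list())
    structure(list(case_label = case_label, action = action,
                   intervals = intervals), class = "pairend_decision")

  if (length(matches) == 0) return(decision("a", "SINGLE_WHOLE",
                                            list(c(0L, len))))
  if (length(matches) >= 2) return(decision("b", "DISCARD"))
  m <- matches[[1]]
  left <- c(0L, m$start)               # flank before the linker
  right <- c(m$end, len)               # flank after the linker
  left_len <- m$start
  right_len <- len - m$end
  full <- (m$mismatches + m$gapped_bases) <= cfg$full_mismatch_max &&
    m$completeness >= 1
  if (!full) {
    terminal <- m$start <= cfg$end_margin || (len - m$end) <= cfg$end_margin
    if (!terminal) return(decision("d", "DISCARD"))
    keep <- if (left_len >= right_len) left else right
    return(decision("c", "SINGLE_CLIPPED", list(keep)))
  }
  ok_left <- left_len >= cfg$min_end_len
  ok_right <- right_len >= cfg$min_end_len
  if (ok_left && ok_right) return(decision("e", "PAIR", list(left, right)))
  if (ok_left || ok_right)
    return(decision("g", "SINGLE_CLIPPED", list(if (ok_left) left else right)))
  decision("f", "DISCARD")
}

#' Split a read according to its paired-end decision
#'
#' @param r a single-read `ReadSet` (qualities, if present, are sliced
#'   in parallel with the sequence).
#' @param d a `pairend_decision` produced for `r`.
#' @return A `ReadSet` of 0 (discard), 1 (single) or 2 (pair) reads.
#'   Mates are named `<id>/1` (flank left of the linker in read
#'   orientation) and `<id>/2` (right flank).
#' @export
split_pairend <- function(r, d) {
  stopifnot(inherits(r, "ReadSet"), length(r) == 1,
            inherits(d, "pairend_decision"))
  slice <- function(iv, new_id) {
    s <- substr(r$seq[1], iv[1] + 1L, iv[2])
    q <- if (is.null(r$qual)) NULL else list(r$qual[[1]][(iv[1] + 1L):iv[2]])
    read_set(new_id, s, qual = q, origin = r$origin,
             format_of_origin = r$format_of_origin)
  }
  switch(d$action,
    DISCARD = r[integer(0)],
    SINGLE_WHOLE = r,
    SINGLE_CLIPPED = slice(d$intervals[[1]], r$id[1]),
    PAIR = bind_read_sets(list(slice(d$intervals[[1]], paste0(r$id[1], "/1")),
                               slice(d$intervals[[2]], paste0(r$id[1], "/2"))))
  )
}
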
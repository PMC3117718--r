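#' Construct a set of sequencing reads
#'
#' A `ReadSet` is the uniform in-memory collection every cleaning step
#' operates on: an ordered set of reads, each with an identifier, a DNA
#' sequence over `{A,C,G,T,N}` and (optionally) per-base Phred qualities.
#' Iteration order is the input-file order; downstream tie-breaking
#' (e.g. which duplicate representative is written first) depends on it.
#'
#' Sequences are uppercased on ingest; any character outside `{A,C,G,T,N}`
#' (including IUPAC ambiguity codes) is mapped to `N` with a warning, so
#' that every filter sees a fixed five-letter alphabet.
#'
#' @param id character vector of unique read identifiers.
#' @param seq character vector of DNA sequences, same length as `id`.
#' @param qual optional list of integer vectors of Phred-scaled base
#'   qualities (0-93), one per read, each of length `nchar(seq)`; or
#'   `NULL` when qualities are absent.
#' @param origin optional character scalar naming the source (file path,
#'   or a label such as `"simulated"`).
#' @param format_of_origin one of `"fastq"`, `"fasta"`, `"sff"` or `NA`.
#' @return An object of class `ReadSet`.
#' @export
read_set <- function(id, seq, qual = NULL, origin = NA_character_,
                     format_of_origin = NA_character_) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq))
    stop("`id` and `seq` must have the same length")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate read id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    warning(sum(bad), " read(s) contained characters outside {A,C,G,T,N}; ",
            "mapped to N")
    seq[bad] <- gsub("[^ACGTN]", "N", seq[bad])
  }
  if (!is.null(qual)) {
    if (length(qual) != length(id))
      stop("`qual` must have one entry per read")
    qual <- lapply(qual, as.integer)
    lens_ok <- vapply(seq_along(qual),
                      function(i) length(qual[[i]]) == nchar(seq[i]), logical(1))
    if (!all(lens_ok))
      stop("quality length differs from sequence length for read(s): ",
           paste(utils::head(id[!lens_ok], 5), collapse = ", "))
    rng_ok <- vapply(qual, function(q) all(q >= 0L & q <= 93L), logical(1))
    if (!all(rng_ok))
      stop("Phred qualities must be in [0, 93]")
  }
  structure(
    list(id = id, seq = seq, qual = qual, origin = origin,
         format_of_origin = format_of_origin),
    class = "ReadSet"
  )
}

#' @export
length.ReadSet <- function(x) length(x$id)

#' Subset a ReadSet
#'
#' @param x a `ReadSet`.
#' @param i index vector (integer, logical, or read ids).
#' @param ... unused.
#' @return A `ReadSet` containing the selected reads, in the selected order.
#' @export
`[.ReadSet` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  read_set(x$id[i], x$seq[i],
           qual = if (is.null(x$qual)) NULL else x$qual[i],
           origin = x$origin, format_of_origin = x$format_of_origin)
}

#' @export
print.ReadSet <- function(x, ...) {
  n <- length(x)
  cat("ReadSet of", n, "read(s)")
  if (!is.na(x$format_of_origin)) cat(" [", x$format_of_origin, "]", sep = "")
  cat("\n")
  if (n > 0) {
    lens <- nchar(x$seq)
    cat("  lengths: min", min(lens), "/ median", stats::median(lens),
        "/ max", max(lens), "\n")
    cat("  qualities:", if (is.null(x$qual)) "absent" else "present", "\n")
    show <- utils::head(seq_len(n), 3)
    for (i in show)
      cat("  ", x$id[i], " (", lens[i], " bp)\n", sep = "")
    if (n > 3) cat("  ...\n")
  }
  invisible(x)
}

#' Read lengths of a ReadSet
#' @param rs a `ReadSet`.
#' @return Integer vector of sequence lengths, in read order.
#' @export
read_lengths <- function(rs) nchar(rs$seq)

#' Concatenate ReadSets
#' @param rs_list list of `ReadSet` objects.
#' @return A single `ReadSet`; ids must remain unique across inputs.
#' @export
bind_read_sets <- function(rs_list) {
  rs_list <- rs_list[vapply(rs_list, length, integer(1)) > 0]
  if (length(rs_list) == 0) return(read_set(character(0), character(0)))
  has_q <- vapply(rs_list, function(r) !is.null(r$qual), logical(1))
  qual <- if (all(has_q)) do.call(c, lapply(rs_list, `[[`, "qual")) else NULL
  read_set(unlist(lapply(rs_list, `[[`, "id")),
           unlist(lapply(rs_list, `[[`, "seq")),
           qual = qual,
           origin = rs_list[[1]]$origin,
           format_of_origin = rs_list[[1]]$format_of_origin)
}

# reverse complement over {A,C,G,T,N}; vectorised
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
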
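#' Load sequencing reads from FASTQ, FASTA or SFF
#'
#' Materialises every record of a read file as a [read_set()]. FASTQ must
#' be Sanger/Phred+33. For FASTA, a quality sidecar file (`X.qual` next to
#' `X.fasta`, space-separated integers in FASTA-like records — the legacy
#' 454 convention) is loaded automatically when present. SFF v1 files are
#' parsed natively; the stored clip points (quality and adapter, 1-based
#' inclusive in the file) are converted to a 0-based half-open interval
#' using `max(left clips, 1) - 1` and the smallest positive right clip,
#' and the returned sequence/qualities are the clipped region. Flowgram
#' values are parsed and discarded.
#'
#' @param path path to the input file.
#' @param format `"fastq"`, `"fasta"`, `"sff"`, or `"auto"` (default).
#'   Auto-detection looks at magic bytes: `.sff` (0x2E736666) for SFF,
#'   then the first character (`@` FASTQ, `>` FASTA).
#' @return A `ReadSet`; reads appear in file order.
#' @export
load_reads <- function(path, format = c("auto", "fastq", "fasta", "sff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- detect_format(path)
  rs <- switch(format,
    fastq = load_fastq(path),
    fasta = load_fasta(path),
    sff   = load_sff(path)
  )
  rs$origin <- path
  rs$format_of_origin <- format
  rs
}

detect_format <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) == 4 && identical(magic, as.raw(c(0x2E, 0x73, 0x66, 0x66))))
    return("sff")
  first <- rawToChar(magic[1])
  if (first == "@") return("fastq")
  if (first == ">") return("fasta")
  stop("cannot detect format of ", path,
       " (not SFF magic, '@' or '>'); pass `format` explicitly")
}

load_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  quals <- S4Vectors::mcols(x)$qualities
  ids <- sub("\\s.*$", "", names(x))
  sw <- Biostrings::width(x)
  qw <- Biostrings::width(quals)
  if (any(sw != qw)) {
    bad <- which(sw != qw)[1]
    stop("malformed FASTQ record '", ids[bad], "': sequence length ", sw[bad],
         " != quality length ", qw[bad])
  }
  # a too-short quality line comes back nul-padded; decode per record
  qs <- tryCatch(as.character(quals), error = function(e) NULL)
  if (is.null(qs)) {
    for (i in seq_along(quals)) {
      ok <- tryCatch({ as.character(quals[i]); TRUE },
                     error = function(e) FALSE)
      if (!ok) stop("malformed FASTQ record '", ids[i],
                    "': corrupt quality line")
    }
    stop("malformed FASTQ in ", path)
  }
  qual <- lapply(qs, function(q) utf8ToInt(q) - 33L)
  bad_q <- vapply(qual, function(q) any(q < 0L | q > 93L), logical(1))
  if (any(bad_q))
    stop("malformed FASTQ record '", ids[which(bad_q)[1]],
         "': quality outside the Sanger Phred+33 range")
  read_set(ids, as.character(x), qual = qual)
}

load_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  qual <- NULL
  qpath <- qual_sidecar_path(path)
  if (!is.null(qpath)) {
    qtab <- parse_qual_file(qpath)
    missing_q <- setdiff(ids, names(qtab))
    if (length(missing_q) > 0)
      stop("quality sidecar ", qpath, " lacks record(s): ",
           paste(utils::head(missing_q, 5), collapse = ", "))
    qual <- unname(qtab[ids])
  }
  read_set(ids, as.character(x), qual = qual)
}

qual_sidecar_path <- function(path) {
  cands <- unique(c(sub("\\.[^.]*$", ".qual", path), paste0(path, ".qual")))
  cands <- cands[cands != path & file.exists(cands)]
  if (length(cands) == 0) NULL else cands[1]
}

# .qual sidecar: FASTA-style headers, bodies of space-separated integers
parse_qual_file <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a .qual file (no '>' headers): ", path)
  grp <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  vals <- lapply(split(lines[!hdr], grp[!hdr]), function(body) {
    as.integer(scan(text = paste(body, collapse = " "), quiet = TRUE))
  })
  names(vals) <- ids
  vals
}

#' Write reads to FASTQ or FASTA
#'
#' FASTQ output requires qualities on every read (use `format = "fasta"`
#' otherwise). The FASTQ round trip is the identity on (id, seq, qual).
#'
#' @param rs a `ReadSet`.
#' @param path output path.
#' @param format `"fastq"` or `"fasta"`.
#' @return Invisibly, the number of records written.
#' @export
write_reads <- function(rs, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "fastq" && is.null(rs$qual) && length(rs) > 0)
    stop("reads carry no qualities; cannot write FASTQ (use fasta)")
  x <- Biostrings::DNAStringSet(rs$seq)
  names(x) <- rs$id
  if (format == "fastq") {
    q <- Biostrings::BStringSet(unname(vapply(rs$qual, function(v)
      intToUtf8(v + 33L), character(1))))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 20000L)
  }
  invisible(length(rs))
}

## ---- SFF v1 binary reader -------------------------------------------------

# 454 SFF v1 layout, all integers big-endian, every section 8-byte padded.
# Common header: magic(4) version(4) index_offset(8) index_length(4)
#   number_of_reads(4) header_length(2) key_length(2) number_of_flows(2)
#   flowgram_format(1) flow_chars key_sequence padding.
# Per read: header_length(2) name_length(2) number_of_bases(4)
#   clip_qual_left/right, clip_adapter_left/right (2 each, 1-based), name,
#   padding; then flow values (2*flows), flow index per base (bases),
#   bases, qualities (bases), padding.
load_sff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(256L, 1L))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(3:0))
  if (length(raw) < 31 ||
      !identical(raw[1:4], as.raw(c(0x2E, 0x73, 0x66, 0x66))))
    stop("not an SFF file (bad magic): ", path)
  version <- u32(4)
  if (version != 1) stop("unsupported SFF version ", version, " (expected 1)")
  index_offset <- sum(as.numeric(raw[9:16]) * 256^(7:0))
  index_length <- u32(16)
  n_reads <- u32(20)
  header_length <- u16(24)
  key_length <- u16(26)
  n_flows <- u16(28)
  flowgram_format <- as.integer(raw[31])
  if (flowgram_format != 1)
    stop("unsupported SFF flowgram format ", flowgram_format, " (expected 1)")
  pos <- header_length  # header_length is already 8-byte padded
  pad8 <- function(n) as.integer(ceiling(n / 8) * 8)

  ids <- character(n_reads)
  seqs <- character(n_reads)
  quals <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    if (index_offset > 0 && pos == index_offset)
      pos <- pos + pad8(index_length)
    rh_len <- u16(pos)
    name_len <- u16(pos + 2)
    n_bases <- u32(pos + 4)
    cql <- u16(pos + 8); cqr <- u16(pos + 10)
    cal <- u16(pos + 12); car <- u16(pos + 14)
    ids[i] <- rawToChar(raw[pos + 16 + seq_len(name_len)])
    pos <- pos + rh_len
    # data section: flowgrams + flow indexes + bases + quals, jointly padded
    bases_off <- pos + 2 * n_flows + n_bases
    bases <- rawToChar(raw[bases_off + seq_len(n_bases)])
    qv <- as.integer(raw[bases_off + n_bases + seq_len(n_bases)])
    pos <- pos + pad8(2 * n_flows + 3 * n_bases)

    # 1-based inclusive clips -> 0-based half-open [left, right)
    left <- max(cql, cal, 1L) - 1L
    rights <- c(cqr, car)
    rights <- rights[rights > 0]
    right <- if (length(rights) == 0) n_bases else min(rights)
    if (left >= right)
      stop("SFF read '", ids[i], "': empty clipped region [",
           left, ",", right, ")")
    seqs[i] <- substr(bases, left + 1L, right)
    quals[[i]] <- qv[(left + 1L):right]
  }
  read_set(ids, seqs, qual = quals)
}
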
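#' Run the read-cleaning pipeline
#'
#' Applies the enabled cleaning stages in a fixed order: paired-end
#' linker splitting first (it rewrites the read set), then the length
#' filter, the undetermined-base filter, the complexity filter, the
#' quality filter, and finally duplicate removal. A read is attributed
#' to the first stage that removes it, so the per-reason counters sum
#' to the input read count.
#'
#' When paired-end cleaning is enabled the surviving reads are divided
#' into validated mate pairs (`<prefix>_pairs`) and single reads
#' (`<prefix>_singles`); if one mate of a pair is later removed by a
#' filter, the surviving mate is demoted to the singles output.
#' Otherwise a single `<prefix>_clean` file is written. A per-read log
#' with summary and duplication-profile footer goes to
#' `<prefix>_log.tsv` (see [write_log()]).
#'
#' @param input a `ReadSet`, or a path accepted by [load_reads()].
#' @param out_prefix output path prefix; `NULL` (default) writes no
#'   files and only returns the results.
#' @param format output format, `"fastq"` or `"fasta"`.
#' @param clean_pairends,clean_length_win,clean_length_std,clean_complexity_full,clean_complexity_win,clean_quality,clean_ns,clean_duplicates
#'   logical switches enabling each stage. At least one must be on;
#'   the two length modes (and the two complexity modes) are mutually
#'   exclusive.
#' @param linkers linker list from [load_linkers()] (required when
#'   `clean_pairends = TRUE`).
#' @param filter_cfg a [filter_config()].
#' @param dedup_cfg a [dedup_config()].
#' @param pairend_cfg a [pairend_config()].
#' @return A list with `report` (a `cleaning_report`), `kept` (surviving
#'   working reads, input order), and when paired-end cleaning is on,
#'   `pairs` and `singles` `ReadSet`s; plus `files`, the paths written.
#' @export
run_pipeline <- function(input, out_prefix = NULL, format = c("fastq", "fasta"),
                         clean_pairends = FALSE,
                         clean_length_win = FALSE, clean_length_std = FALSE,
                         clean_ns = FALSE,
                         clean_complexity_full = FALSE,
                         clean_complexity_win = FALSE,
                         clean_quality = FALSE,
                         clean_duplicates = FALSE,
                         linkers = NULL,
                         filter_cfg = filter_config(),
                         dedup_cfg = dedup_config(),
                         pairend_cfg = pairend_config()) {
  format <- match.arg(format)
  if (clean_length_win && clean_length_std)
    stop("enable only one of clean_length_win / clean_length_std")
  if (clean_complexity_full && clean_complexity_win)
    stop("enable only one of clean_complexity_full / clean_complexity_win")
  stages_on <- c(clean_pairends, clean_length_win, clean_length_std,
                 clean_ns, clean_complexity_full, clean_complexity_win,
                 clean_quality, clean_duplicates)
  if (!any(stages_on)) stop("no cleaning stage enabled")
  if (clean_pairends && is.null(linkers))
    stop("clean_pairends requires `linkers` (see load_linkers())")
  rs <- if (inherits(input, "ReadSet")) input else load_reads(input)

  input_ids <- rs$id
  n_input <- length(rs)

  # working reads carry their source input id; pairend may split them
  work <- rs
  source_id <- rs$id
  fate <- stats::setNames(rep(NA_character_, n_input), input_ids)
  detail <- stats::setNames(rep("", n_input), input_ids)
  pairend_case <- stats::setNames(rep(NA_character_, n_input), input_ids)

  if (clean_pairends && n_input > 0) {
    pieces <- vector("list", n_input)
    src <- vector("list", n_input)
    for (i in seq_len(n_input)) {
      r1 <- rs[i]
      d <- classify_pairend(r1, find_linker_matches(r1, linkers, pairend_cfg),
                            pairend_cfg)
      pairend_case[i] <- d$case_label
      if (d$action == "DISCARD") {
        fate[i] <- "removed:linker"
        detail[i] <- paste0("case ", d$case_label)
        pieces[[i]] <- r1[integer(0)]
      } else {
        pieces[[i]] <- split_pairend(r1, d)
      }
      src[[i]] <- rep(rs$id[i], length(pieces[[i]]))
    }
    work <- bind_read_sets(pieces)
    source_id <- unlist(src)
  }

  # per-working-read removal reason, NA while alive
  w_reason <- rep(NA_character_, length(work))
  w_detail <- rep("", length(work))
  alive <- function() which(is.na(w_reason))

  apply_predicate <- function(reason, pred) {
    for (i in alive()) {
      if (!pred(work[i])) {
        w_reason[i] <<- reason
      }
    }
  }

  if (clean_length_win)
    apply_predicate("length", function(r) filter_length_window(r, filter_cfg))
  if (clean_length_std && length(alive()) > 0) {
    res <- filter_length_std(work[alive()], filter_cfg)
    w_reason[match(res$removed_ids, work$id)] <- "length"
  }
  if (clean_ns)
    apply_predicate("ns", function(r) filter_n_rate(r, filter_cfg))
  if (clean_complexity_full)
    apply_predicate("complexity",
                    function(r) filter_complexity_full(r, filter_cfg))
  if (clean_complexity_win)
    apply_predicate("complexity",
                    function(r) filter_complexity_window(r, filter_cfg))
  if (clean_quality)
    apply_predicate("quality", function(r) filter_quality(r, filter_cfg))

  clusters <- list()
  if (clean_duplicates && length(alive()) > 0) {
    dd <- deduplicate(work[alive()], dedup_cfg)
    clusters <- dd$clusters
    if (NROW(dd$removed) > 0) {
      ri <- match(dd$removed$id, work$id)
      w_reason[ri] <- "duplicate"
      w_detail[ri] <- paste0("cluster ", dd$removed$cluster_id)
    }
  }

  # fold working-read outcomes back onto input reads
  kept_idx <- alive()
  for (id in input_ids[is.na(fate)]) {
    wi <- which(source_id == id)
    live <- wi[is.na(w_reason[wi])]
    dead <- wi[!is.na(w_reason[wi])]
    was_pair <- length(wi) == 2
    if (length(live) == length(wi)) {
      fate[id] <- if (!clean_pairends) "kept"
                  else if (was_pair) "split:pair" else "split:single"
      if (clean_pairends) detail[id] <- paste0("case ", pairend_case[id])
    } else if (length(live) == 0) {
      fate[id] <- paste0("removed:", w_reason[dead[1]])
      detail[id] <- paste(paste0(work$id[dead], " ", w_reason[dead],
                                 ifelse(nzchar(w_detail[dead]),
                                        paste0(" (", w_detail[dead], ")"), "")),
                          collapse = "; ")
    } else {
      # one mate of a pair survived: demote to singles
      fate[id] <- "split:single"
      detail[id] <- paste0("mate ", work$id[dead], " removed:",
                           w_reason[dead])
    }
  }

  kept <- work[kept_idx]
  # pairs vs singles partition of the surviving reads
  pairs_rs <- singles_rs <- NULL
  if (clean_pairends) {
    pair_src <- input_ids[fate[input_ids] == "split:pair"]
    in_pairs <- source_id[kept_idx] %in% pair_src
    pairs_rs <- kept[which(in_pairs)]
    singles_rs <- kept[which(!in_pairs)]
  }

  reason <- ifelse(startsWith(fate, "removed:"),
                   sub("^removed:", "", fate), fate)
  counters <- table(reason)
  counters <- stats::setNames(as.integer(counters), names(counters))

  report <- structure(list(
    records = data.frame(id = input_ids, fate = unname(fate[input_ids]),
                         detail = unname(detail[input_ids]),
                         stringsAsFactors = FALSE),
    counters = counters,
    profile = duplication_profile(clusters),
    input_count = n_input,
    output_count = length(kept)
  ), class = "cleaning_report")

  files <- character(0)
  if (!is.null(out_prefix)) {
    ext <- format
    if (clean_pairends) {
      fp <- paste0(out_prefix, "_pairs.", ext)
      fs <- paste0(out_prefix, "_singles.", ext)
      write_reads(pairs_rs, fp, format)
      write_reads(singles_rs, fs, format)
      files <- c(pairs = fp, singles = fs)
    } else {
      fc <- paste0(out_prefix, "_clean.", ext)
      write_reads(kept, fc, format)
      files <- c(clean = fc)
    }
    fl <- paste0(out_prefix, "_log.tsv")
    write_log(report, fl)
    files <- c(files, log = fl)
  }

  out <- list(report = report, kept = kept, files = files)
  if (clean_pairends) {
    out$pairs <- pairs_rs
    out$singles <- singles_rs
  }
  out
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:", x$input_count, "read(s) in,",
      x$output_count, "out\n")
  for (nm in names(x$counters))
    cat(sprintf("  %-12s %d\n", nm, x$counters[[nm]]))
  if (length(x$profile$histogram) > 0) {
    cat("  duplication profile (cluster size: count):\n")
    h <- x$profile$histogram
    cat("   ", paste0(names(h), ":", h, collapse = "  "), "\n")
    cat(sprintf("  dup membership rate %.4f, removal rate %.4f\n",
                x$profile$dup_membership_rate, x$profile$removal_rate))
  }
  invisible(x)
}

#' Write the cleaning log
#'
#' One tab-separated row per input read (`id`, `fate`, `detail`),
#' followed by a footer of `#`-prefixed lines holding the summary
#' counters and the duplication-profile histogram. The footer can be
#' parsed back with [read_log_footer()].
#'
#' @param report a `cleaning_report` from [run_pipeline()].
#' @param path output path.
#' @param timestamp if `TRUE`, include a timestamp line (off by default
#'   so identical runs produce byte-identical logs).
#' @return Invisibly, `path`.
#' @export
write_log <- function(report, path, timestamp = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (timestamp)
    writeLines(paste0("# generated\t", format(Sys.time())), con)
  writeLines("id\tfate\tdetail", con)
  with(report$records,
       writeLines(paste(id, fate, detail, sep = "\t"), con))
  writeLines(paste0("# input\t", report$input_count), con)
  writeLines(paste0("# output\t", report$output_count), con)
  for (nm in names(report$counters))
    writeLines(paste0("# summary\t", nm, "\t", report$counters[[nm]]), con)
  h <- report$profile$histogram
  for (nm in names(h))
    writeLines(paste0("# histogram\t", nm, "\t", h[[nm]]), con)
  invisible(path)
}

#' Parse a cleaning-log footer
#'
#' @param path a log file written by [write_log()].
#' @return A list with `input_count`, `output_count`, `counters` (named
#'   integer vector) and `histogram` (named integer vector, cluster
#'   size -> count).
#' @export
read_log_footer <- function(path) {
  lines <- grep("^# ", readLines(path), value = TRUE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get1 <- function(key) {
    v <- fields[vapply(fields, function(f) f[1] == paste0("# ", key),
                       logical(1))]
    v
  }
  pick <- function(key) {
    v <- get1(key)
    stats::setNames(as.integer(vapply(v, `[[`, character(1), 3)),
                    vapply(v, `[[`, character(1), 2))
  }
  list(input_count = as.integer(get1("input")[[1]][2]),
       output_count = as.integer(get1("output")[[1]][2]),
       counters = pick("summary"),
       histogram = pick("histogram"))
}
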
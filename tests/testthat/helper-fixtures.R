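# shared fixture builders (all fixtures are generated in code)

rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# substitute the bases at `pos` with a different base each
with_subs <- function(s, pos) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in pos) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  paste(chars, collapse = "")
}

write_fastq_lines <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals))
    quals <- lapply(nchar(seqs), function(l) rep(40L, l))
  lines <- unlist(lapply(seq_along(ids), function(i)
    c(paste0("@", ids[i]), seqs[i], "+",
      intToUtf8(quals[[i]] + 33L))))
  writeLines(lines, path)
  path
}

# a synthetic 44 bp linker used throughout the paired-end tests
# (fixed arbitrary sequence, deliberately not self-complementary)
test_linker <- function() {
  list(id = "test_linker",
       seq = "ACCTGCAGTTCGAAGGCTAAGCGGTTCACAGTTATCGCGGATCC")
}

# one constructed read per paired-end decision-tree case; reads are
# 300 bp unless the case demands otherwise, the linker is 44 bp
make_case_read <- function(case, lk = test_linker()) {
  L <- lk$seq
  frag25 <- substr(L, 1, 25)  # partial linker: 25/44 = 0.57 completeness
  seq <- switch(case,
    a = rnd_seq(300),
    b = paste0(rnd_seq(60), L, rnd_seq(76), L, rnd_seq(76)),
    c = paste0(rnd_seq(275), frag25),
    d = paste0(rnd_seq(150), frag25, rnd_seq(125)),
    e = paste0(rnd_seq(120), L, rnd_seq(136)),
    f = paste0(rnd_seq(48), L, rnd_seq(48)),
    g = paste0(rnd_seq(10), L, rnd_seq(246))
  )
  read_set(paste0("case_", case), seq,
           qual = list(rep(35L, nchar(seq))))
}

# the 20-read pipeline accounting fixture: each problem read violates
# exactly one filter; expected counters are
# {length:2, ns:1, complexity:1, quality:2, duplicate:2}, 12 kept
accounting_fixture <- function() {
  set.seed(2024)
  ids <- character(0); seqs <- character(0); quals <- list()
  add <- function(id, s, q) {
    ids <<- c(ids, id); seqs <<- c(seqs, s)
    quals[[length(quals) + 1]] <<- q
  }
  good_q <- function(l) rep(40L, l)
  # 11 clean reads
  for (i in 1:11) {
    s <- rnd_seq(250 + 10 * i)
    add(sprintf("good_%02d", i), s, good_q(nchar(s)))
  }
  # 2 too short
  add("short_1", rnd_seq(30), good_q(30))
  add("short_2", rnd_seq(45), good_q(45))
  # 1 all N (passes the length window, fails the N-rate filter)
  add("all_n", strrep("N", 100), good_q(100))
  # 1 homopolymer (fails complexity)
  add("homopoly", strrep("A", 300), good_q(300))
  # 2 poor quality (random sequence, every base at Phred 5)
  add("lowq_1", rnd_seq(200), rep(5L, 200))
  add("lowq_2", rnd_seq(220), rep(5L, 220))
  # 3 identical copies of one template (cluster of 3; 2 removed)
  tpl <- rnd_seq(300)
  add("dup_a", tpl, good_q(300))
  add("dup_b", tpl, good_q(300))
  add("dup_c", tpl, good_q(300))
  read_set(ids, seqs, qual = quals)
}
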
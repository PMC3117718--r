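test_that("an exact interior linker copy is found with full completeness", {
  set.seed(41)
  lk <- test_linker()
  r <- paste0(rnd_seq(150), lk$seq, rnd_seq(106))
  m <- find_linker_matches(r, list(lk))
  expect_equal(length(m), 1)
  expect_equal(m[[1]]$start, 150)
  expect_equal(m[[1]]$end, 194)
  expect_equal(m[[1]]$completeness, 1.0)
  expect_equal(m[[1]]$mismatches, 0)
  expect_equal(m[[1]]$strand, "+")

  expect_equal(length(find_linker_matches(rnd_seq(300), list(lk))), 0)
})

test_that("a reverse-complement linker copy is found on the minus strand", {
  set.seed(42)
  lk <- test_linker()
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(lk$seq)))
  r <- paste0(rnd_seq(100), rc, rnd_seq(100))
  m <- find_linker_matches(r, list(lk))
  expect_equal(length(m), 1)
  expect_equal(m[[1]]$strand, "-")
  expect_equal(m[[1]]$start, 100)
  expect_equal(m[[1]]$end, 144)
})

test_that("a linker copy with a couple of errors still counts as full", {
  set.seed(43)
  lk <- test_linker()
  damaged <- with_subs(lk$seq, c(15, 30))  # interior, stays full-span
  r <- paste0(rnd_seq(120), damaged, rnd_seq(136))
  m <- find_linker_matches(r, list(lk))
  expect_equal(length(m), 1)
  expect_equal(m[[1]]$mismatches, 2)
  expect_equal(m[[1]]$completeness, 1.0)
  d <- classify_pairend(r, m)
  expect_equal(d$case_label, "e")
})

test_that("the decision tree assigns every constructed case its action", {
  set.seed(44)
  lk <- test_linker()
  expected <- list(a = "SINGLE_WHOLE", b = "DISCARD", c = "SINGLE_CLIPPED",
                   d = "DISCARD", e = "PAIR", f = "DISCARD",
                   g = "SINGLE_CLIPPED")
  for (case in names(expected)) {
    r <- make_case_read(case, lk)
    d <- classify_pairend(r, find_linker_matches(r, list(lk)))
    expect_equal(d$case_label, case)
    expect_equal(d$action, expected[[case]])
  }
})

test_that("pair and clip intervals are placed around the linker", {
  set.seed(45)
  lk <- test_linker()
  e <- make_case_read("e", lk)
  de <- classify_pairend(e, find_linker_matches(e, list(lk)))
  expect_equal(de$intervals, list(c(0L, 120L), c(164L, 300L)))
  sp <- split_pairend(e, de)
  expect_equal(sp$id, c("case_e/1", "case_e/2"))
  expect_equal(nchar(sp$seq), c(120L, 136L))
  expect_equal(lengths(sp$qual), c(120L, 136L))

  g <- make_case_read("g", lk)
  dg <- classify_pairend(g, find_linker_matches(g, list(lk)))
  expect_equal(dg$intervals, list(c(54L, 300L)))
  sg <- split_pairend(g, dg)
  expect_equal(sg$id, "case_g")
  expect_equal(nchar(sg$seq), 246L)

  b <- make_case_read("b", lk)
  db <- classify_pairend(b, find_linker_matches(b, list(lk)))
  expect_equal(length(split_pairend(b, db)), 0)
})

test_that("emitted bases are a subset of the input and exclude the linker", {
  set.seed(46)
  lk <- test_linker()
  for (case in c("a", "c", "e", "g")) {
    r <- make_case_read(case, lk)
    m <- find_linker_matches(r, list(lk))
    d <- classify_pairend(r, m)
    out <- split_pairend(r, d)
    for (iv in d$intervals) {
      expect_true(iv[1] >= 0 && iv[2] <= nchar(r$seq))
      piece <- substr(r$seq, iv[1] + 1, iv[2])
      expect_true(piece %in% out$seq)
      if (length(m) == 1 && m[[1]]$completeness == 1) {
        expect_true(iv[2] <= m[[1]]$start || iv[1] >= m[[1]]$end)
      }
    }
  }
})

test_that("classification is total over fuzzed reads and match lists", {
  set.seed(47)
  lk <- test_linker()
  actions <- c("SINGLE_WHOLE", "DISCARD", "SINGLE_CLIPPED", "PAIR")
  for (i in 1:150) {
    len <- sample(60:400, 1)
    r <- rnd_seq(len)
    nm <- sample(0:3, 1)
    matches <- list()
    if (nm > 0) {
      for (k in seq_len(nm)) {
        st <- sample(0:(len - 10), 1)
        en <- min(len, st + sample(10:44, 1))
        matches[[k]] <- list(linker_id = lk$id, start = st, end = en,
                             strand = sample(c("+", "-"), 1),
                             matches = en - st,
                             mismatches = sample(0:5, 1),
                             gapped_bases = sample(0:2, 1),
                             completeness = runif(1, 0.5, 1),
                             score = en - st)
      }
    }
    d <- classify_pairend(r, matches)
    expect_true(d$case_label %in% letters[1:7])
    expect_true(d$action %in% actions)
    for (iv in d$intervals) expect_true(iv[1] >= 0 && iv[2] <= len)
  }
})

test_that("the shipped example linker file loads", {
  path <- system.file("extdata", "linkers_example.fasta",
                      package = "pyroclean")
  lks <- load_linkers(path)
  expect_equal(length(lks), 2)
  expect_true(all(nchar(vapply(lks, `[[`, character(1), "seq")) > 40))
})
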
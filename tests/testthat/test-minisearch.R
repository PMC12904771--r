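test_that("smith_waterman handles identity and all-negative cases", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  r <- smith_waterman(s, s)
  smat <- divorph:::scoring_matrix()
  expect_equal(r$score,
               sum(diag(smat)[match(strsplit(s, "")[[1]],
                                    rownames(smat))]))
  expect_equal(r$pident, 100)
  expect_equal(c(r$qstart, r$qend, r$sstart, r$send), c(1, 20, 1, 20))

  r0 <- smith_waterman("AAAA", "CCCC")  # BLOSUM62 A/C = 0, no positive path
  expect_equal(r0$score, 0)
  expect_error(smith_waterman("", "ACD"), "non-empty")
})

test_that("DP optimum equals the independent affine recursion on 50 pairs", {
  set.seed(11)
  for (k in 1:50) {
    a <- random_records(1, 5, 30, prefix = "a")$sequence
    b <- random_records(1, 5, 30, prefix = "b")$sequence
    expect_equal(smith_waterman(a, b)$score, sw_oracle_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment statistics are internally consistent", {
  set.seed(12)
  for (k in 1:25) {
    a <- random_records(1, 20, 60, prefix = "a")$sequence
    b <- random_records(1, 20, 60, prefix = "b")$sequence
    r <- smith_waterman(a, b)
    if (r$score == 0) next
    expect_lte(r$qend, nchar(a)); expect_lte(r$send, nchar(b))
    expect_gte(r$qstart, 1); expect_gte(r$sstart, 1)
    # columns = matches + mismatches + gap columns
    gap_cols <- r$align_len - r$identities - r$mismatches
    expect_gte(gap_cols, 0)
    expect_equal((r$qend - r$qstart + 1) + (r$send - r$sstart + 1),
                 2 * (r$identities + r$mismatches) + gap_cols)
  }
})

test_that("evalue/bitscore formula is exact and monotone", {
  # bitscore 10 from the inverse formula, query 100, db 100
  p <- search_params()
  s10 <- (10 * log(2) + log(p$K)) / p$lambda
  eb <- evalue_and_bitscore(s10, 100, 100, p)
  expect_equal(eb$bitscore, 10, tolerance = 1e-12)
  expect_equal(eb$evalue, 9.765625, tolerance = 1e-9)

  scores <- seq(20, 200, by = 5)
  ev <- evalue_and_bitscore(scores, 150, 1e5, p)$evalue
  expect_true(all(diff(ev) < 0))
})

test_that("search_all equals exhaustive pairwise SW + E-value filter", {
  set.seed(13)
  queries <- random_records(6, 25, 50, prefix = "q")
  db <- random_records(40, 25, 50, prefix = "d")
  par <- search_params(e_max = 5)  # loose ceiling so some chance hits pass
  hits <- search_all(queries, db, par)
  db_size <- sum(nchar(db$sequence))

  manual <- list()
  for (qi in seq_len(nrow(queries))) for (si in seq_len(nrow(db))) {
    al <- smith_waterman(queries$sequence[qi], db$sequence[si], par)
    if (al$score == 0) next
    eb <- evalue_and_bitscore(al$score, nchar(queries$sequence[qi]),
                              db_size, par)
    if (eb$evalue <= par$e_max)
      manual[[length(manual) + 1L]] <-
        data.frame(qseqid = queries$id[qi], sseqid = db$id[si],
                   evalue = eb$evalue, bitscore = eb$bitscore,
                   qstart = al$qstart, send = al$send)
  }
  manual <- do.call(rbind, manual)
  expect_equal(nrow(hits), nrow(manual))
  key <- function(d) paste(d$qseqid, d$sseqid)
  expect_setequal(key(hits), key(manual))
  m <- manual[match(key(hits), key(manual)), ]
  expect_equal(hits$evalue, m$evalue, tolerance = 1e-12)
  expect_equal(hits$qstart, m$qstart)
  expect_equal(hits$send, m$send)

  # per-query ordering: ascending evalue then subject id
  for (q in unique(hits$qseqid)) {
    hq <- hits[hits$qseqid == q, ]
    expect_identical(order(hq$evalue, hq$sseqid), seq_len(nrow(hq)))
  }
})

test_that("query identical to a database entry is its top hit at pident 100", {
  set.seed(14)
  db <- random_records(50, 30, 80, prefix = "d")
  q <- db[7, , drop = FALSE]
  q$id <- "the_query"
  hits <- search_all(q, db)
  expect_equal(hits$sseqid[1], "d7")
  expect_equal(hits$pident[1], 100)
  expect_equal(hits$length[1], nchar(q$sequence))
})

test_that("search output is schema-closed under tabular round trip", {
  set.seed(15)
  hits <- search_all(random_records(4, 30, 60, prefix = "q"),
                     random_records(30, 30, 60, prefix = "d"),
                     search_params(e_max = 10))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(hits, f)
  back <- read_tabular_hits(f)
  expect_equal(nrow(back), nrow(hits))
  expect_equal(back$bitscore, hits$bitscore, tolerance = 1e-9)
})

test_that("null calibration: shuffled queries are not anti-conservative", {
  # average number of chance hits with E <= c should not exceed ~3c
  set.seed(16)
  db <- random_records(400, 40, 80, prefix = "d")   # ~2e4+ residues
  q <- random_records(40, 40, 80, prefix = "q")
  hits <- search_all(q, db, search_params(e_max = 1))
  for (cc in c(0.1, 1)) {
    mean_hits <- sum(hits$evalue <= cc) / nrow(q)
    expect_lte(mean_hits, 3 * cc)
  }
})
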
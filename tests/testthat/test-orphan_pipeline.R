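mini_queries <- function(ids, lens = 100) {
  protein_records(ids, vapply(rep_len(lens, length(ids)), function(L)
    paste(rep("A", L), collapse = ""), character(1)))
}

hit_row <- function(q, e, s = "s1") {
  data.frame(qseqid = q, sseqid = s, pident = 30, length = 50, mismatch = 30,
             gapopen = 1, qstart = 1, qend = 50, sstart = 1, send = 50,
             evalue = e, bitscore = 25, stringsAsFactors = FALSE)
}

test_that("eligibility three-way status follows the band definition", {
  qs <- mini_queries(c("sig", "elig", "none", "nohit"))
  hits <- rbind(hit_row("sig", 5e-4), hit_row("sig", 0.5),
                hit_row("elig", 0.002), hit_row("elig", 0.5, "s2"),
                hit_row("none", 3))  # above band_max
  calls <- call_eligibility(hits, qs)
  st <- setNames(calls$calls$status, calls$calls$query_id)
  expect_equal(st[["sig"]], "has_significant_hit")
  expect_equal(st[["elig"]], "eligible_orphan")
  expect_equal(st[["none"]], "no_band_hits")
  expect_equal(st[["nohit"]], "no_band_hits")
  expect_equal(calls$calls$n_band_hits[calls$calls$query_id == "elig"], 2L)
  expect_true(all(calls$band_hits$qseqid == "elig"))
  expect_true(all(calls$band_hits$evalue >= 1e-3 &
                  calls$band_hits$evalue <= 1))

  # boundary: closed band by default, strict upper on request
  qb <- mini_queries("b")
  hb <- hit_row("b", 1.0)
  expect_equal(call_eligibility(hb, qb)$calls$status, "eligible_orphan")
  expect_equal(call_eligibility(hb, qb, strict_upper = TRUE)$calls$status,
               "no_band_hits")
})

test_that("eligible set responds monotonically to the significance cutoff", {
  # enumerate a 20-query toy table over a sweep of sig thresholds: raising
  # the cutoff can only move queries out of eligibility into significance
  set.seed(21)
  qs <- mini_queries(paste0("q", 1:20))
  hits <- do.call(rbind, lapply(1:20, function(i) {
    n <- sample(1:4, 1)
    do.call(rbind, lapply(seq_len(n), function(j)
      hit_row(paste0("q", i), 10^runif(1, -6, 0), paste0("s", j))))
  }))
  sweep <- c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)
  eligible <- lapply(sweep, function(sig)
    with(call_eligibility(hits, qs, sig, 1)$calls,
         query_id[status == "eligible_orphan"]))
  sig_set <- lapply(sweep, function(sig)
    with(call_eligibility(hits, qs, sig, 1)$calls,
         query_id[status == "has_significant_hit"]))
  for (k in seq_along(sweep)[-1]) {
    # significant set grows with the cutoff
    expect_true(all(sig_set[[k - 1]] %in% sig_set[[k]]))
    # queries leaving the eligible set only ever become significant
    left <- setdiff(eligible[[k - 1]], eligible[[k]])
    expect_true(all(left %in% sig_set[[k]]))
  }
})

test_that("reverse_sequence preserves length and composition", {
  rec <- protein_records("a", "ACDE")
  expect_equal(reverse_sequence(rec)$sequence, "EDCA")
  expect_equal(reverse_sequence(rec)$provenance, "reversed")

  pal <- protein_records("p", "ACDCA")
  expect_equal(reverse_sequence(pal)$sequence, "ACDCA")

  recs <- random_records(1000, 5, 50, seed = 22)
  revs <- reverse_sequence(recs)
  expect_equal(nchar(revs$sequence), nchar(recs$sequence))
  for (i in seq_len(50)) {  # spot-check composition multisets
    expect_identical(sort(strsplit(revs$sequence[i], "")[[1]]),
                     sort(strsplit(recs$sequence[i], "")[[1]]))
  }
})

test_that("truncation calibration recovers a planted length offset", {
  # negatives exactly 25% longer; eligibility independent of length:
  # a fake search backend makes every query eligible, so the calibration
  # objective reduces to matching means and f* = 0.2 restores equality
  set.seed(23)
  pos_len <- rep(80L, 50)
  neg <- mini_queries(paste0("n", 1:50), lens = 100L)
  fake_search <- function(records)
    do.call(rbind, lapply(records$id, function(i) hit_row(i, 0.5)))
  # fake backend reports band hits for every query regardless of length;
  # eligibility then keeps all, and mean length tracks truncation directly
  fake_search2 <- function(records) {
    h <- fake_search(records)
    h$qend <- pmin(h$qend, nchar(records$sequence[match(h$qseqid, records$id)]))
    h
  }
  cal <- calibrate_truncation(pos_len, neg, fake_search2,
                              grid = seq(0, 0.4, by = 0.05))
  expect_equal(cal$fraction, 0.2)
  expect_true(cal$fraction %in% seq(0, 0.4, by = 0.05))

  # means already equal -> 0 (ties resolved to the smaller fraction)
  cal0 <- calibrate_truncation(rep(100L, 10), neg, fake_search2,
                               grid = c(0, 0.1, 0.2))
  expect_equal(cal0$fraction, 0)
  expect_error(calibrate_truncation(pos_len, neg, fake_search2,
                                    grid = numeric(0)), "empty")
})

test_that("dataset assembly balances classes and honors the min rule", {
  pos <- toy_labeled_table(100)[1:100, 1:5]
  neg <- toy_labeled_table(80, seed = 2)[1:80, 1:5]
  ds <- assemble_dataset(pos, neg, seed = 1)
  expect_equal(sum(ds$CLASS == 1), 80)
  expect_equal(sum(ds$CLASS == 0), 80)
  expect_error(assemble_dataset(pos, neg, n_per_class = 90), "available")

  ds1 <- assemble_dataset(pos, neg, seed = 5)
  ds2 <- assemble_dataset(pos, neg, seed = 5)
  expect_identical(ds1, ds2)

  # mixed rule: 16 subsets with min yield 195 -> 16*195 rows per class
  subsets <- lapply(1:16, function(i) {
    n <- 195 + sample(0:40, 1)
    list(positives = data.frame(f = rnorm(n)),
         negatives = data.frame(f = rnorm(n + sample(0:20, 1))))
  })
  subsets[[7]]$positives <- subsets[[7]]$positives[1:195, , drop = FALSE]
  mixed <- assemble_mixed_dataset(subsets, seed = 3)
  expect_equal(attr(mixed, "n_per_class"), 195)
  expect_equal(sum(mixed$CLASS == 1), 16 * 195)
  expect_equal(sum(mixed$CLASS == 0), 16 * 195)
})
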
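test_that("parse_sccs resolves prefix paths at every accepted depth", {
  p <- parse_sccs("a.38.1")
  expect_equal(p$class_id, "a")
  expect_equal(p$fold_id, "a.38")
  expect_equal(p$superfamily_id, "a.38.1")
  expect_true(is.na(p$family_id))
  expect_equal(p$depth, 3L)

  p4 <- parse_sccs("e.1.1.2")
  expect_equal(p4$superfamily_id, "e.1.1")
  expect_equal(p4$family_id, "e.1.1.2")
  expect_equal(p4$depth, 4L)

  p2 <- parse_sccs("b.22")
  expect_equal(p2$fold_id, "b.22")
  expect_equal(p2$depth, 2L)
})

test_that("parse_sccs rejects malformed tokens naming the offence", {
  expect_error(parse_sccs("a.38.1.2.5"), "components")
  expect_error(parse_sccs("a"), "components")
  expect_error(parse_sccs("ab.1.1"), "single letter")
  expect_error(parse_sccs("a.x.1"), "positive integer")
  expect_error(parse_sccs("a.0.1"), "positive integer")
})

test_that("format_sccs and parse_sccs round-trip over generated paths", {
  set.seed(42)
  for (i in 1:200) {
    depth <- sample(2:4, 1)
    token <- paste(c(sample(letters[1:7], 1),
                     sample(1:120, depth - 1, replace = TRUE)),
                   collapse = ".")
    expect_identical(format_sccs(parse_sccs(token)), token)
  }
})

test_that("read_astral_fasta parses the Astral header dialect", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">dTOY1a_ a.1.1.1 (A:) toy protein one",
    "mkv",
    ">dTOY2a_ a.1.1.2 (A:1-50,A:90-120) two-span protein",
    "MKVL",
    ">dTOY3a_ (B:) header without classification",
    "MKVLA"
  ), path)
  db <- read_astral_fasta(path)
  expect_s3_class(db, "DomainDatabase")
  expect_equal(nrow(db), 2L)
  expect_equal(db$domain_id, c("dTOY1a_", "dTOY2a_"))
  expect_equal(db$family_id[1], "a.1.1.1")
  expect_equal(db$sequence[1], "MKV")       # uppercased
  expect_equal(db$span_count, c(1L, 2L))    # comma-separated regions
  expect_equal(db$description[1], "toy protein one")
  expect_equal(nrow(attr(db, "skipped")), 1L)
})

test_that("read_astral_fasta rejects duplicate ids and empty files", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">dX a.1.1.1 (A:) p", "MKV", ">dX a.1.1.2 (A:) q", "MKVL"),
             path)
  expect_error(read_astral_fasta(path), "duplicate")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_astral_fasta(empty))
})

test_that("annotation tables read, validate per row, and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("domain_id\tsccs\tsequence",
               "d1\ta.1.1.1\tMKV",
               "d2\tb.1\tMKVL",
               "d3\tc.2.1.3\tACDEFGHIKLMNPQRSTVWY"), path)
  expect_warning(db <- read_annotation_table(path), "rejected")
  expect_equal(nrow(db), 2L)
  expect_equal(attr(db, "skipped")$domain_id, "d2")  # depth-2 sccs rejected

  out <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(db, out)
  db2 <- read_annotation_table(out)
  expect_equal(as.data.frame(db2), as.data.frame(db), ignore_attr = TRUE)

  hdr_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines("domain_id\tsccs\tsequence", hdr_only)
  expect_warning(empty <- read_annotation_table(hdr_only), "no data rows")
  expect_equal(nrow(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("domain_id\tsequence", "d1\tMKV"), bad)
  expect_error(read_annotation_table(bad), "sccs")
})

test_that("preprocessing filters remove exactly the matching records", {
  db <- toy_db(c("a.1.1.1", "a.1.1.2", "c.2.1.1", "b.5.1.1", "b.5.2.1"))
  db$span_count <- c(1L, 2L, 1L, 1L, 1L)

  out <- apply_preprocessing_filters(db, excluded_fold_ids = "c.2")
  rep1 <- attr(out, "filter_report")
  expect_equal(nrow(out), 4L)
  expect_equal(rep1$removed[rep1$rule == "excluded_fold"], 1L)
  expect_false("c.2.1.1" %in% out$sccs)
  expect_equal(nrow(db), 5L)  # input untouched

  out2 <- apply_preprocessing_filters(db, require_single_span = TRUE)
  expect_false("a.1.1.2" %in% out2$sccs)

  # conservation: removed + retained = input
  out3 <- apply_preprocessing_filters(db, excluded_fold_ids = c("c.2", "b.5"),
                                      require_single_span = TRUE)
  expect_equal(nrow(out3) + sum(attr(out3, "filter_report")$removed), nrow(db))

  # identity transformation with no rules active
  out4 <- apply_preprocessing_filters(db)
  expect_equal(as.data.frame(out4), as.data.frame(db), ignore_attr = TRUE)
})

test_that("greedy identity filter retains longest-first below threshold", {
  # identical sequences collapse to one
  db <- toy_db(c("a.1.1.1", "a.1.1.2"), ids = c("dA", "dB"),
               seqs = c("MKVLMKVL", "MKVLMKVL"))
  expect_equal(nrow(greedy_identity_filter(db, 0.95)), 1L)

  # disjoint alphabets: identity 0, both kept even at a tight threshold
  db2 <- toy_db(c("a.1.1.1", "a.1.1.2"), ids = c("dA", "dB"),
                seqs = c("AAAA", "CCCC"))
  expect_equal(nrow(greedy_identity_filter(db2, 0.10)), 2L)

  # A and B near-identical (9 matches over alignment length 12 = 0.75),
  # C shares no letters with either; at th = 0.5 the longer of A/B plus C
  db3 <- toy_db(c("a.1.1.1", "a.1.1.2", "b.1.1.1"),
                ids = c("dA", "dB", "dC"),
                seqs = c("ACDEFGHIKLWW", "ACDEFGHIKM", "PPPPP"))
  kept <- greedy_identity_filter(db3, 0.5)
  expect_setequal(kept$domain_id, c("dA", "dC"))
  expect_equal(attr(kept, "identity_threshold_label"), 0.5)

  expect_error(greedy_identity_filter(db3, 1.5), "\\(0, 1\\]")
  expect_error(greedy_identity_filter(db3, 0), "\\(0, 1\\]")
})

test_that("greedy filter output never contains a pair above threshold", {
  set.seed(11)
  aa <- c("A", "C", "D", "E")
  seqs <- vapply(1:8, function(i)
    paste(sample(aa, sample(6:12, 1), replace = TRUE), collapse = ""), "")
  db <- toy_db(sprintf("a.1.1.%d", 1:8), seqs = seqs)
  for (th in c(0.4, 0.7)) {
    kept <- greedy_identity_filter(db, th)
    if (nrow(kept) >= 2L) {
      pairs <- utils::combn(nrow(kept), 2)
      for (k in seq_len(ncol(pairs))) {
        ident <- remhombench:::pairwise_identity(kept$sequence[pairs[1, k]],
                                                 kept$sequence[pairs[2, k]])
        expect_lte(ident, th)
      }
    }
  }
})
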
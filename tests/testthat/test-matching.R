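test_that("label normalization is deterministic and idempotent", {
  expect_equal(normalize_label("Zeta potential"), c("zeta", "potential"))
  expect_equal(normalize_label("  Zeta---Potential!! "),
               c("zeta", "potential"))
  expect_equal(normalize_label(""), character())
  set.seed(11)
  alphabet <- c(letters, "-", ".", " ", "(", ")", "0", "7")
  for (i in 1:50) {
    lab <- paste(sample(alphabet, sample(1:25, 1), replace = TRUE),
                 collapse = "")
    once <- normalize_label(lab)
    again <- normalize_label(paste(once, collapse = " "))
    expect_equal(again, once, label = paste("idempotent on", dQuote(lab)))
  }
})

test_that("exact matching uses synonyms on both sides", {
  vocab <- mit_vocabulary(data.frame(
    term_id = c("T2", "T1"),
    label = c("zeta potential", "irrelevant"),
    synonyms = c("", ""), parent_id = "", stringsAsFactors = FALSE))
  field <- list(field_id = "surface_charge", name = "surface charge",
                synonyms = "zeta potential")
  d <- match_exact(field, vocab)
  expect_equal(d$match_type, "exact")
  expect_equal(d$term_id, "T2")
  expect_equal(d$score, 1)
  # term-side synonym
  vocab2 <- mit_vocabulary(data.frame(
    term_id = "Z9", label = "zeta potential",
    synonyms = "surface charge", parent_id = "", stringsAsFactors = FALSE))
  field2 <- list(field_id = "sc", name = "surface charge", synonyms = "")
  expect_equal(match_exact(field2, vocab2)$match_type, "exact")
  # empty vocabulary matches nothing
  empty <- mit_vocabulary(data.frame(term_id = character(),
                                     label = character()))
  expect_equal(match_exact(field2, empty)$match_type, "none")
})

test_that("exact matcher agrees with a brute-force oracle on 50 terms", {
  set.seed(42)
  words <- c("particle", "size", "surface", "charge", "dose", "cell",
             "medium", "protocol", "exposure", "assay", "laser", "image")
  terms <- data.frame(
    term_id = sprintf("T%02d", 1:50),
    label = replicate(50, paste(sample(words, sample(1:3, 1)),
                                collapse = " ")),
    synonyms = "", parent_id = "", stringsAsFactors = FALSE)
  vocab <- mit_vocabulary(terms)
  sch <- tiny_schema()
  f <- sch$fields
  extra <- data.frame(field_id = sprintf("F%02d", 1:20),
                      name = replicate(20, paste(sample(words,
                                                        sample(1:3, 1)),
                                                 collapse = " ")),
                      synonyms = "", stringsAsFactors = FALSE)
  fields <- rbind(f[, c("field_id", "name", "synonyms")], extra)
  for (i in seq_len(nrow(fields))) {
    got <- match_exact(fields[i, ], vocab)
    want <- oracle_exact_match(fields$name[i], fields$synonyms[i], terms)
    expect_equal(got$term_id, want, label = fields$name[i])
    expect_equal(got$match_type, if (want == "") "none" else "exact")
  }
})

test_that("partial matching scores token subsets by Jaccard", {
  vocab <- mit_vocabulary(data.frame(
    term_id = c("T1", "T2"), label = c("protocol", "unrelated thing"),
    synonyms = "", parent_id = "", stringsAsFactors = FALSE))
  field <- list(field_id = "dispersion_protocol",
                name = "dispersion protocol", synonyms = "")
  d <- match_partial(field, vocab)
  expect_equal(d$match_type, "partial")
  expect_equal(d$term_id, "T1")
  expect_equal(d$score, 0.5)
  # identical labels are exact-matching territory, never partial
  same <- mit_vocabulary(data.frame(term_id = "T1",
                                    label = "dispersion protocol"))
  expect_equal(match_partial(field, same)$match_type, "none")
  # below min_score threshold
  long_field <- list(field_id = "f",
                     name = "one two three four five", synonyms = "")
  one_tok <- mit_vocabulary(data.frame(term_id = "T1", label = "one"))
  expect_equal(match_partial(long_field, one_tok,
                             min_score = 0.25)$match_type, "none")
  expect_equal(match_partial(long_field, one_tok,
                             min_score = 0.2)$match_type, "partial")
  expect_error(match_partial(field, vocab, min_score = 0), "min_score")
})

test_that("partial tie-breaks by score then lowest term id", {
  vocab <- mit_vocabulary(data.frame(
    term_id = c("T9", "T3"),
    label = c("dispersion", "protocol"),
    synonyms = "", parent_id = "", stringsAsFactors = FALSE))
  field <- list(field_id = "dp", name = "dispersion protocol",
                synonyms = "")
  d <- match_partial(field, vocab)
  expect_equal(d$score, 0.5)
  expect_equal(d$term_id, "T3")
})

test_that("crosswalk is total, deterministic, and honors precedence", {
  sch <- tiny_schema()
  vocab <- mit_vocabulary(data.frame(
    term_id = c("T1", "T2"),
    label = c("zeta potential", "protocol"),
    synonyms = "", parent_id = "", stringsAsFactors = FALSE))
  cw <- auto_crosswalk(sch, vocab)
  expect_equal(nrow(cw$decisions), nrow(sch$fields))
  expect_setequal(cw$decisions$field_id, sch$fields$field_id)
  # deterministic
  cw2 <- auto_crosswalk(sch, vocab)
  expect_identical(cw$decisions, cw2$decisions)
  # exact beats partial
  zp <- cw$decisions[cw$decisions$field_id == "zeta_potential", ]
  expect_equal(zp$match_type, "exact")
  dp <- cw$decisions[cw$decisions$field_id == "dispersion_protocol", ]
  expect_equal(dp$match_type, "partial")
  # curated "none" overrides an automatic exact match
  curated <- data.frame(field_id = "zeta_potential", term_id = "",
                        match_type = "none", stringsAsFactors = FALSE)
  cw3 <- auto_crosswalk(sch, vocab, curated = curated)
  zp3 <- cw3$decisions[cw3$decisions$field_id == "zeta_potential", ]
  expect_equal(zp3$match_type, "none")
  expect_equal(zp3$method, "curated")
  expect_equal(zp3$score, 0)
  # curated decisions for unknown fields are an integrity error
  bad <- data.frame(field_id = "ghost", term_id = "T1",
                    match_type = "exact", stringsAsFactors = FALSE)
  expect_error(auto_crosswalk(sch, vocab, curated = bad),
               "unknown field_id")
})

test_that("empty vocabulary yields an all-none crosswalk", {
  sch <- tiny_schema()
  empty <- mit_vocabulary(data.frame(term_id = character(),
                                     label = character()))
  cw <- auto_crosswalk(sch, empty)
  expect_true(all(cw$decisions$match_type == "none"))
  expect_true(all(cw$decisions$term_id == ""))
  expect_true(all(cw$decisions$score == 0))
})

test_that("every exact one-to-one match is also matched in partial mode", {
  sch <- build_reference_mit()
  gv <- generate_vocabulary(sch, 0.5, 0.3, 0.2, seed = 5)
  cw <- auto_crosswalk(sch, gv$vocabulary)
  one <- coverage_report(cw, "one_to_one")$rows
  par <- coverage_report(cw, "partial")$rows
  expect_true(all(par$matched >= one$matched))
})

test_that("vocabulary invariants reject bad term tables", {
  expect_error(mit_vocabulary(data.frame(term_id = c("A", "A"),
                                         label = c("x", "y"))),
               "duplicate term_id")
  expect_error(mit_vocabulary(data.frame(term_id = "A", label = "x",
                                         parent_id = "B")),
               "does not resolve")
  expect_error(mit_vocabulary(data.frame(term_id = c("A", "B"),
                                         label = c("x", "y"),
                                         parent_id = c("B", "A"))),
               "cyclic")
})

test_that("crosswalk TSV round-trips through write/read", {
  sch <- tiny_schema()
  gv <- generate_vocabulary(sch, 0.5, 0.25, 0.25, seed = 2)
  cw <- auto_crosswalk(sch, gv$vocabulary)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_crosswalk(cw, p)
  cw2 <- read_crosswalk(p, sch, vocab_id = cw$vocab_id)
  expect_equal(cw2$decisions, cw$decisions)
  expect_identical(coverage_report(cw2, "partial")$rows,
                   coverage_report(cw, "partial")$rows)
})
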
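# Coverage arithmetic is checked against every printed (percent, matched,
# total) pair of the published compatibility analyses, reproduced here on
# count-specified crosswalk fixtures.

published_pairs <- function() {
  read.csv(text = "
percent,matched,total
34,113,333
17,55,333
24,8,33
15,5,33
35,105,300
17,50,300
77,231,300
86,257,300
91,29,32
64,14,22
23,16,69
27,13,48
22,22,98
35,11,31
59,13,22
81,26,32
84,58,69
94,45,48
15,15,98
84,26,31", stringsAsFactors = FALSE)
}

test_that("round-half-up percent reproduces every published pair", {
  tab <- published_pairs()
  for (i in seq_len(nrow(tab))) {
    expect_equal(percent_half_up(tab$matched[i], tab$total[i]),
                 tab$percent[i],
                 label = sprintf("%d of %d", tab$matched[i],
                                 tab$total[i]))
  }
  # the pairs that discriminate half-up from round-half-even
  expect_equal(percent_half_up(55, 333), 17L)   # 16.52
  expect_equal(percent_half_up(11, 31), 35L)    # 35.48
  expect_equal(percent_half_up(0, 0), 0L)
})

test_that("eNanoMapper one-to-one fixture reproduces the printed report", {
  sch <- build_reference_mit()
  counts <- rbind(data.frame(stratum = "grouping", exact = 8L),
                  enm_module_exact_counts())
  cw <- crosswalk_from_counts(sch, counts, vocab_id = "enm-synthetic")
  rep <- coverage_report(cw, "one_to_one")
  r <- rep$rows
  pick <- function(s) r[r$stratum == s, ]
  expect_equal(pick("overall")$matched, 113L)
  expect_equal(pick("overall")$percent, 34L)
  expect_equal(pick("grouping")$matched, 8L)
  expect_equal(pick("grouping")$percent, 24L)
  expect_equal(pick("content_bearing")$matched, 105L)
  expect_equal(pick("content_bearing")$percent, 35L)
  expect_equal(pick("general_information")$percent, 64L)
  expect_equal(pick("material_information")$percent, 91L)
  expect_equal(pick("biological_model_information")$percent, 23L)
  expect_equal(pick("exposure_information")$percent, 27L)
  expect_equal(pick("endpoint_readout_information")$percent, 22L)
  expect_equal(pick("analysis_statistics")$percent, 35L)
  # additivity: module matched counts sum to the content-bearing row
  mods <- r[r$stratum_type == "module", ]
  expect_equal(sum(mods$matched), pick("content_bearing")$matched)
  expect_equal(14 + 29 + 16 + 13 + 22 + 11, 105)
})

test_that("ISA-TAB fixtures reproduce the printed category rows", {
  sch <- build_reference_mit()
  # one-to-one: 5 of 33 grouping, 50 of 300 content-bearing
  counts <- data.frame(
    stratum = c("grouping", mit_modules()),
    exact = c(5L, 10L, 10L, 10L, 10L, 5L, 5L))
  cw <- crosswalk_from_counts(sch, counts, vocab_id = "isatab-synthetic")
  r <- coverage_report(cw, "one_to_one")$rows
  expect_equal(r[r$stratum == "grouping", ]$percent, 15L)
  expect_equal(r[r$stratum == "content_bearing", ]$matched, 50L)
  expect_equal(r[r$stratum == "content_bearing", ]$percent, 17L)
  expect_equal(r[r$stratum == "overall", ]$matched, 55L)
  expect_equal(r[r$stratum == "overall", ]$percent, 17L)
  # partial mode content-bearing total 257 of 300 -> 86%
  counts2 <- data.frame(
    stratum = mit_modules(),
    exact = c(5L, 5L, 11L, 8L, 15L, 6L),
    partial = c(8L, 21L, 47L, 37L, 80L, 14L))
  cw2 <- crosswalk_from_counts(sch, counts2)
  r2 <- coverage_report(cw2, "partial")$rows
  expect_equal(r2[r2$stratum == "content_bearing", ]$matched, 257L)
  expect_equal(r2[r2$stratum == "content_bearing", ]$percent, 86L)
  # the printed ISA-TAB per-module partial figures, asserted pairwise
  counts3 <- data.frame(
    stratum = mit_modules(),
    exact = 0L,
    partial = c(13L, 26L, 58L, 45L, 15L, 26L))
  r3 <- coverage_report(crosswalk_from_counts(sch, counts3),
                        "partial")$rows
  want <- c(general_information = 59L, material_information = 81L,
            biological_model_information = 84L,
            exposure_information = 94L,
            endpoint_readout_information = 15L,
            analysis_statistics = 84L)
  for (m in names(want)) {
    expect_equal(r3[r3$stratum == m, ]$percent, want[[m]], label = m)
  }
})

test_that("partial mapping lifts eNanoMapper content coverage to 77%", {
  sch <- build_reference_mit()
  counts <- enm_module_exact_counts()
  counts$partial <- c(8L, 3L, 42L, 32L, 21L, 20L)  # sums to 126
  cw <- crosswalk_from_counts(sch, counts)
  one <- coverage_report(cw, "one_to_one")
  par <- coverage_report(cw, "partial")
  expect_equal(par$rows[par$rows$stratum == "content_bearing",
                        ]$matched, 231L)
  expect_equal(par$rows[par$rows$stratum == "content_bearing",
                        ]$percent, 77L)
  delta <- compare_reports(one, par)
  expect_equal(delta$delta_percent[delta$stratum == "content_bearing"],
               77L - 35L)  # +42 points
  expect_true(all(delta$delta_percent >= 0))
})

test_that("coverage counts equal a brute-force recount over decisions", {
  sch <- build_reference_mit()
  gv <- generate_vocabulary(sch, 0.4, 0.3, 0.3, seed = 9)
  cw <- auto_crosswalk(sch, gv$vocabulary)
  for (mode in c("one_to_one", "partial")) {
    r <- coverage_report(cw, mode)$rows
    keep <- if (mode == "one_to_one") "exact" else c("exact", "partial")
    d <- cw$decisions
    sf <- cw$schema_fields
    # brute force: loop over decisions, recount every stratum
    for (i in seq_len(nrow(r))) {
      sel <- switch(r$stratum_type[i],
                    module = sf$category == "content_bearing" &
                      sf$module_id == r$stratum[i],
                    category = if (r$stratum[i] == "grouping")
                      sf$category == "grouping" else
                        sf$category == "content_bearing",
                    overall = rep(TRUE, nrow(sf)))
      expect_equal(r$matched[i], sum(d$match_type[sel] %in% keep),
                   label = paste(mode, r$stratum[i]))
      expect_equal(r$total[i], sum(sel))
    }
  }
})

test_that("count fixtures round-trip: counts(coverage(fixture)) == spec", {
  sch <- build_reference_mit()
  sizes <- c(grouping = 33L, schema_stats(sch)$per_module)
  names(sizes) <- c("grouping", mit_modules())
  set.seed(31)
  for (trial in 1:10) {
    spec <- data.frame(stratum = names(sizes),
                       exact = vapply(sizes, function(n)
                         sample(0:n, 1), integer(1)))
    spec$partial <- vapply(seq_len(nrow(spec)), function(i)
      sample(0:(sizes[[spec$stratum[i]]] - spec$exact[i]), 1), integer(1))
    cw <- crosswalk_from_counts(sch, spec)
    r1 <- coverage_report(cw, "one_to_one")$rows
    rp <- coverage_report(cw, "partial")$rows
    for (i in seq_len(nrow(spec))) {
      s <- spec$stratum[i]
      expect_equal(r1[r1$stratum == s, ]$matched, spec$exact[i],
                   label = paste("trial", trial, s, "exact"))
      expect_equal(rp[rp$stratum == s, ]$matched,
                   spec$exact[i] + spec$partial[i],
                   label = paste("trial", trial, s, "partial"))
    }
    # mode monotonicity in every stratum
    expect_true(all(rp$percent >= r1$percent))
  }
})

test_that("count fixtures reject requests exceeding the stratum size", {
  sch <- build_reference_mit()
  expect_error(crosswalk_from_counts(sch, data.frame(
    stratum = "general_information", exact = 23L)), "bounds error")
  # all-zero spec is the all-none crosswalk
  cw <- crosswalk_from_counts(sch, data.frame(stratum = "grouping",
                                              exact = 0L))
  r <- coverage_report(cw, "partial")$rows
  expect_true(all(r$percent == 0L))
})

test_that("empty strata are flagged, not errors", {
  e <- mit_schema(data.frame(name = "only grouping",
                             category = "grouping",
                             module_id = "general_information",
                             stringsAsFactors = FALSE))
  voc <- mit_vocabulary(data.frame(term_id = character(),
                                   label = character()))
  r <- coverage_report(auto_crosswalk(e, voc), "one_to_one")$rows
  cb <- r[r$stratum == "content_bearing", ]
  expect_equal(cb$percent, 0L)
  expect_true(cb$empty_stratum)
})

test_that("reports over different strata are not comparable", {
  sch <- build_reference_mit()
  tiny <- tiny_schema()
  voc <- mit_vocabulary(data.frame(term_id = character(),
                                   label = character()))
  a <- coverage_report(auto_crosswalk(sch, voc), "one_to_one")
  b <- coverage_report(auto_crosswalk(tiny, voc), "one_to_one")
  expect_error(compare_reports(a, b), "comparability")
  self <- compare_reports(a, a)
  expect_true(all(self$delta_percent == 0L))
})
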
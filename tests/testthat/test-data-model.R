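# Claims record format, vocabulary, grouper, and cohort selection.

test_that("claims JSONL round-trips losslessly and enforces invariants", {
  sim <- small_sim()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_claims(sim$records, path)
  back <- read_claims(path)
  expect_identical(lapply(back, unclass), lapply(sim$records, unclass))

  # empty corpus -> empty readable file
  write_claims(list(), path)
  expect_length(read_claims(path), 0L)

  # unicode ids survive
  r <- patient_record("pätient-1", "U", 2010L,
                      list(visit("2015-05-05", "IP", dx = "X")))
  write_claims(list(r), path)
  expect_identical(read_claims(path)[[1]]$patient_id, "pätient-1")

  # date-shuffled visits are sorted on construction/load
  lines <- paste0('{"patient_id":"a","gender":"M","birth_year":2008,',
                  '"visits":[{"date":"2014-03-01","type":"OP","dx":["B"]},',
                  '{"date":"2014-01-01","type":"IP","dx":["A"]}]}')
  writeLines(lines, path)
  rec <- read_claims(path)[[1]]
  expect_identical(vapply(rec$visits, `[[`, character(1), "dx"), c("A", "B"))

  # malformed lines name the line and the problem
  writeLines('{"gender":"M"}', path)
  expect_error(read_claims(path), "line 1.*patient_id")
  writeLines(paste0('{"patient_id":"a","gender":"M","birth_year":2008,',
                    '"visits":[{"date":"2014-01-01","type":"ER","dx":["A"]}]}'),
              path)
  expect_error(read_claims(path), "visit_type")
  writeLines('{"patient_id":"a","gender":"M","birth_year":2008,"visits":[]}', path)
  expect_error(read_claims(path), "empty visit list")
})

test_that("vocabulary indexing is deterministic, frequency-ordered, min_count-aware", {
  mk <- function(codes) patient_record("p", "M", 2008L, list(
    visit("2014-01-01", "OP", dx = codes)))
  recs <- list(mk(c("a", "b")), mk("a"))
  v1 <- build_vocabulary(recs, min_count = 1L)
  # a (freq 2) before b (freq 1), OOV last
  expect_lt(v1$channels$DIAG[["a"]], v1$channels$DIAG[["b"]])
  expect_identical(unname(v1$channels$DIAG[["<OOV>"]]), 2L)
  expect_identical(sort(unname(v1$channels$DIAG)), 0:2)

  v2 <- build_vocabulary(recs, min_count = 2L)
  expect_false("b" %in% names(v2$channels$DIAG))
  expect_identical(unname(claimformer:::vocab_index(v2, "DIAG", "b")),
                   unname(v2$channels$DIAG[["<OOV>"]]))

  v0 <- build_vocabulary(list(), min_count = 1L)
  expect_identical(names(v0$channels$DIAG), "<OOV>")

  # determinism + TSV round trip
  sim <- small_sim()
  va <- build_vocabulary(sim$records, 2L)
  vb <- build_vocabulary(sim$records, 2L)
  expect_identical(va, vb)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(va, tf)
  expect_identical(read_vocabulary(tf), va)
  expect_identical(claimformer:::vocab_fingerprint(read_vocabulary(tf)),
                   claimformer:::vocab_fingerprint(va))
})

test_that("grouper maps every code to exactly one category, OOV for unknowns", {
  g <- category_grouper(data.frame(
    channel = c("DIAG", "DIAG"), code = c("493.00", "493.01"),
    category = c("CCS:28", "CCS:28")))
  expect_identical(map_code_to_category(g, "DIAG", "493.00"), "CCS:28")
  expect_identical(map_code_to_category(g, "DIAG", "999.99"), "<OOV>")
  # identity grouper
  gi <- category_grouper(data.frame(channel = "DIAG", code = "X", category = "X"))
  expect_identical(map_code_to_category(gi, "DIAG", "X"), "X")
  # duplicate mapping rejected
  expect_error(category_grouper(data.frame(
    channel = "DIAG", code = c("a", "a"), category = c("c1", "c2"))), "more than one")
  # TSV round trip
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_grouper(g, tf)
  expect_identical(read_grouper(tf)$maps, g$maps)

  # simulator grouper covers every emitted code
  sim <- small_sim()
  for (ch in c("DIAG", "PROC", "DRUG")) {
    field <- c(DIAG = "dx", PROC = "px", DRUG = "rx")[[ch]]
    codes <- unique(unlist(lapply(sim$records, function(r)
      unlist(lapply(r$visits, `[[`, field)))))
    cats <- map_code_to_category(sim$grouper, ch, codes)
    expect_false(any(cats == "<OOV>"))
  }
})

test_that("cohort selection truncates cases, samples controls, reproduces", {
  # 163 cases : 326 controls, the canonical 1:2 design
  set.seed(5)
  mk <- function(id, event_at = NA, n = 4L) {
    vs <- lapply(seq_len(n), function(i)
      visit(16000L + 30L * i, "OP",
            dx = if (!is.na(event_at) && i == event_at) c("C", "EVT") else "C"))
    patient_record(id, "F", 2006L, vs)
  }
  cases <- lapply(1:163, function(i) mk(paste0("case", i), event_at = sample(2:4, 1)))
  ctrls <- lapply(1:400, function(i) mk(paste0("ctrl", i)))
  pred <- function(v) "EVT" %in% v$dx
  coh <- select_cohort(c(cases, ctrls), pred, control_ratio = 2, seed = 9L)
  labs <- vapply(coh, `[[`, integer(1), "label")
  expect_identical(sum(labs == 1L), 163L)
  expect_identical(sum(labs == 0L), 326L)
  # no positive retains an event visit
  for (ex in coh[labs == 1L])
    expect_false(any(vapply(ex$record$visits, pred, logical(1))))
  # determinism
  coh2 <- select_cohort(c(cases, ctrls), pred, control_ratio = 2, seed = 9L)
  expect_identical(coh, coh2)

  # a case whose only flagged visit is its first is dropped and counted
  early <- mk("early", event_at = 1L)
  coh3 <- select_cohort(c(cases, list(early), ctrls), pred, 2, seed = 9L)
  expect_identical(attr(coh3, "dropped_cases"), 1L)
  expect_identical(attr(coh3, "n_cases"), 163L)

  # demanding more controls than available errors with counts
  expect_error(select_cohort(c(cases, ctrls[1:10]), pred, 2, seed = 1L),
               "326 controls but only 10")
})
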
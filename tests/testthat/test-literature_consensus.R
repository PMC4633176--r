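test_that("name normalization applies aliases, collapses agreeing duplicates", {
  aliases <- mirna_alias_table()
  calls <- data.frame(study_id = "s1", tumor_type = "PTC",
                      mirna = c("miR-221-3p", "miR-146b"),
                      direction = "up", stringsAsFactors = FALSE)
  out <- normalize_mirna_names(calls, aliases)
  expect_equal(out$mirna, c("miR-221-3p", "miR-146b-5p"))

  # same study reports the alias and the canonical name with one direction
  dup <- data.frame(study_id = "s1", tumor_type = "PTC",
                    mirna = c("miR-146b", "miR-146b-5p"),
                    direction = "up", stringsAsFactors = FALSE)
  out <- normalize_mirna_names(dup, aliases)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mirna, "miR-146b-5p")
})

test_that("normalization rejects post-rename direction conflicts and unknown names", {
  aliases <- mirna_alias_table()
  conflict <- data.frame(study_id = "s1", tumor_type = "PTC",
                         mirna = c("miR-21", "miR-21-5p"),
                         direction = c("up", "down"),
                         stringsAsFactors = FALSE)
  expect_error(normalize_mirna_names(conflict, aliases), "conflict")

  unk <- data.frame(study_id = "s1", tumor_type = "PTC",
                    mirna = "miR-99999", direction = "up",
                    stringsAsFactors = FALSE)
  expect_error(normalize_mirna_names(unk, aliases), "miR-99999")
  expect_warning(out <- normalize_mirna_names(unk, aliases, strict = FALSE),
                 "miR-99999")
  expect_equal(out$mirna, "miR-99999")
})

test_that("tallies count distinct studies per direction and conserve calls", {
  calls <- thyroid_mirna_calls()
  tal <- tally_calls(calls)
  expect_equal(sum(tal$n_reports), nrow(calls))

  r221 <- tal[tal$mirna == "miR-221-3p" & tal$tumor_type == "PTC", ]
  expect_equal(c(r221$n_up, r221$n_down), c(9L, 0L))
  r26a <- tal[tal$mirna == "miR-26a-5p" & tal$tumor_type == "PTC", ]
  expect_equal(c(r26a$n_up, r26a$n_down), c(1L, 2L))

  empty <- calls[0, ]
  expect_equal(nrow(tally_calls(empty)), 0L)
})

test_that("the packaged survey yields the known PTC and ATC consensus panels", {
  tal <- select_consensus(tally_calls(thyroid_mirna_calls()), 3)
  ptc <- tal[tal$tumor_type == "PTC", ]
  expect_setequal(
    ptc$mirna[ptc$status == "selected"],
    c("miR-146b-5p", "miR-221-3p", "miR-222-3p", "miR-181b-5p",
      "miR-155-5p", "miR-34a-5p", "miR-138-5p", "miR-187-3p",
      "miR-224-5p", "miR-31-5p"))
  expect_equal(sum(ptc$n_reports >= 3), 12L)
  expect_setequal(ptc$mirna[ptc$status == "inconsistent"],
                  c("miR-26a-5p", "miR-34b-5p"))

  atc <- tal[tal$tumor_type == "ATC" & tal$status == "selected", ]
  expect_setequal(atc$mirna[atc$direction == "up"],
                  c("miR-221-3p", "miR-222-3p"))
  expect_setequal(atc$mirna[atc$direction == "down"],
                  c("let-7c", "miR-125b-5p", "miR-26a-5p", "miR-30a-5p",
                    "miR-30d"))
})

test_that("a mixed-direction miRNA with enough reports is inconsistent, never selected", {
  calls <- data.frame(study_id = c("s1", "s2", "s3"), tumor_type = "PTC",
                      mirna = "m1", direction = c("up", "up", "down"),
                      stringsAsFactors = FALSE)
  tal <- select_consensus(tally_calls(calls), 3)
  expect_equal(tal$status, "inconsistent")
  expect_true(is.na(tal$direction))
  expect_error(select_consensus(tal, 0), "min_studies")
})

test_that("selection agrees with a brute-force tuple filter on random call matrices", {
  set.seed(42)
  for (i in 1:20) {
    calls <- rand_calls(n_studies = sample(3:12, 1),
                        n_mirnas = sample(5:50, 1),
                        n_calls = sample(20:120, 1))
    m <- sample(1:4, 1)
    got <- select_consensus(tally_calls(calls), m)
    want <- oracle_select(calls, m)
    key <- function(d) paste(d$mirna, d$tumor_type)
    idx <- match(key(got), key(want))
    expect_false(anyNA(idx))
    expect_equal(got$n_up, want$n_up[idx])
    expect_equal(got$n_down, want$n_down[idx])
    expect_equal(got$status, want$status[idx])
    # partition: every tallied miRNA gets exactly one status
    expect_true(all(got$status %in%
                      c("selected", "inconsistent", "insufficient")))
  }
})

test_that("raising the study threshold never adds a selected miRNA", {
  set.seed(7)
  calls <- rand_calls(n_studies = 8, n_mirnas = 30, n_calls = 150)
  tal <- tally_calls(calls)
  prev <- NULL
  for (m in 1:6) {
    sel <- select_consensus(tal, m)
    cur <- paste(sel$mirna, sel$tumor_type)[sel$status == "selected"]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("tally ordering is a stable documented sort, identical across runs", {
  calls <- thyroid_mirna_calls()
  t1 <- tally_calls(calls)
  t2 <- tally_calls(calls[sample.int(nrow(calls)), ])
  expect_identical(t1, t2)
  ord <- order(t1$tumor_type, -t1$n_reports, t1$mirna, method = "radix")
  expect_identical(ord, seq_len(nrow(t1)))
})

test_that("shared miRNAs require at least one report in each tumor type", {
  tal <- tally_calls(thyroid_mirna_calls())
  shared <- shared_mirnas(tal)
  expect_true("miR-221-3p" %in% shared)
  expect_false("miR-34a-5p" %in% shared)
  expect_length(shared_mirnas(tal[0, ]), 0)
})
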
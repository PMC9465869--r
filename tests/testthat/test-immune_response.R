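test_that("stimulation index is the ratio of mean stimulated to mean unstimulated counts", {
  a <- proliferation_assay("P1", "week7", "mix",
                           stimulated_counts = c(3000, 3100, 2900),
                           unstimulated_counts = c(1000, 1000, 1000))
  expect_equal(stimulation_index(a), 3.0)
  same <- proliferation_assay("P1", "week7", "mix",
                              stimulated_counts = c(500, 600, 700),
                              unstimulated_counts = c(500, 600, 700))
  expect_equal(stimulation_index(same), 1)
  # scale invariance
  scaled <- proliferation_assay("P1", "week7", "mix",
                                stimulated_counts = 17 * c(3000, 3100, 2900),
                                unstimulated_counts = 17 * c(1000, 1000, 1000))
  expect_equal(stimulation_index(scaled), 3.0)
})

test_that("invalid assays are flagged rather than producing infinite SI", {
  zero <- proliferation_assay("P1", "week7", "mix",
                              stimulated_counts = c(100, 100, 100),
                              unstimulated_counts = c(0, 0, 0))
  expect_warning(si <- stimulation_index(zero), "invalid")
  expect_true(is.na(si))
  expect_error(proliferation_assay("P1", "week7", "mix",
                                   stimulated_counts = c(1, 2),
                                   unstimulated_counts = c(1, 2, 3)),
               "3 replicates")
})

test_that("the response caller applies the inclusive SI >= 3 rule per post-baseline assay", {
  mk <- function(tp, si) proliferation_assay(
    "P1", tp, "mix", stimulated_counts = rep(1000 * si, 3),
    unstimulated_counts = rep(1000, 3))
  # below threshold everywhere -> non-responder
  neg <- call_response(list(mk("baseline", 1.1), mk("week7", 2.3)))
  expect_false(neg$responder)
  expect_equal(neg$max_si, 2.3)
  # one strong response -> responder
  pos <- call_response(list(mk("week7", 60)))
  expect_true(pos$responder)
  expect_equal(pos$max_si, 60)
  # exact boundary is positive
  expect_true(call_response(list(mk("week7", 3)))$responder)
  # baseline SI alone never triggers a call
  base_only <- call_response(list(mk("baseline", 50)))
  expect_false(base_only$evaluable)
  expect_true(is.na(base_only$responder))
  # evaluation window excludes late assays
  late <- call_response(list(mk("week7", 1.5), mk("week40", 9)),
                        window = "week7")
  expect_false(late$responder)
})

test_that("the relative-to-baseline variant scores the rise over the baseline SI", {
  mk <- function(tp, si) proliferation_assay(
    "P1", tp, "mix", stimulated_counts = rep(1000 * si, 3),
    unstimulated_counts = rep(1000, 3))
  # baseline SI 2, week7 SI 5: ratio 2.5 < 3 -> negative under the
  # relative rule, positive under the per-sample rule
  assays <- list(mk("baseline", 2), mk("week7", 5))
  expect_true(call_response(assays)$responder)
  expect_false(call_response(assays, relative_to_baseline = TRUE)$responder)
})

test_that("responder calls are monotone in the threshold", {
  mk <- function(si) proliferation_assay(
    "P9", "week7", "mix", stimulated_counts = rep(100 * si, 3),
    unstimulated_counts = rep(100, 3))
  sis <- c(1.2, 2.5, 3.5, 8, 20)
  for (thr in c(2, 3, 5)) {
    lo <- sum(vapply(sis, function(s)
      call_response(list(mk(s)), threshold = thr)$responder, logical(1)))
    hi <- sum(vapply(sis, function(s)
      call_response(list(mk(s)), threshold = thr + 1)$responder,
      logical(1)))
    expect_gte(lo, hi)
  }
})

test_that("cohort summary excludes non-evaluable patients from the denominator", {
  mk_call <- function(id, si, evaluable = TRUE) {
    tp <- if (evaluable) "week7" else "baseline"
    call_response(list(proliferation_assay(
      id, tp, "mix", stimulated_counts = rep(1000 * si, 3),
      unstimulated_counts = rep(1000, 3))))
  }
  sis <- c(2.3, 3.5, 5, 7, 9, 11.5, 15, 20, 30, 45, 60)
  calls <- c(lapply(seq_along(sis),
                    function(i) mk_call(paste0("N", i), sis[i])),
             list(mk_call("N12", 10, evaluable = FALSE)))
  s <- cohort_summary(calls)
  expect_equal(s$n_evaluable, 11)
  expect_equal(s$n_responders, 10)
  expect_equal(s$responder_pct, 91)
  expect_equal(s$median_max_si, 11.5)
  expect_equal(s$range_max_si, c(2.3, 60))

  none <- cohort_summary(lapply(1:5, function(i)
    mk_call(paste0("X", i), 1.5)))
  expect_equal(none$responder_pct, 0)
  expect_error(cohort_summary(list(mk_call("Y", 5, evaluable = FALSE))),
               "no evaluable")
})

test_that("objective response rate counts CR and PR over all enrolled", {
  bor <- c("CR", "PR", "PR", "PR", "SD", "SD", "SD", "SD", "SD", "PD",
           "PD", "NE")
  orr <- objective_response_rate(bor)
  expect_equal(orr$n_enrolled, 12)
  expect_equal(orr$n_responses, 4)
  expect_equal(orr$orr_pct, 33)
})

test_that("long-format assay CSVs round-trip through read_assays", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    patient_id = "P1", timepoint = "week7",
    peptide = rep(c("mix", "p725"), each = 6),
    condition = rep(c("stimulated", "unstimulated"), each = 3, times = 2),
    count = c(900, 1000, 1100, 100, 100, 100, 290, 300, 310, 100, 95, 105))
  write.csv(df, path, row.names = FALSE)
  assays <- read_assays(path)
  expect_equal(length(assays), 2)
  expect_equal(stimulation_index(assays[[1]]), 10)
  call <- call_response(assays)
  expect_true(call$responder)
  expect_equal(sort(names(call$per_peptide_si)), c("mix", "p725"))
})
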
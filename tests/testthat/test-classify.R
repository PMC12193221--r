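test_that("larval query matches its species uniquely at 0.10 degC", {
  res <- classify_sample(77.50, hrm_panel("cox2_larva"), query_id = "larva")
  expect_equal(res$status, "match")
  expect_equal(res$assigned_species, "P. dux")
  expect_equal(res$delta_tm, 0.10)
  expect_equal(nrow(res$candidates), 1L)
})

test_that("a 76.73 query against the ten-species panel is ambiguous", {
  res <- classify_sample(76.73, hrm_panel("cox2"))
  expect_equal(res$status, "ambiguous")
  expect_equal(res$candidates$species, c("B. peregrina", "H. ligurriens"))
  expect_equal(res$candidates$delta_tm, c(0.00, 0.03))
  expect_equal(res$delta_tm, 0.00)
})

test_that("single-peak query vs a multi-peak signature is partial", {
  res <- classify_sample(74.70, hrm_panel("c1"),
                         classifier_config(peak_match_mode = "full_signature"))
  expect_equal(res$status, "partial_signature")
  expect_equal(res$assigned_species, "S. princeps")
  expect_equal(res$delta_tm, 0.05)

  # the full three-peak signature matches outright
  res3 <- classify_sample(
    structure(data.frame(tm = c(74.75, 77.65, 80.32),
                         height = c(0.3, 0.5, 0.25),
                         prominence = c(0.3, 0.5, 0.25)),
              class = c("PeakSet", "data.frame")),
    hrm_panel("c1"),
    classifier_config(peak_match_mode = "full_signature"))
  expect_equal(res3$status, "match")
  expect_equal(res3$assigned_species, "S. princeps")
})

test_that("queries far from every panel species come back novel", {
  res <- classify_sample(70.00, hrm_panel("cox2"))
  expect_equal(res$status, "novel")
  expect_true(is.na(res$assigned_species))
  expect_equal(nrow(res$candidates), 0L)
  empty <- reference_panel("none", "x", character(0), list())
  expect_equal(classify_sample(76.5, empty)$status, "novel")
})

test_that("separations of exactly the threshold count as distinct", {
  p <- reference_panel("b", "x", c("near", "boundary"),
                       list(76.60, 76.88))
  res <- classify_sample(76.73, p)
  # 0.13 below threshold -> candidate; exactly 0.15 -> distinct
  expect_equal(res$status, "match")
  expect_equal(res$assigned_species, "near")
  expect_false("boundary" %in% res$candidates$species)
})

test_that("panel discriminability audits match brute-force pair counts", {
  cox2 <- hrm_panel("cox2")
  ind <- pairwise_discriminability(cox2)
  expect_equal(nrow(ind), 5L)
  # brute force over all 45 pairs with the boundary-is-distinct rule
  tm <- principal_peaks(cox2)
  brute <- sum(outer(tm, tm, function(a, b) abs(a - b))[lower.tri(diag(10))]
               < 0.15 - 1e-9)
  expect_equal(nrow(ind), brute)
  expect_true(all(ind$delta_tm < 0.15))

  # single-peak subset of the six-species COXI panel: one clash (0.07)
  c1 <- hrm_panel("c1")
  singles <- lengths(c1$peaks) == 1L
  sub <- reference_panel("c1s", "C1", c1$species[singles],
                         c1$peaks[singles], c1$batch[singles])
  ind1 <- pairwise_discriminability(sub)
  expect_equal(nrow(ind1), 1L)
  expect_setequal(c(ind1$species_a, ind1$species_b),
                  c("P. dux", "P. scopariiformis"))
  expect_equal(ind1$delta_tm, 0.07)

  # invariant under species reordering
  perm <- sample(seq_along(cox2$species))
  shuffled <- reference_panel("perm", "x", cox2$species[perm],
                              cox2$peaks[perm], cox2$batch[perm])
  ind_p <- pairwise_discriminability(shuffled)
  key <- function(df) sort(paste(df$species_a, df$species_b))
  expect_equal(key(ind_p), key(ind))
})

test_that("replicate drift between re-extractions is summarized per species", {
  re <- replicate_error(hrm_panel("cox2"), hrm_panel("cox2_repeat"))
  expect_equal(nrow(re$per_species), 5L)
  expect_equal(re$min_abs, 0.02)
  expect_equal(re$max_abs, 0.10)
  expect_equal(re$n_up, 5L)  # every species drifted upward
  expect_setequal(re$only_a,
                  c("C. megacephala", "H. ligurriens", "A. rufifacies",
                    "S. princeps", "M. domestica"))
  expect_equal(re$only_b, character(0))

  same <- replicate_error(hrm_panel("cox2"), hrm_panel("cox2"))
  expect_true(all(same$per_species$abs_delta == 0))
  expect_error(replicate_error(hrm_panel("cox2_repeat"),
                               reference_panel("z", "x", "other sp",
                                               list(70))),
               "share no species")
})

test_that("cross-batch comparison warns but classification still returns", {
  expect_identical(batch_consistency_guard("run1", "run1"), "pass")
  expect_warning(batch_consistency_guard("run2", "run1"),
                 class = "hrmid_batch_warning")
  expect_warning(batch_consistency_guard(NA, "run1"), "batch unknown")
  res <- NULL
  expect_warning(
    res <- classify_sample(77.50, hrm_panel("cox2_larva"),
                           query_batch = "otherrun"),
    class = "hrmid_batch_warning")
  expect_equal(res$status, "match")
})

test_that("candidate sets grow monotonically with the threshold", {
  set.seed(17)
  for (i in 1:20) {
    tms <- round(runif(8, 74, 79), 2)
    p <- reference_panel("m", "x", paste0("s", 1:8), as.list(tms))
    q <- round(runif(1, 74, 79), 2)
    prev <- character(0)
    for (thr in c(0.05, 0.15, 0.5, 1.5)) {
      res <- classify_sample(q, p, classifier_config(thr))
      expect_true(all(prev %in% res$candidates$species))
      prev <- res$candidates$species
    }
  }
})

test_that("classification is invariant to panel order and reports ties", {
  p <- reference_panel("t", "x", c("a", "b", "c"),
                       list(76.60, 76.80, 78.00))
  q <- 76.70  # exactly 0.10 from both a and b
  res <- classify_sample(q, p)
  expect_equal(res$status, "ambiguous")
  expect_setequal(res$candidates$species, c("a", "b"))
  perm <- reference_panel("t2", "x", c("c", "b", "a"),
                          list(78.00, 76.80, 76.60))
  res2 <- classify_sample(q, perm)
  expect_equal(res2$candidates, res$candidates)
})

test_that("classification results serialize to JSON", {
  res <- classify_sample(76.73, hrm_panel("cox2"), query_id = "q1")
  f <- withr::local_tempfile(fileext = ".json")
  write_classification_json(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$status, "ambiguous")
  expect_equal(back$candidates$species, c("B. peregrina", "H. ligurriens"))
})
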
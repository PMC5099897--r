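# Build a mirna_table from a named list of per-miRNA sample rows.
make_mirna <- function(rows, conditions = c(s1 = "A", s2 = "A",
                                            s3 = "B", s4 = "B"),
                       spike_ids = character()) {
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(names(rows), names(conditions))
  mirna_table(mat, conditions, spike_ids)
}

test_that("miRNA tables validate their design", {
  expect_error(make_mirna(list(m1 = c(1, 2, 3, 4)),
                          conditions = c(s1 = "A", s2 = "A", s3 = "A",
                                         s4 = "A")),
               "two conditions")
  expect_error(make_mirna(list(m1 = c(1, -2, 3, 4))), "finite and >= 0")
  expect_error(make_mirna(list(m1 = c(1, 2, 3, 4)), spike_ids = "nope"),
               "subset")
})

test_that("spike normalization equalizes spike means and preserves ranks", {
  tab <- make_mirna(list(spike1 = c(10, 20, 10, 40),
                         m1 = c(100, 60, 50, 80),
                         m2 = c(5, 30, 2, 4)),
                    spike_ids = "spike1")
  norm <- normalize_by_spike(tab)
  spike_means <- colMeans(norm$intensities["spike1", , drop = FALSE])
  expect_true(all(abs(spike_means - mean(spike_means)) < 1e-12))
  # sample 2 spikes at 2x sample 1: its column is halved relative to input
  expect_equal(norm$intensities["m1", "s2"] / norm$intensities["m1", "s1"],
               (60 / 100) / 2)
  # within-sample rank order is unchanged
  for (s in colnames(tab$intensities)) {
    expect_identical(order(norm$intensities[, s]),
                     order(tab$intensities[, s]))
  }
  # already-equal spikes leave the table unchanged
  eq <- make_mirna(list(spike1 = c(10, 10, 10, 10), m1 = c(1, 2, 3, 4)),
                   spike_ids = "spike1")
  expect_equal(normalize_by_spike(eq)$intensities, eq$intensities)
  # zero spike intensity in a sample is an error
  z <- make_mirna(list(spike1 = c(10, 0, 10, 10), m1 = c(1, 2, 3, 4)),
                  spike_ids = "spike1")
  expect_error(normalize_by_spike(z), "s2")
  expect_error(normalize_by_spike(make_mirna(list(m1 = c(1, 2, 3, 4)))),
               "no spike")
})

test_that("presence detection applies the floor and replicate rule", {
  tab <- make_mirna(list(m1 = c(5, 5, 0, 0),    # A only
                         m2 = c(5, 0, 5, 5),    # one A replicate below floor
                         m3 = c(0, 0, 0, 0),
                         spike1 = c(9, 9, 9, 9)),
                    spike_ids = "spike1")
  pres <- detect_present(tab, detection_floor = 1)
  expect_equal(pres$A, "m1")        # m2 misses the all-replicates default
  expect_equal(pres$B, "m2")
  # relaxing min_samples admits m2 in A; spikes never appear
  pres1 <- detect_present(tab, detection_floor = 1, min_samples = 1)
  expect_setequal(pres1$A, c("m1", "m2"))
  expect_false(any(grepl("spike", unlist(pres1))))
  # floor above the global maximum empties both sets
  hi <- detect_present(tab, detection_floor = 100)
  expect_length(hi$A, 0)
  expect_length(hi$B, 0)
  # all-zero data at floor 0 is absent everywhere (strict >)
  zz <- detect_present(make_mirna(list(m3 = c(0, 0, 0, 0))), 0)
  expect_length(zz$A, 0)
})

test_that("condition comparison computes set partition and fold ratios", {
  tab <- make_mirna(list(m1 = c(20, 22, 1, 1),   # means 21 vs 1
                         m2 = c(3, 3, 1, 1),
                         m3 = c(2, 2, 2, 2),
                         m4 = c(5, 5, 0, 0),     # A only -> Inf sentinel
                         m5 = c(0, 0, 4, 4)))    # B only -> ratio 0
  cmp <- compare_conditions(tab, detection_floor = 0.5)
  expect_equal(unname(cmp$fold_ratio["m1"]), 21)
  expect_equal(unname(cmp$fold_ratio["m2"]), 3)
  expect_equal(unname(cmp$fold_ratio["m3"]), 1)
  expect_true(is.infinite(cmp$fold_ratio["m4"]))
  expect_equal(unname(cmp$fold_ratio["m5"]), 0)
  expect_equal(cmp$unique_a, "m4")
  expect_equal(cmp$unique_b, "m5")
  expect_setequal(cmp$shared, c("m1", "m2", "m3"))
  # the set identity behind unique/shared bookkeeping
  expect_equal(length(cmp$present_a) - length(cmp$unique_a),
               length(cmp$shared))
  expect_equal(length(cmp$present_b) - length(cmp$unique_b),
               length(cmp$shared))

  # m1 counts at >2 and >10; m2 only at >2; sentinels never counted
  counts <- count_enriched(cmp, c(2, 10))
  expect_equal(unname(counts), c(2L, 1L))
  # opposite direction: only m5's reciprocal is excluded (infinite), m3 is 1
  counts_b <- count_enriched(cmp, c(2, 10), "b_over_a")
  expect_equal(unname(counts_b), c(0L, 0L))
  expect_error(count_enriched(cmp, c(1, 2)), "> 1")

  # identical condition means: all ratios 1, nothing enriched either way
  flat <- compare_conditions(make_mirna(list(m1 = c(4, 4, 4, 4),
                                             m2 = c(7, 7, 7, 7))))
  expect_true(all(flat$fold_ratio == 1))
  expect_true(all(count_enriched(flat) == 0))
  expect_true(all(count_enriched(flat, direction = "b_over_a") == 0))
})

test_that("swapping condition labels inverts finite ratios", {
  set.seed(21)
  mat <- matrix(rexp(40 * 4, 1 / 50) + 1, 40, 4,
                dimnames = list(paste0("m", 1:40), paste0("s", 1:4)))
  tab <- mirna_table(mat, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  r1 <- compare_conditions(tab)$fold_ratio
  r2 <- compare_conditions(tab, condition_a = "B")$fold_ratio
  expect_equal(r2, 1 / r1)
})

test_that("the unique/shared set identity holds on random tables", {
  set.seed(33)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    mat <- matrix(rbinom(n * 4, 1, 0.6) * rexp(n * 4, 1 / 20), n, 4,
                  dimnames = list(paste0("m", 1:n), paste0("s", 1:4)))
    tab <- mirna_table(mat, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
    cmp <- compare_conditions(tab, detection_floor = 0.5,
                              min_samples = sample(1:2, 1))
    expect_equal(length(cmp$present_a) - length(cmp$unique_a),
                 length(cmp$present_b) - length(cmp$unique_b))
    expect_setequal(cmp$shared, intersect(cmp$present_a, cmp$present_b))
    # threshold monotonicity
    cts <- count_enriched(cmp, c(2, 5, 10))
    expect_true(all(diff(cts) <= 0))
  }
})

test_that("the miRNA pipeline runs from files and writes its summary", {
  cfg <- simulation_config(seed = 4, noise_sigma = 0)
  mir <- generate_mirna_tables(cfg)
  d <- tempfile(); dir.create(d)
  write_mirna_table(mir$table, file.path(d, "int.tsv"),
                    file.path(d, "samples.tsv"))
  res <- run_mirna_pipeline(file.path(d, "int.tsv"),
                            file.path(d, "samples.tsv"),
                            file.path(d, "out"), detection_floor = 1)
  smry <- jsonlite::read_json(file.path(d, "out", "mirna_summary.json"),
                              simplifyVector = TRUE)
  expect_equal(smry$n_unique_a, 104)
  expect_equal(smry$n_unique_b, 15)
  expect_equal(smry$enriched_a_over_b$`>2`, 450)
  expect_equal(smry$enriched_a_over_b$`>10`, 34)
  expect_equal(smry$enriched_b_over_a$`>2`, 147)
  expect_equal(smry$enriched_b_over_a$`>10`, 14)
  expect_true(file.exists(file.path(d, "out", "manifest.json")))
})
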
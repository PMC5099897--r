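test_that("protein mapping uses first-hit preference and partitions input", {
  atl <- expression_atlas(c("c1", "c2"),
                          matrix(1, 2, 2, dimnames = list(c("gY", "gZ"),
                                                          NULL)))
  prot <- data.frame(protein_id = c("P1", "P2", "P3"),
                     stringsAsFactors = FALSE)
  prot$gene_ids <- list(c("gX", "gY"), character(0), c("gZ", "gY"))
  res <- map_proteins(prot, atl)
  expect_equal(res$mapped$gene_id[res$mapped$protein_id == "P1"], "gY")
  expect_equal(res$mapped$gene_id[res$mapped$protein_id == "P3"], "gZ")
  expect_equal(res$unmapped, "P2")
  expect_equal(nrow(res$mapped) + length(res$unmapped), nrow(prot))
})

test_that("the median-multiple call rule matches hand-computed cases", {
  # uniform vector: nothing exceeds 3x its own median
  expect_false(any(call_categories(c(5, 5, 5, 5), 3)$called))
  # median 1, cutoff 3: only the first category is called
  cs <- call_categories(c(31, 1, 1, 1, 1), 3)
  expect_equal(which(cs$called), 1L)
  expect_equal(cs$median, 1)
  expect_equal(unname(cs$ratio[1]), 31)
  # zero median falls back to the absolute floor
  cs0 <- call_categories(c(0, 0, 0, 9), 3, expression_floor = 1)
  expect_equal(which(cs0$called), 4L)
  expect_true(all(is.na(cs0$ratio)))
  # strictness: exactly 3x the median is NOT a call
  expect_false(call_categories(c(3, 1, 1), 3)$called[1])
  expect_error(call_categories(c(1, 2), threshold_multiple = 0), "positive")
})

test_that("call rule agrees with an independent oracle on random vectors", {
  set.seed(101)
  for (i in 1:500) {
    n <- sample(3:62, 1)
    v <- round(rexp(n, 1 / 50), 2)
    if (i %% 4 == 0) v[sample(n, ceiling(n * 0.7))] <- 0  # zero-median cases
    m <- sample(c(1.5, 3, 6), 1)
    expect_identical(unname(call_categories(v, m, 1)$called),
                     unname(call_oracle(v, m, 1)))
  }
})

test_that("call sets are nested as the threshold multiple increases", {
  set.seed(55)
  for (i in 1:100) {
    v <- rexp(20, 1 / 10)
    prev <- call_categories(v, 1.5)$called
    for (m in c(3, 6, 12)) {
      cur <- call_categories(v, m)$called
      expect_true(all(!cur | prev))  # cur subset of prev
      prev <- cur
    }
  }
})

test_that("call sets are invariant under positive rescaling", {
  set.seed(77)
  for (i in 1:50) {
    v <- rexp(15, 1 / 10) + 0.01  # positive median
    for (c in c(0.001, 0.5, 7, 1e4)) {
      expect_identical(call_categories(v * c, 3)$called,
                       call_categories(v, 3)$called)
    }
  }
})

test_that("source-group profiles derive the right partition labels", {
  map <- source_map(c(liver = "peripheral_tissues",
                      kidney = "peripheral_tissues",
                      CD4 = "T_cells", B220 = "B_cells",
                      misc = "unassigned"),
                    c("peripheral_tissues", "T_cells", "B_cells"))
  p <- profile_source_groups(c("liver", "kidney"), map)
  expect_equal(p$partition_label, "exclusive:peripheral_tissues")
  expect_equal(profile_source_groups(character(0), map)$partition_label,
               "none")
  expect_equal(profile_source_groups(c("liver", "CD4", "B220"),
                                     map)$partition_label, "all_groups")
  expect_equal(profile_source_groups(c("liver", "CD4"), map)$partition_label,
               "mixed:T_cells+peripheral_tissues")
  # unassigned categories never contribute a group
  expect_equal(profile_source_groups("misc", map)$partition_label, "none")
  expect_error(profile_source_groups("unknown_cat", map), "unknown_cat")
})

test_that("the Venn census matches examples and the enumeration oracle", {
  s <- summarize_venn(list("A", c("A", "B"), character(0)), c("A", "B"))
  expect_equal(unname(s$region_counts["A"]), 1L)
  expect_equal(unname(s$region_counts["A+B"]), 1L)
  expect_equal(s$none, 1L)
  expect_equal(s$total_input, 3)

  # empty input: every region zero
  s0 <- summarize_venn(list(), c("A", "B", "C"))
  expect_true(all(s0$region_counts == 0))

  # one profile per subset of 3 groups: every region counts exactly 1
  groups <- c("A", "B", "C")
  subsets <- c(list(character(0)),
               unlist(lapply(1:3, function(k) {
                 apply(combn(groups, k), 2, identity, simplify = FALSE)
               }), recursive = FALSE))
  s1 <- summarize_venn(subsets, groups)
  expect_true(all(s1$region_counts == 1L))
  expect_equal(sum(s1$region_counts), 8)

  # random profiles over 5 groups agree with the brute-force oracle
  set.seed(5)
  g5 <- paste0("grp", 1:5)
  profiles <- lapply(1:100, function(i) sample(g5, sample(0:5, 1)))
  expect_identical(summarize_venn(profiles, g5)$region_counts,
                   venn_oracle(profiles, g5))
})

test_that("Venn counts conserve the input and exclusivity arithmetic holds", {
  set.seed(9)
  for (i in 1:25) {
    g <- paste0("G", seq_len(sample(2:5, 1)))
    n <- sample(0:80, 1)
    profiles <- lapply(seq_len(n), function(j) sample(g, sample(0:length(g),
                                                                1)))
    unmapped <- sample(0:10, 1)
    s <- summarize_venn(profiles, g, unmapped)
    expect_equal(s$unmapped + sum(s$region_counts), n + unmapped)
    # two-group identity: total_in_X - exclusive_X = shared, both ways
    in_g <- vapply(g[1:2], function(x) {
      sum(vapply(profiles, function(p) x %in% p, logical(1)))
    }, numeric(1))
    shared <- sum(vapply(profiles,
                         function(p) all(g[1:2] %in% p), logical(1)))
    excl <- vapply(g[1:2], function(x) {
      sum(vapply(profiles, function(p) setequal(p, x), logical(1)))
    }, numeric(1))
    only <- vapply(g[1:2], function(x) {
      sum(vapply(profiles, function(p)
        x %in% p && !all(g[1:2] %in% p), logical(1)))
    }, numeric(1))
    expect_equal(unname(in_g - only), rep(shared, 2))
  }
})

test_that("heat-map normalization scales each row to unit maximum", {
  m <- rbind(a = c(10, 5, 0), b = c(0, 0, 0), c = c(7, 7, 7))
  h <- heatmap_normalize(m)
  expect_equal(unname(h["a", ]), c(1, 0.5, 0))
  expect_equal(unname(h["b", ]), c(0, 0, 0))
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(unname(heatmap_normalize(matrix(7, 1, 1))[1, ]), 1)
  rmax <- apply(h, 1, max)
  expect_true(all(rmax == 1 | rowSums(m) == 0))
})

test_that("the provenance pipeline composes stages and writes outputs", {
  files <- tiny_study_files()
  out <- file.path(files$dir, "out")
  res <- run_provenance_pipeline(files$atlas, files$source_map,
                                 files$proteins, out)
  # gA: collapse keeps pA1 (max 30); 30 > 3*median(30,2,1,1)=4.5 only liver
  expect_equal(res$profiles$partition_label[res$profiles$protein_id == "P1"],
               "exclusive:peripheral_tissues")
  expect_equal(res$profiles$partition_label[res$profiles$protein_id == "P2"],
               "exclusive:T_cells")
  # gC is flat: no call
  expect_equal(res$profiles$partition_label[res$profiles$protein_id == "P3"],
               "none")
  expect_equal(res$unmapped, "P4")
  expect_equal(res$summary$total_input, 4)
  expect_equal(res$summary$unmapped + sum(res$summary$region_counts), 4)
  for (f in c("calls.tsv", "profiles.tsv", "venn_summary.tsv",
              "venn_summary.json", "heatmap.tsv", "unmapped.tsv",
              "manifest.json")) {
    expect_true(file.exists(file.path(out, f)))
  }

  # raising the multiple beyond any ratio drives every profile to "none"
  res_hi <- run_provenance_pipeline(files$atlas, files$source_map,
                                    files$proteins,
                                    file.path(files$dir, "out_hi"),
                                    threshold_multiple = 1e6)
  expect_true(all(res_hi$profiles$partition_label == "none"))

  # errors carry the failing stage name
  expect_error(
    run_provenance_pipeline(files$atlas, files$proteins, files$proteins,
                            file.path(files$dir, "bad")),
    "\\[read_source_map\\]")
})

test_that("identical pipeline configurations produce byte-identical outputs", {
  files <- tiny_study_files()
  out1 <- file.path(files$dir, "run1")
  out2 <- file.path(files$dir, "run2")
  run_provenance_pipeline(files$atlas, files$source_map, files$proteins, out1)
  run_provenance_pipeline(files$atlas, files$source_map, files$proteins, out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = paste("file", f))
  }
})
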
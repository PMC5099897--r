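# Shared fixtures and independent oracles for the test suite.

# Build an atlas_probes object from a compact list spec:
#   list(probe_id = list(gene, c(values...)), ...)
make_probes <- function(spec, categories = NULL) {
  probe_ids <- names(spec)
  genes <- vapply(spec, function(x) x[[1]], character(1))
  expr <- do.call(rbind, lapply(spec, function(x) x[[2]]))
  if (is.null(categories)) categories <- paste0("cat", seq_len(ncol(expr)))
  colnames(expr) <- categories
  atlas_probes(probe_ids, genes, expr)
}

# Independent probe-collapse oracle: sort each gene's probes by
# (max value desc, probe_set_id asc), take the first.
collapse_oracle <- function(probes) {
  genes <- unique(probes$gene_id)
  rows <- lapply(genes, function(g) {
    idx <- which(probes$gene_id == g)
    rmax <- apply(probes$expr[idx, , drop = FALSE], 1, max)
    ord <- idx[order(-rmax, probes$probe_set_id[idx])]
    probes$expr[ord[1], ]
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- genes
  mat
}

# Independent expression-call oracle: literal median-and-compare, with the
# documented absolute-floor fallback at zero median.
call_oracle <- function(values, multiple = 3, floor = 1) {
  med <- sort(values)[ceiling(length(values) / 2)]
  if (length(values) %% 2 == 0) {
    s <- sort(values)
    med <- (s[length(values) / 2] + s[length(values) / 2 + 1]) / 2
  }
  if (med > 0) values > multiple * med else values > floor
}

# Brute-force Venn census: test every profile against every subset of groups.
venn_oracle <- function(profiles, groups) {
  keys <- "none"
  for (k in seq_along(groups)) {
    keys <- c(keys, apply(combn(sort(groups), k), 2, paste, collapse = "+"))
  }
  subsets <- c(list(character(0)),
               unlist(lapply(seq_along(groups), function(k) {
                 apply(combn(sort(groups), k), 2, identity,
                       simplify = FALSE)
               }), recursive = FALSE))
  counts <- setNames(integer(length(keys)), keys)
  for (i in seq_along(subsets)) {
    counts[i] <- sum(vapply(profiles, setequal, logical(1), subsets[[i]]))
  }
  counts
}

# Write a small TSV fixture and return its path.
write_tsv_fixture <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A tiny 2-group atlas + map + proteins on disk, returned as a path list.
tiny_study_files <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  atlas <- data.frame(
    probe_set_id = c("pA1", "pA2", "pB1", "pC1", "pD1"),
    gene_id = c("gA", "gA", "gB", "gC", "gD"),
    liver = c(30, 5, 1, 5, 0),
    kidney = c(2, 5, 1, 5, 0),
    CD4_T = c(1, 5, 25, 5, 0),
    CD8_T = c(1, 5, 2, 5, 0),
    check.names = FALSE)
  smap <- data.frame(
    category = c("liver", "kidney", "CD4_T", "CD8_T"),
    source_group = c("peripheral_tissues", "peripheral_tissues",
                     "T_cells", "T_cells"))
  prot <- data.frame(
    protein_id = c("P1", "P2", "P3", "P4"),
    gene_ids = c("gA", "gB", "gC", "gX;gZ"))
  list(
    atlas = write_tsv_fixture(atlas, dir),
    source_map = write_tsv_fixture(smap, dir),
    proteins = write_tsv_fixture(prot, dir),
    dir = dir)
}
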
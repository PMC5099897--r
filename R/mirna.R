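#' Two-condition miRNA intensity table
#'
#' Container for a miRNA x sample intensity matrix with a two-condition
#' design and optional spike-in control rows. Spike-ins are synthetic
#' reference RNAs added at a known common amount; they are kept in the table
#' (flagged) for normalization but excluded from presence sets and fold
#' counts.
#'
#' @param intensities Non-negative numeric matrix, one row per miRNA
#'   (rownames = miRNA ids), one column per sample (colnames = sample names).
#' @param condition Named character vector mapping each sample name to one of
#'   exactly two condition labels.
#' @param spike_ids Character vector of miRNA ids flagged as spike-in
#'   controls (subset of rownames).
#' @return An object of class `mirna_table`.
#' @export
mirna_table <- function(intensities, condition, spike_ids = character()) {
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(rownames(intensities)) || anyDuplicated(rownames(intensities))) {
    stop("intensities must have unique miRNA-id rownames")
  }
  if (is.null(colnames(intensities))) {
    stop("intensities must have sample colnames")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0")
  }
  condition <- vapply(condition, as.character, character(1))
  if (!setequal(names(condition), colnames(intensities))) {
    stop("condition must be named by the sample names")
  }
  condition <- condition[colnames(intensities)]
  if (length(unique(condition)) != 2) {
    stop("exactly two conditions are required")
  }
  if (any(table(condition) < 1)) stop("each condition needs >= 1 sample")
  spike_ids <- as.character(spike_ids)
  if (!all(spike_ids %in% rownames(intensities))) {
    stop("spike_ids must be a subset of the miRNA ids")
  }
  structure(list(intensities = intensities, condition = condition,
                 spike_ids = spike_ids,
                 conditions = unique(unname(condition))),
            class = "mirna_table")
}

#' @export
print.mirna_table <- function(x, ...) {
  cat(sprintf("mirna_table: %d miRNAs (%d spike-ins) x %d samples (%s)\n",
              nrow(x$intensities), length(x$spike_ids), ncol(x$intensities),
              paste(sprintf("%s: %d", x$conditions,
                            table(x$condition)[x$conditions]),
                    collapse = ", ")))
  invisible(x)
}

#' Read a miRNA intensity table and sample sheet from TSV
#'
#' The intensity TSV has a `mirna_id` column then one numeric column per
#' sample. The sample sheet TSV has columns `sample` and `condition` (exactly
#' two condition labels). Spike-in rows are flagged either explicitly via
#' `spike_ids` or by matching `spike_pattern` against the miRNA ids.
#'
#' @param intensity_file Path to the intensity TSV.
#' @param sample_file Path to the sample sheet TSV.
#' @param spike_ids Explicit spike-in ids, or `NULL` to use `spike_pattern`.
#' @param spike_pattern Regular expression identifying spike-in rows when
#'   `spike_ids` is `NULL` (default `"^spike"`).
#' @return A [mirna_table].
#' @export
read_mirna_table <- function(intensity_file, sample_file, spike_ids = NULL,
                             spike_pattern = "^spike") {
  raw <- utils::read.delim(intensity_file, header = TRUE, sep = "\t",
                           quote = "", check.names = FALSE,
                           colClasses = "character")
  if (!"mirna_id" %in% names(raw)) {
    stop("intensity table must have a mirna_id column")
  }
  samples <- setdiff(names(raw), "mirna_id")
  mat <- matrix(NA_real_, nrow(raw), length(samples),
                dimnames = list(raw$mirna_id, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[samples[j]]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric intensity '%s' at row %d, column '%s'",
                   raw[[samples[j]]][bad[1]], bad[1], samples[j]))
    }
    mat[, j] <- v
  }
  sheet <- utils::read.delim(sample_file, header = TRUE, sep = "\t",
                             quote = "", check.names = FALSE,
                             colClasses = "character")
  if (!all(c("sample", "condition") %in% names(sheet))) {
    stop("sample sheet must have columns: sample, condition")
  }
  cond <- stats::setNames(sheet$condition, sheet$sample)
  if (is.null(spike_ids)) {
    spike_ids <- grep(spike_pattern, rownames(mat), value = TRUE)
  }
  mirna_table(mat, cond, spike_ids)
}

#' Write a miRNA table as intensity TSV plus sample sheet
#' @param table A [mirna_table].
#' @param intensity_file Output path for the intensity TSV.
#' @param sample_file Output path for the sample sheet TSV.
#' @return `intensity_file`, invisibly.
#' @export
write_mirna_table <- function(table, intensity_file, sample_file) {
  stopifnot(inherits(table, "mirna_table"))
  df <- data.frame(mirna_id = rownames(table$intensities),
                   signif(table$intensities, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, intensity_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample = colnames(table$intensities),
                      condition = unname(table$condition),
                      stringsAsFactors = FALSE)
  utils::write.table(sheet, sample_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(intensity_file)
}

#' Scale samples so spike-in levels agree
#'
#' Each sample's column is rescaled so that its mean spike-in intensity
#' equals the grand mean of the per-sample spike means. Spike rows stay in
#' the table, still flagged. Scaling is per-sample and multiplicative, so the
#' within-sample rank order of miRNAs is unchanged.
#'
#' @param table A [mirna_table] with at least one spike-in row.
#' @return The rescaled [mirna_table].
#' @export
normalize_by_spike <- function(table) {
  stopifnot(inherits(table, "mirna_table"))
  if (length(table$spike_ids) == 0) stop("no spike-in rows in table")
  spikes <- table$intensities[table$spike_ids, , drop = FALSE]
  sample_means <- colMeans(spikes)
  if (any(sample_means <= 0)) {
    stop("zero spike-in intensity in sample: ",
         paste(names(sample_means)[sample_means <= 0], collapse = ", "))
  }
  scale <- mean(sample_means) / sample_means
  out <- sweep(table$intensities, 2, scale, "*")
  mirna_table(out, table$condition, table$spike_ids)
}

#' Presence calls per condition
#'
#' A miRNA is called present in a condition when its intensity is strictly
#' above `detection_floor` in at least `min_samples` of that condition's
#' replicates. Spike-in rows are excluded from presence sets.
#'
#' @param table A [mirna_table].
#' @param detection_floor Non-negative intensity floor (default 0).
#' @param min_samples Minimum replicates above the floor; default `NULL`
#'   requires all replicates of the condition.
#' @return A named list of two character vectors (one per condition, in
#'   first-appearance order) of present miRNA ids.
#' @export
detect_present <- function(table, detection_floor = 0, min_samples = NULL) {
  stopifnot(inherits(table, "mirna_table"))
  if (detection_floor < 0) stop("detection_floor must be >= 0")
  ids <- setdiff(rownames(table$intensities), table$spike_ids)
  out <- list()
  for (cond in table$conditions) {
    cols <- names(table$condition)[table$condition == cond]
    need <- if (is.null(min_samples)) length(cols) else min_samples
    if (need > length(cols)) {
      stop("min_samples exceeds replicate count for condition ", cond)
    }
    hits <- rowSums(table$intensities[ids, cols, drop = FALSE] >
                      detection_floor)
    out[[cond]] <- ids[hits >= need]
  }
  out
}

#' Compare miRNA content between two conditions
#'
#' Computes per-condition presence sets, the unique/shared set partition, and
#' per-miRNA fold ratios of condition means (first condition over second,
#' pseudo-count applied to both). With `pseudo_count = 0` a miRNA with signal
#' only in the numerator condition gets the `Inf` sentinel and one with
#' signal only in the denominator gets 0; both are reported in the unique
#' sets and excluded from threshold counts. Spike-ins are excluded
#' throughout.
#'
#' @param table A [mirna_table].
#' @param detection_floor,min_samples Passed to [detect_present()].
#' @param pseudo_count Non-negative value added to both condition means
#'   before the ratio (default 0).
#' @param condition_a Which condition is the ratio numerator; default the
#'   first condition in sample order.
#' @return An object of class `mirna_comparison`: list with `condition_a`,
#'   `condition_b`, `present_a`, `present_b`, `unique_a`, `unique_b`,
#'   `shared`, `mean_a`, `mean_b` and `fold_ratio` (named numeric; `Inf`/0
#'   sentinels possible at pseudo-count 0, `NaN` when both means are zero).
#' @export
compare_conditions <- function(table, detection_floor = 0,
                               min_samples = NULL, pseudo_count = 0,
                               condition_a = NULL) {
  stopifnot(inherits(table, "mirna_table"))
  if (pseudo_count < 0) stop("pseudo_count must be >= 0")
  present <- detect_present(table, detection_floor, min_samples)
  if (is.null(condition_a)) condition_a <- table$conditions[1]
  if (!condition_a %in% table$conditions) {
    stop("unknown condition: ", condition_a)
  }
  cond_a <- condition_a
  cond_b <- setdiff(table$conditions, cond_a)
  ids <- setdiff(rownames(table$intensities), table$spike_ids)
  cols_a <- names(table$condition)[table$condition == cond_a]
  cols_b <- names(table$condition)[table$condition == cond_b]
  mean_a <- rowMeans(table$intensities[ids, cols_a, drop = FALSE])
  mean_b <- rowMeans(table$intensities[ids, cols_b, drop = FALSE])
  num <- mean_a + pseudo_count
  den <- mean_b + pseudo_count
  ratio <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
  names(ratio) <- ids
  structure(list(
    condition_a = cond_a, condition_b = cond_b,
    present_a = present[[cond_a]], present_b = present[[cond_b]],
    unique_a = setdiff(present[[cond_a]], present[[cond_b]]),
    unique_b = setdiff(present[[cond_b]], present[[cond_a]]),
    shared = intersect(present[[cond_a]], present[[cond_b]]),
    mean_a = mean_a, mean_b = mean_b, fold_ratio = ratio,
    pseudo_count = pseudo_count
  ), class = "mirna_comparison")
}

#' @export
print.mirna_comparison <- function(x, ...) {
  cat(sprintf("mirna_comparison: %s vs %s\n", x$condition_a, x$condition_b))
  cat(sprintf("present: %d / %d; unique: %d / %d; shared: %d\n",
              length(x$present_a), length(x$present_b), length(x$unique_a),
              length(x$unique_b), length(x$shared)))
  invisible(x)
}

#' Count fold-enriched miRNAs at strict thresholds
#'
#' Counts miRNAs whose finite fold ratio is strictly greater than each
#' threshold, in the stated direction ("more than twofold" means ratio > 2).
#' Non-finite ratios (the presence-only sentinels) are never counted. Counts
#' are non-increasing in the threshold.
#'
#' @param comparison A [compare_conditions()] result.
#' @param thresholds Numeric thresholds, each > 1 (default `c(2, 10)`).
#' @param direction `"a_over_b"` counts enrichment in the first condition,
#'   `"b_over_a"` in the second.
#' @return Named integer vector of counts (names like `">2"`).
#' @export
count_enriched <- function(comparison, thresholds = c(2, 10),
                           direction = c("a_over_b", "b_over_a")) {
  stopifnot(inherits(comparison, "mirna_comparison"))
  direction <- match.arg(direction)
  if (any(!is.finite(thresholds)) || any(thresholds <= 1)) {
    stop("thresholds must all be > 1")
  }
  r <- comparison$fold_ratio
  if (direction == "b_over_a") r <- 1 / r
  counts <- vapply(thresholds,
                   function(t) sum(is.finite(r) & r > t, na.rm = TRUE),
                   numeric(1))
  stats::setNames(as.integer(counts), paste0(">", thresholds))
}

#' Run the full two-condition miRNA comparison pipeline
#'
#' Reads the intensity table and sample sheet, optionally rescales by
#' spike-ins, computes presence sets, unique/shared partitions and
#' fold-enrichment counts in both directions, and writes `comparison.tsv`,
#' `mirna_summary.json` and `manifest.json` to `out_dir`.
#'
#' @param intensity_file,sample_file Input TSVs (see [read_mirna_table()]).
#' @param out_dir Output directory, created if needed.
#' @param detection_floor,min_samples,pseudo_count See [compare_conditions()].
#' @param fold_thresholds Thresholds for [count_enriched()] (default
#'   `c(2, 10)`).
#' @param normalize_spike Rescale samples by spike-ins first (default `TRUE`
#'   when spike rows exist).
#' @param spike_ids,spike_pattern See [read_mirna_table()].
#' @return Invisibly, a list with `comparison` and `enriched` (list with one
#'   count vector per direction).
#' @export
run_mirna_pipeline <- function(intensity_file, sample_file, out_dir,
                               detection_floor = 0, min_samples = NULL,
                               pseudo_count = 0, fold_thresholds = c(2, 10),
                               normalize_spike = TRUE, spike_ids = NULL,
                               spike_pattern = "^spike") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- with_stage("read_mirna", read_mirna_table(intensity_file,
                                                   sample_file, spike_ids,
                                                   spike_pattern))
  if (normalize_spike && length(tab$spike_ids) > 0) {
    tab <- with_stage("normalize_by_spike", normalize_by_spike(tab))
  }
  cmp <- with_stage("compare_conditions",
                    compare_conditions(tab, detection_floor, min_samples,
                                       pseudo_count))
  enriched <- with_stage("count_enriched", list(
    a_over_b = count_enriched(cmp, fold_thresholds, "a_over_b"),
    b_over_a = count_enriched(cmp, fold_thresholds, "b_over_a")))

  with_stage("write_outputs", {
    ids <- names(cmp$fold_ratio)
    out_df <- data.frame(
      mirna_id = ids,
      mean_a = signif(unname(cmp$mean_a), 6),
      mean_b = signif(unname(cmp$mean_b), 6),
      fold_ratio = signif(unname(cmp$fold_ratio), 6),
      present_a = ids %in% cmp$present_a,
      present_b = ids %in% cmp$present_b,
      stringsAsFactors = FALSE)
    names(out_df)[2:3] <- paste0("mean_", c(cmp$condition_a,
                                            cmp$condition_b))
    names(out_df)[5:6] <- paste0("present_", c(cmp$condition_a,
                                               cmp$condition_b))
    utils::write.table(out_df, file.path(out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(condition_a = cmp$condition_a, condition_b = cmp$condition_b,
           n_present_a = length(cmp$present_a),
           n_present_b = length(cmp$present_b),
           n_unique_a = length(cmp$unique_a),
           n_unique_b = length(cmp$unique_b),
           n_shared = length(cmp$shared),
           enriched_a_over_b = as.list(enriched$a_over_b),
           enriched_b_over_a = as.list(enriched$b_over_a)),
      file.path(out_dir, "mirna_summary.json"), auto_unbox = TRUE,
      digits = NA)
    write_manifest(
      file.path(out_dir, "manifest.json"), subcommand = "mirna",
      params = list(detection_floor = detection_floor,
                    min_samples = min_samples, pseudo_count = pseudo_count,
                    fold_thresholds = fold_thresholds,
                    normalize_spike = normalize_spike),
      inputs = c(intensities = intensity_file, samples = sample_file))
  })
  invisible(list(comparison = cmp, enriched = enriched))
}
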
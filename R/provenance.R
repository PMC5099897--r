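#' Read a cargo protein list from TSV
#'
#' Expects columns `protein_id` and `gene_ids` (semicolon-separated candidate
#' gene identifiers, in the caller's preference order; may be empty). Any
#' additional columns (e.g. a simulator's `true_label`) are carried through.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with `protein_id`, list-column `gene_ids`, and any
#'   extra input columns.
#' @export
read_protein_list <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("protein_id", "gene_ids") %in% names(raw))) {
    stop("protein list must have columns: protein_id, gene_ids")
  }
  dup <- unique(raw$protein_id[duplicated(raw$protein_id)])
  if (length(dup) > 0) {
    stop("duplicate protein_id: ", paste(dup, collapse = ", "))
  }
  out <- raw
  out$gene_ids <- I(lapply(strsplit(raw$gene_ids, ";", fixed = TRUE),
                           function(g) g[nzchar(g)]))
  out
}

#' Write a protein list to TSV
#' @param proteins Data.frame with `protein_id` and list-column or
#'   semicolon-joined `gene_ids`; extra columns are written as-is.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_list <- function(proteins, path) {
  df <- proteins
  if (is.list(df$gene_ids) && !is.character(df$gene_ids)) {
    df$gene_ids <- vapply(df$gene_ids, paste, character(1), collapse = ";")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve cargo proteins against an atlas
#'
#' Each protein resolves to the first of its candidate gene ids present in the
#' atlas (the list order is the caller's preference order, e.g. from an
#' upstream identifier-conversion step). Proteins with no atlas hit are
#' reported as unmapped; mapped and unmapped together partition the input.
#'
#' @param proteins Data.frame as returned by [read_protein_list()].
#' @param atlas An [expression_atlas].
#' @return A list with `mapped` (data.frame `protein_id`, `gene_id`) and
#'   `unmapped` (character vector of protein ids).
#' @export
map_proteins <- function(proteins, atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  atlas_genes <- rownames(atlas$matrix)
  hit <- vapply(proteins$gene_ids, function(gs) {
    m <- gs[gs %in% atlas_genes]
    if (length(m) == 0) NA_character_ else m[1]
  }, character(1))
  mapped <- data.frame(protein_id = proteins$protein_id[!is.na(hit)],
                       gene_id = hit[!is.na(hit)],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(mapped = mapped, unmapped = proteins$protein_id[is.na(hit)])
}

#' Call the categories in which a protein is expressed
#'
#' The expression-call rule: a protein is declared expressed in a category
#' when its value there is strictly above `threshold_multiple` times the
#' median of its own expression vector across all atlas categories. When the
#' median is zero the ratio is undefined; the call then falls back to an
#' absolute floor: expressed iff value > `expression_floor`.
#'
#' @param values Non-negative numeric vector, one value per atlas category
#'   (names preserved if present).
#' @param threshold_multiple Positive multiple of the median (default 3).
#' @param expression_floor Non-negative absolute floor used only when the
#'   median is zero (default 1, in atlas intensity units).
#' @return A list with `value`, `median`, `ratio` (value/median, `NA` when the
#'   median is zero) and logical `called`.
#' @export
call_categories <- function(values, threshold_multiple = 3,
                            expression_floor = 1) {
  if (!is.numeric(threshold_multiple) || length(threshold_multiple) != 1 ||
      is.na(threshold_multiple) || threshold_multiple <= 0) {
    stop("threshold_multiple must be a single positive number")
  }
  if (!is.numeric(expression_floor) || length(expression_floor) != 1 ||
      is.na(expression_floor) || expression_floor < 0) {
    stop("expression_floor must be a single non-negative number")
  }
  if (length(values) == 0) stop("values must be non-empty")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and >= 0")
  }
  med <- stats::median(values)
  if (med > 0) {
    ratio <- values / med
    called <- values > threshold_multiple * med
  } else {
    ratio <- rep(NA_real_, length(values))
    names(ratio) <- names(values)
    called <- values > expression_floor
  }
  list(value = values, median = med, ratio = ratio, called = called)
}

#' Derive a protein's source-group provenance profile
#'
#' Maps the called categories through the source map and summarises the
#' resulting set of groups into a Venn partition label: `none` (empty set),
#' `exclusive:<group>` (singleton), `all_groups` (every group hit), or
#' `mixed:<g1+g2+...>` (sorted subset). Categories mapped to `"unassigned"`
#' are excluded from the census.
#'
#' @param called_categories Character vector of category names that were
#'   called expressed.
#' @param map A [source_map].
#' @return A list with `source_groups` (sorted character vector) and
#'   `partition_label`.
#' @export
profile_source_groups <- function(called_categories, map) {
  stopifnot(inherits(map, "source_map"))
  outside <- setdiff(called_categories, names(map$mapping))
  if (length(outside) > 0) {
    stop("category outside source map domain: ",
         paste(outside, collapse = ", "))
  }
  hit <- unique(unname(map$mapping[called_categories]))
  hit <- sort(setdiff(hit, "unassigned"))
  label <- if (length(hit) == 0) {
    "none"
  } else if (setequal(hit, map$groups)) {
    "all_groups"
  } else if (length(hit) == 1) {
    paste0("exclusive:", hit)
  } else {
    paste0("mixed:", paste(hit, collapse = "+"))
  }
  list(source_groups = hit, partition_label = label)
}

# Canonical region key for a set of groups: sorted "+"-joined names, or "none".
venn_region_key <- function(groups_hit) {
  if (length(groups_hit) == 0) "none" else paste(sort(groups_hit),
                                                 collapse = "+")
}

# All 2^G region keys for a group list, empty set first, then by subset size.
venn_all_regions <- function(groups) {
  keys <- "none"
  for (k in seq_along(groups)) {
    keys <- c(keys, apply(utils::combn(sort(groups), k), 2, paste,
                          collapse = "+"))
  }
  keys
}

#' Census the Venn partition of provenance profiles
#'
#' Counts each profile into exactly one of the 2^G subset regions of the group
#' list (the empty region is reported as `none`). Proteins that could not be
#' mapped to the atlas are counted separately so that
#' `unmapped + sum(region_counts) == total_input`.
#'
#' @param profiles List of character vectors, each a protein's set of source
#'   groups (as in the `source_groups` field of [profile_source_groups()]).
#' @param groups Character vector of all candidate group names.
#' @param n_unmapped Number of input proteins that had no atlas mapping.
#' @return An object of class `provenance_summary`: list with `total_input`,
#'   `unmapped`, `groups`, `region_counts` (named integer vector over all 2^G
#'   regions), and convenience counts `exclusive` (per group), `all_groups`,
#'   `none`.
#' @export
summarize_venn <- function(profiles, groups, n_unmapped = 0) {
  groups <- as.character(groups)
  if (length(groups) == 0 || anyDuplicated(groups)) {
    stop("groups must be non-empty and unique")
  }
  keys <- venn_all_regions(groups)
  counts <- stats::setNames(integer(length(keys)), keys)
  for (p in profiles) {
    bad <- setdiff(p, groups)
    if (length(bad) > 0) {
      stop("profile contains unknown group: ", paste(bad, collapse = ", "))
    }
    k <- venn_region_key(p)
    counts[k] <- counts[k] + 1L
  }
  exclusive <- stats::setNames(counts[match(sort(groups), names(counts))],
                               sort(groups))
  structure(list(
    total_input = length(profiles) + n_unmapped,
    unmapped = as.integer(n_unmapped),
    groups = groups,
    region_counts = counts,
    exclusive = exclusive,
    all_groups = unname(counts[venn_region_key(groups)]),
    none = unname(counts["none"])
  ), class = "provenance_summary")
}

#' @export
print.provenance_summary <- function(x, ...) {
  cat(sprintf("provenance_summary: %d proteins (%d unmapped)\n",
              x$total_input, x$unmapped))
  cat("exclusive:", paste(sprintf("%s=%d", names(x$exclusive), x$exclusive),
                          collapse = ", "), "\n")
  cat(sprintf("all_groups=%d, none=%d\n", x$all_groups, x$none))
  invisible(x)
}

#' Normalize an expression matrix per protein for heat-map display
#'
#' Divides each row by its own maximum so every row's maximum is 1; all-zero
#' rows are left as zeros. This per-protein scaling preserves the ratios the
#' call rule depends on.
#'
#' @param mat Non-negative numeric matrix (proteins x categories).
#' @return A matrix of the same shape with values in \[0, 1\].
#' @export
heatmap_normalize <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) == 0) return(mat)
  if (any(!is.finite(mat)) || any(mat < 0)) {
    stop("matrix values must be finite and >= 0")
  }
  rmax <- apply(mat, 1, max)
  scale <- ifelse(rmax > 0, rmax, 1)
  mat / scale
}

# Run one stage, attaching the stage name to any error.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full cargo-provenance pipeline
#'
#' Deterministic composition of the analysis stages: read the probe-level
#' atlas, filter low probes, collapse to gene level, read and validate the
#' source map, map proteins, call categories with the median-multiple rule,
#' profile source groups, and census the Venn partition. All outputs are
#' written to `out_dir` together with a run manifest (parameters, input
#' checksums, package version) sufficient to re-run bit-identically.
#'
#' Output files: `calls.tsv` (protein, category, value, ratio, called),
#' `profiles.tsv` (protein, resolved gene, source groups, partition label),
#' `venn_summary.tsv` + `venn_summary.json`, `heatmap.tsv`, `unmapped.tsv`,
#' `manifest.json`.
#'
#' @param atlas_file Probe-level atlas TSV (see [read_atlas_table()]).
#' @param source_map_file Category-to-group TSV (see [read_source_map()]).
#' @param protein_file Protein list TSV (see [read_protein_list()]).
#' @param out_dir Output directory, created if needed.
#' @param groups Group names for the Venn census; default `NULL` uses the
#'   groups found in the source-map file (all mapped-to names except
#'   `"unassigned"`, in first-appearance order).
#' @param threshold_multiple Median multiple for the call rule (default 3).
#' @param probe_floor Floor for [filter_low_probes()] (default 0).
#' @param expression_floor Zero-median fallback floor for [call_categories()]
#'   (default 1).
#' @return Invisibly, a list with `summary` ([summarize_venn()] result),
#'   `profiles` (data.frame), `calls` (data.frame), `heatmap` (matrix) and
#'   `unmapped` (character).
#' @export
run_provenance_pipeline <- function(atlas_file, source_map_file, protein_file,
                                    out_dir, groups = NULL,
                                    threshold_multiple = 3, probe_floor = 0,
                                    expression_floor = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  probes <- with_stage("read_atlas", read_atlas_table(atlas_file))
  probes <- with_stage("filter_probes", filter_low_probes(probes, probe_floor))
  atlas <- with_stage("collapse_probes", collapse_probe_sets(probes))
  if (is.null(groups)) {
    raw <- utils::read.delim(source_map_file, sep = "\t",
                             colClasses = "character", check.names = FALSE)
    groups <- setdiff(unique(raw$source_group), "unassigned")
  }
  map <- with_stage("read_source_map", read_source_map(source_map_file,
                                                       groups))
  with_stage("validate_source_map", {
    rep <- validate_source_map(atlas, map)
    if (!rep$ok) {
      stop("atlas categories missing from source map: ",
           paste(rep$missing_categories, collapse = ", "))
    }
  })
  proteins <- with_stage("read_proteins", read_protein_list(protein_file))
  mapping <- with_stage("map_proteins", map_proteins(proteins, atlas))

  calls_rows <- vector("list", nrow(mapping$mapped))
  profiles <- vector("list", nrow(mapping$mapped))
  labels <- character(nrow(mapping$mapped))
  with_stage("call_and_profile", {
    for (i in seq_len(nrow(mapping$mapped))) {
      gid <- mapping$mapped$gene_id[i]
      pid <- mapping$mapped$protein_id[i]
      cs <- call_categories(atlas$matrix[gid, ], threshold_multiple,
                            expression_floor)
      prof <- profile_source_groups(atlas$categories[cs$called], map)
      calls_rows[[i]] <- data.frame(
        protein_id = pid, gene_id = gid, category = atlas$categories,
        value = unname(cs$value), ratio_to_median = unname(cs$ratio),
        called = unname(cs$called), stringsAsFactors = FALSE)
      profiles[[i]] <- prof$source_groups
      labels[i] <- prof$partition_label
    }
  })
  calls <- if (length(calls_rows) > 0) do.call(rbind, calls_rows) else
    data.frame(protein_id = character(), gene_id = character(),
               category = character(), value = numeric(),
               ratio_to_median = numeric(), called = logical())
  summary <- with_stage("summarize_venn",
                        summarize_venn(profiles, groups,
                                       length(mapping$unmapped)))
  prof_df <- data.frame(
    protein_id = mapping$mapped$protein_id,
    gene_id = mapping$mapped$gene_id,
    source_groups = vapply(profiles, venn_region_key, character(1)),
    partition_label = labels, stringsAsFactors = FALSE)
  heat <- with_stage("heatmap", {
    m <- atlas$matrix[mapping$mapped$gene_id, , drop = FALSE]
    rownames(m) <- mapping$mapped$protein_id
    heatmap_normalize(m)
  })

  with_stage("write_outputs", {
    calls_out <- calls
    calls_out$value <- signif(calls_out$value, 6)
    calls_out$ratio_to_median <- signif(calls_out$ratio_to_median, 6)
    utils::write.table(calls_out, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(prof_df, file.path(out_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    venn_df <- data.frame(region = names(summary$region_counts),
                          count = unname(summary$region_counts))
    utils::write.table(venn_df, file.path(out_dir, "venn_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(total_input = summary$total_input, unmapped = summary$unmapped,
           groups = summary$groups,
           region_counts = as.list(summary$region_counts),
           exclusive = as.list(summary$exclusive),
           all_groups = summary$all_groups, none = summary$none),
      file.path(out_dir, "venn_summary.json"), auto_unbox = TRUE, digits = NA)
    heat_df <- data.frame(protein_id = rownames(heat), signif(heat, 6),
                          check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(heat_df, file.path(out_dir, "heatmap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(protein_id = mapping$unmapped),
      file.path(out_dir, "unmapped.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(
      file.path(out_dir, "manifest.json"), subcommand = "provenance",
      params = list(threshold_multiple = threshold_multiple,
                    probe_floor = probe_floor,
                    expression_floor = expression_floor, groups = groups),
      inputs = c(atlas = atlas_file, source_map = source_map_file,
                 proteins = protein_file))
  })

  invisible(list(summary = summary, profiles = prof_df, calls = calls,
                 heatmap = heat, unmapped = mapping$unmapped))
}
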
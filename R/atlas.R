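#' Probe-level expression atlas records
#'
#' Container for probe-level rows of a categorized expression atlas: one row
#' per probe set, one non-negative intensity per atlas category. Several probe
#' sets may measure the same gene; [collapse_probe_sets()] reduces them to one
#' row per gene.
#'
#' @param probe_set_id Character vector of unique probe-set identifiers.
#' @param gene_id Character vector of gene identifiers, parallel to
#'   `probe_set_id`.
#' @param expr Numeric matrix, one row per probe set, one column per atlas
#'   category; column names are the category names (header order is preserved
#'   everywhere, no internal sorting).
#' @return An object of class `atlas_probes`: a list with elements
#'   `probe_set_id`, `gene_id`, `expr` and `categories`.
#' @seealso [read_atlas_table()], [filter_low_probes()],
#'   [collapse_probe_sets()]
#' @export
atlas_probes <- function(probe_set_id, gene_id, expr) {
  probe_set_id <- as.character(probe_set_id)
  gene_id <- as.character(gene_id)
  if (!is.matrix(expr)) expr <- matrix(expr, nrow = length(probe_set_id))
  storage.mode(expr) <- "double"
  if (length(probe_set_id) != length(gene_id) ||
      nrow(expr) != length(probe_set_id)) {
    stop("probe_set_id, gene_id and expr rows must have equal length")
  }
  if (is.null(colnames(expr)) || anyDuplicated(colnames(expr)) ||
      any(!nzchar(colnames(expr)))) {
    stop("expr must have unique, non-empty category column names")
  }
  rownames(expr) <- NULL
  dup <- probe_set_id[duplicated(probe_set_id)]
  if (length(dup) > 0) {
    stop("duplicate probe_set_id: ", paste(unique(dup), collapse = ", "))
  }
  if (length(expr) > 0 && (any(!is.finite(expr)) || any(expr < 0))) {
    stop("expression values must be finite and >= 0")
  }
  structure(
    list(probe_set_id = probe_set_id, gene_id = gene_id, expr = expr,
         categories = colnames(expr)),
    class = "atlas_probes"
  )
}

#' @export
print.atlas_probes <- function(x, ...) {
  cat(sprintf("atlas_probes: %d probe sets, %d genes, %d categories\n",
              length(x$probe_set_id), length(unique(x$gene_id)),
              length(x$categories)))
  invisible(x)
}

#' @export
length.atlas_probes <- function(x) length(x$probe_set_id)

# Subset probes by integer/logical index, keeping order.
probes_subset <- function(probes, idx) {
  atlas_probes(probes$probe_set_id[idx], probes$gene_id[idx],
               probes$expr[idx, , drop = FALSE])
}

#' Read a probe-level atlas table from TSV
#'
#' Expected dialect: UTF-8, tab-separated, "." decimal point; columns
#' `probe_set_id`, `gene_id`, then one numeric column per atlas category.
#' Category order is taken from the header and preserved downstream.
#'
#' @param path Path to the TSV file.
#' @return An [atlas_probes] object (possibly with zero rows).
#' @export
read_atlas_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  need <- c("probe_set_id", "gene_id")
  if (!all(need %in% names(raw))) {
    stop("atlas table must have columns: ", paste(need, collapse = ", "))
  }
  cats <- setdiff(names(raw), need)
  if (length(cats) < 1) stop("atlas table needs at least one category column")
  dup <- unique(raw$probe_set_id[duplicated(raw$probe_set_id)])
  if (length(dup) > 0) {
    stop("duplicate probe_set_id: ", paste(dup, collapse = ", "))
  }
  expr <- matrix(NA_real_, nrow = nrow(raw), ncol = length(cats),
                 dimnames = list(NULL, cats))
  for (j in seq_along(cats)) {
    v <- suppressWarnings(as.numeric(raw[[cats[j]]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric expression value '%s' at row %d, column '%s'",
                   raw[[cats[j]]][bad[1]], bad[1], cats[j]))
    }
    neg <- which(v < 0)
    if (length(neg) > 0) {
      stop(sprintf("negative expression value %s at row %d, column '%s'",
                   raw[[cats[j]]][neg[1]], neg[1], cats[j]))
    }
    expr[, j] <- v
  }
  atlas_probes(raw$probe_set_id, raw$gene_id, expr)
}

#' Write a probe-level atlas table to TSV
#'
#' Emits the same dialect [read_atlas_table()] reads, with numeric values
#' printed at 6 significant digits so read/write round-trips are stable.
#'
#' @param probes An [atlas_probes] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas_table <- function(probes, path) {
  stopifnot(inherits(probes, "atlas_probes"))
  df <- data.frame(probe_set_id = probes$probe_set_id,
                   gene_id = probes$gene_id,
                   signif(probes$expr, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop probe sets whose maximum intensity is low
#'
#' Retains exactly the probe sets whose maximum expression across categories is
#' strictly greater than `floor`; input order is preserved. The default floor
#' of 0 keeps every probe set with any positive signal.
#'
#' @param probes An [atlas_probes] object.
#' @param floor Non-negative filtering floor, in atlas intensity units.
#' @return A filtered [atlas_probes] object (possibly empty).
#' @export
filter_low_probes <- function(probes, floor = 0) {
  stopifnot(inherits(probes, "atlas_probes"))
  if (!is.numeric(floor) || length(floor) != 1 || is.na(floor) || floor < 0) {
    stop("floor must be a single non-negative number")
  }
  if (length(probes) == 0) return(probes)
  keep <- apply(probes$expr, 1, max) > floor
  probes_subset(probes, keep)
}

#' Collapse probe sets to one expression row per gene
#'
#' For each gene, keeps the expression vector of the probe set with the
#' largest maximum value across categories; ties are broken by the
#' lexicographically smallest `probe_set_id` so results are deterministic.
#' Gene order follows first appearance in the input.
#'
#' @param probes An [atlas_probes] object.
#' @param provenance_note Free-text note describing the atlas source/version,
#'   stored on the result.
#' @return An object of class `expression_atlas`: list with `categories`
#'   (character), `matrix` (genes x categories, rownames = gene ids) and
#'   `provenance_note`.
#' @export
collapse_probe_sets <- function(probes, provenance_note = "") {
  stopifnot(inherits(probes, "atlas_probes"))
  n <- length(probes)
  if (n == 0) {
    mat <- probes$expr[0, , drop = FALSE]
    rownames(mat) <- character(0)
    return(expression_atlas(probes$categories, mat, provenance_note))
  }
  rmax <- apply(probes$expr, 1, max)
  genes <- unique(probes$gene_id)  # first-appearance order
  pick <- vapply(genes, function(g) {
    idx <- which(probes$gene_id == g)
    best <- idx[rmax[idx] == max(rmax[idx])]
    best[order(probes$probe_set_id[best])][1]
  }, integer(1))
  mat <- probes$expr[pick, , drop = FALSE]
  rownames(mat) <- genes
  expression_atlas(probes$categories, mat, provenance_note)
}

#' Gene-level expression atlas
#'
#' @param categories Ordered character vector of unique category names.
#' @param matrix Numeric matrix, one row per gene (rownames = gene ids), one
#'   column per category.
#' @param provenance_note Free-text source/version note.
#' @return An object of class `expression_atlas`.
#' @export
expression_atlas <- function(categories, matrix, provenance_note = "") {
  categories <- as.character(categories)
  if (anyDuplicated(categories) || any(!nzchar(categories))) {
    stop("category names must be unique and non-empty")
  }
  if (ncol(matrix) != length(categories)) {
    stop("matrix must have one column per category")
  }
  if (nrow(matrix) > 0) {
    if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
      stop("matrix must have unique gene-id rownames")
    }
    if (any(!is.finite(matrix)) || any(matrix < 0)) {
      stop("atlas values must be finite and >= 0")
    }
  }
  colnames(matrix) <- categories
  structure(list(categories = categories, matrix = matrix,
                 provenance_note = provenance_note),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("expression_atlas: %d genes x %d categories\n",
              nrow(x$matrix), length(x$categories)))
  if (nzchar(x$provenance_note)) cat("note:", x$provenance_note, "\n")
  invisible(x)
}

#' Category-to-source-group mapping
#'
#' Many-to-one mapping from atlas categories to candidate cellular-source
#' groups (e.g. peripheral tissues, T cells, B cells, macrophages, DCs). A
#' category may map to the sentinel `"unassigned"`, in which case it is
#' excluded from the group census.
#'
#' @param mapping Named character vector: names are category names, values are
#'   group names or `"unassigned"`.
#' @param groups Character vector of allowed group names (non-empty, unique).
#' @return An object of class `source_map`.
#' @export
source_map <- function(mapping, groups) {
  groups <- as.character(groups)
  if (length(groups) == 0 || anyDuplicated(groups)) {
    stop("groups must be a non-empty vector of unique names")
  }
  if ("unassigned" %in% groups) stop('"unassigned" is a reserved sentinel')
  mapping <- vapply(mapping, as.character, character(1))
  if (is.null(names(mapping)) || anyDuplicated(names(mapping))) {
    stop("mapping must be named by unique category names")
  }
  unknown <- setdiff(unique(mapping), c(groups, "unassigned"))
  if (length(unknown) > 0) {
    stop("unknown source group: ", paste(unknown, collapse = ", "))
  }
  structure(list(mapping = mapping, groups = groups), class = "source_map")
}

#' Read a category-to-group mapping from TSV
#'
#' Expects columns `category` and `source_group`. Duplicate category rows are
#' tolerated when they agree and rejected when they conflict.
#'
#' @param path Path to the TSV file.
#' @param groups Character vector of allowed group names.
#' @return A [source_map] object.
#' @export
read_source_map <- function(path, groups) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("category", "source_group") %in% names(raw))) {
    stop("source map must have columns: category, source_group")
  }
  by_cat <- split(raw$source_group, raw$category)
  bad <- names(by_cat)[vapply(by_cat, function(g) length(unique(g)) > 1,
                              logical(1))]
  if (length(bad) > 0) {
    stop("conflicting source_group for category: ",
         paste(bad, collapse = ", "))
  }
  dedup <- !duplicated(raw$category)
  mapping <- stats::setNames(raw$source_group[dedup], raw$category[dedup])
  source_map(mapping, groups)
}

#' Write a source map to TSV
#' @param map A [source_map] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_source_map <- function(map, path) {
  stopifnot(inherits(map, "source_map"))
  df <- data.frame(category = names(map$mapping),
                   source_group = unname(map$mapping),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a source map covers an atlas
#'
#' Atlas categories missing from the mapping domain are fatal (every call made
#' against that atlas would be unmappable); mapping entries for categories the
#' atlas does not contain are only warnings.
#'
#' @param atlas An [expression_atlas].
#' @param map A [source_map].
#' @return A list with `missing_categories` (fatal), `extra_categories`
#'   (warning) and logical `ok` (no fatal findings).
#' @export
validate_source_map <- function(atlas, map) {
  stopifnot(inherits(atlas, "expression_atlas"), inherits(map, "source_map"))
  missing <- setdiff(atlas$categories, names(map$mapping))
  extra <- setdiff(names(map$mapping), atlas$categories)
  list(missing_categories = missing, extra_categories = extra,
       ok = length(missing) == 0)
}
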
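#' Simulation configuration
#'
#' Parameters for the synthetic atlas / protein-list / miRNA generators. The
#' defaults emulate the scale of a typical mouse tissue-and-immune-cell
#' expression atlas (5 candidate source groups covering 62 categories) and a
#' two-condition miRNA microarray run with 2 + 2 replicate samples.
#'
#' Atlas genes come in three classes: tissue-restricted genes (expected
#' `basal_level * enrichment_factor` in every category of their home group,
#' `basal_level` elsewhere), ubiquitous genes (basal everywhere) and silent
#' genes (near-zero `silent_level` everywhere). Noise is multiplicative
#' log-normal with scale
#' `noise_sigma` and mean 1, so the stated expected values are exact; each
#' gene gets between `probes_per_gene[1]` and `probes_per_gene[2]`
#' independently jittered probe sets.
#'
#' miRNAs come in designed classes: unique to each condition, shared at equal
#' level, or shared with a designed fold enrichment (`fold_band2` for the
#' 2-10x band, `fold_band10` for the >10x band, in either direction). The
#' default class sizes give 104 and 15 condition-unique miRNAs, 450 (of which
#' 34 above 10-fold) enriched in the first condition and 147 (14 above
#' 10-fold) in the second, on top of 474 equal-level shared miRNAs.
#'
#' @param seed Integer seed; fixes the full output stream of each generator.
#' @param n_groups Number of candidate source groups.
#' @param categories_per_group Integer vector (length `n_groups`, recycled
#'   from a scalar) of categories per group; default splits 62 categories as
#'   evenly as possible over the groups.
#' @param group_names Group names; default the five canonical thymus source
#'   populations when `n_groups == 5`.
#' @param n_restricted_per_group,n_ubiquitous,n_silent Gene-class sizes.
#' @param basal_level Positive baseline expression (linear atlas units).
#' @param silent_level Near-zero background level for silent genes (must be
#'   well below `basal_level`); keeping it positive means silent genes stay
#'   in the atlas under a zero probe-filter floor and are classified by the
#'   call rule (which yields `none` for a flat vector) rather than dropped.
#' @param enrichment_factor Home-group multiplier for restricted genes
#'   (strictly > 1).
#' @param noise_sigma Log-normal noise scale (0 = noiseless).
#' @param probes_per_gene Length-2 integer bounds on probe sets per gene.
#' @param n_mirna_unique_a,n_mirna_unique_b Condition-unique miRNA counts.
#' @param n_mirna_band2_a,n_mirna_band10_a Shared miRNAs enriched in the
#'   first condition: in the 2-10x band and above 10x.
#' @param n_mirna_band2_b,n_mirna_band10_b Same for the second condition.
#' @param n_mirna_equal Shared miRNAs at equal level.
#' @param mirna_replicates Samples per condition.
#' @param n_spike Spike-in control rows.
#' @param mirna_present_level,mirna_spike_level Positive design intensities.
#' @param fold_band2,fold_band10 Designed fold changes for the two bands
#'   (must lie in (2, 10] and (10, Inf)).
#' @param mirna_conditions Length-2 character vector of condition labels.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_groups = 5,
                              categories_per_group = NULL,
                              group_names = NULL,
                              n_restricted_per_group = 40,
                              n_ubiquitous = 100,
                              n_silent = 50,
                              basal_level = 10,
                              silent_level = 0.01,
                              enrichment_factor = 30,
                              noise_sigma = 0.3,
                              probes_per_gene = c(1, 3),
                              n_mirna_unique_a = 104,
                              n_mirna_unique_b = 15,
                              n_mirna_band2_a = 416,
                              n_mirna_band10_a = 34,
                              n_mirna_band2_b = 133,
                              n_mirna_band10_b = 14,
                              n_mirna_equal = 474,
                              mirna_replicates = 2,
                              n_spike = 5,
                              mirna_present_level = 100,
                              mirna_spike_level = 1000,
                              fold_band2 = 4,
                              fold_band10 = 30,
                              mirna_conditions = c("thymus", "spleen")) {
  if (length(seed) != 1 || is.na(seed) || seed != as.integer(seed)) {
    stop("seed must be a single integer")
  }
  if (n_groups < 1) stop("n_groups must be >= 1")
  if (is.null(categories_per_group)) {
    total <- 62
    base <- total %/% n_groups
    extra <- total %% n_groups
    categories_per_group <- rep(base, n_groups) +
      c(rep(1, extra), rep(0, n_groups - extra))
  }
  if (length(categories_per_group) == 1) {
    categories_per_group <- rep(categories_per_group, n_groups)
  }
  if (length(categories_per_group) != n_groups ||
      any(categories_per_group < 1)) {
    stop("categories_per_group must give >= 1 category for each group")
  }
  if (is.null(group_names)) {
    group_names <- if (n_groups == 5) {
      c("peripheral_tissues", "T_cells", "B_cells", "macrophages", "DCs")
    } else {
      paste0("group_", seq_len(n_groups))
    }
  }
  if (length(group_names) != n_groups || anyDuplicated(group_names)) {
    stop("group_names must be unique and match n_groups")
  }
  counts <- c(n_restricted_per_group, n_ubiquitous, n_silent,
              n_mirna_unique_a, n_mirna_unique_b, n_mirna_band2_a,
              n_mirna_band10_a, n_mirna_band2_b, n_mirna_band10_b,
              n_mirna_equal, n_spike)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (basal_level <= 0) stop("basal_level must be > 0")
  if (silent_level <= 0 || silent_level >= basal_level) {
    stop("silent_level must be positive and below basal_level")
  }
  if (enrichment_factor <= 1) stop("enrichment_factor must be > 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (length(probes_per_gene) != 2 || probes_per_gene[1] < 1 ||
      probes_per_gene[2] < probes_per_gene[1]) {
    stop("probes_per_gene must be increasing bounds >= 1")
  }
  if (mirna_replicates < 1) stop("mirna_replicates must be >= 1")
  if (mirna_present_level <= 0 || mirna_spike_level <= 0) {
    stop("design intensity levels must be > 0")
  }
  if (fold_band2 <= 2 || fold_band2 > 10 || fold_band10 <= 10) {
    stop("fold_band2 must lie in (2, 10], fold_band10 above 10")
  }
  if (length(mirna_conditions) != 2 || anyDuplicated(mirna_conditions)) {
    stop("mirna_conditions must be two distinct labels")
  }
  structure(list(
    seed = as.integer(seed), n_groups = n_groups,
    categories_per_group = as.integer(categories_per_group),
    group_names = group_names,
    n_restricted_per_group = n_restricted_per_group,
    n_ubiquitous = n_ubiquitous, n_silent = n_silent,
    basal_level = basal_level, silent_level = silent_level,
    enrichment_factor = enrichment_factor,
    noise_sigma = noise_sigma, probes_per_gene = as.integer(probes_per_gene),
    n_mirna_unique_a = n_mirna_unique_a, n_mirna_unique_b = n_mirna_unique_b,
    n_mirna_band2_a = n_mirna_band2_a, n_mirna_band10_a = n_mirna_band10_a,
    n_mirna_band2_b = n_mirna_band2_b, n_mirna_band10_b = n_mirna_band10_b,
    n_mirna_equal = n_mirna_equal, mirna_replicates = mirna_replicates,
    n_spike = n_spike, mirna_present_level = mirna_present_level,
    mirna_spike_level = mirna_spike_level, fold_band2 = fold_band2,
    fold_band10 = fold_band10, mirna_conditions = mirna_conditions
  ), class = "simulation_config")
}

# Mean-1 multiplicative log-normal noise factors; exactly 1 when sigma is 0.
lognormal_noise <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Generate a synthetic probe-level atlas with known gene labels
#'
#' Builds an atlas whose categories split into source groups, with
#' tissue-restricted, ubiquitous and silent genes as described in
#' [simulation_config()]. Each gene is measured by 1 or more probe sets,
#' each an independently jittered copy of the gene's expected vector.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `probes` ([atlas_probes]), `source_map`
#'   ([source_map]), `truth` (data.frame `gene_id`, `true_label` with labels
#'   `restricted:<group>`, `ubiquitous` or `silent`) and `config`.
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- config$group_names
  categories <- unlist(lapply(seq_along(groups), function(i) {
    paste0(groups[i], "_c", seq_len(config$categories_per_group[i]))
  }))
  cat_group <- rep(groups, config$categories_per_group)
  map <- source_map(stats::setNames(cat_group, categories), groups)

  gene_ids <- character(0)
  labels <- character(0)
  expected <- list()
  for (i in seq_along(groups)) {
    n <- config$n_restricted_per_group
    if (n > 0) {
      ids <- sprintf("g_%s_%03d", groups[i], seq_len(n))
      vec <- ifelse(cat_group == groups[i],
                    config$basal_level * config$enrichment_factor,
                    config$basal_level)
      gene_ids <- c(gene_ids, ids)
      labels <- c(labels, rep(paste0("restricted:", groups[i]), n))
      expected <- c(expected, rep(list(vec), n))
    }
  }
  if (config$n_ubiquitous > 0) {
    ids <- sprintf("g_ubiq_%03d", seq_len(config$n_ubiquitous))
    gene_ids <- c(gene_ids, ids)
    labels <- c(labels, rep("ubiquitous", config$n_ubiquitous))
    expected <- c(expected,
                  rep(list(rep(config$basal_level, length(categories))),
                      config$n_ubiquitous))
  }
  if (config$n_silent > 0) {
    ids <- sprintf("g_silent_%03d", seq_len(config$n_silent))
    gene_ids <- c(gene_ids, ids)
    labels <- c(labels, rep("silent", config$n_silent))
    expected <- c(expected,
                  rep(list(rep(config$silent_level, length(categories))),
                      config$n_silent))
  }

  probe_ids <- character(0)
  probe_genes <- character(0)
  rows <- list()
  for (k in seq_along(gene_ids)) {
    n_probes <- sample(seq(config$probes_per_gene[1],
                           config$probes_per_gene[2]), 1)
    for (p in seq_len(n_probes)) {
      probe_ids <- c(probe_ids, sprintf("%s_p%d", gene_ids[k], p))
      probe_genes <- c(probe_genes, gene_ids[k])
      rows[[length(rows) + 1]] <-
        expected[[k]] * lognormal_noise(length(categories),
                                        config$noise_sigma)
    }
  }
  expr <- do.call(rbind, rows)
  colnames(expr) <- categories
  probes <- atlas_probes(probe_ids, probe_genes, expr)
  truth <- data.frame(gene_id = gene_ids, true_label = labels,
                      stringsAsFactors = FALSE)
  list(probes = probes, source_map = map, truth = truth, config = config)
}

#' Generate a cargo protein list from simulated truth
#'
#' Emits one protein query per sampled gene (identifier `prot_<gene>`, a
#' single-gene mapping) with the gene's true class label attached for later
#' scoring. By default every simulated gene yields one protein.
#'
#' @param sim Result of [generate_atlas()].
#' @param n_proteins Number of proteins to sample (without replacement);
#'   `NULL` uses all genes.
#' @return A data.frame with `protein_id`, list-column `gene_ids` and
#'   `true_label`.
#' @export
generate_protein_list <- function(sim, n_proteins = NULL) {
  truth <- sim$truth
  set.seed(sim$config$seed + 1L)
  idx <- seq_len(nrow(truth))
  if (!is.null(n_proteins)) {
    if (n_proteins > nrow(truth)) stop("n_proteins exceeds simulated genes")
    idx <- sort(sample(idx, n_proteins))
  }
  data.frame(protein_id = paste0("prot_", truth$gene_id[idx]),
             gene_ids = I(as.list(truth$gene_id[idx])),
             true_label = truth$true_label[idx],
             stringsAsFactors = FALSE)
}

#' Generate a two-condition miRNA table with designed truth
#'
#' Builds miRNA rows in the designed classes of [simulation_config()]:
#' condition-unique (present at `mirna_present_level` in one condition, zero
#' in the other), shared-equal, shared-enriched at `fold_band2` or
#' `fold_band10` in either direction, plus spike-in rows at a common level.
#' Replicate noise is mean-1 log-normal with scale `noise_sigma` (exactly the
#' designed values when `noise_sigma = 0`).
#'
#' @param config A [simulation_config()].
#' @return A list with `table` ([mirna_table]) and `truth` (data.frame
#'   `mirna_id`, `class`, `designed_fold`; fold is from the first condition's
#'   point of view, `Inf`/0 for the unique classes, `NA` for spikes).
#' @export
generate_mirna_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  lvl <- config$mirna_present_level
  classes <- list(
    unique_a   = list(n = config$n_mirna_unique_a,  a = lvl, b = 0),
    unique_b   = list(n = config$n_mirna_unique_b,  a = 0,   b = lvl),
    band2_a    = list(n = config$n_mirna_band2_a,
                      a = lvl * config$fold_band2,  b = lvl),
    band10_a   = list(n = config$n_mirna_band10_a,
                      a = lvl * config$fold_band10, b = lvl),
    band2_b    = list(n = config$n_mirna_band2_b,
                      a = lvl, b = lvl * config$fold_band2),
    band10_b   = list(n = config$n_mirna_band10_b,
                      a = lvl, b = lvl * config$fold_band10),
    equal      = list(n = config$n_mirna_equal, a = lvl, b = lvl),
    spike      = list(n = config$n_spike,
                      a = config$mirna_spike_level,
                      b = config$mirna_spike_level)
  )
  ids <- character(0)
  cls <- character(0)
  mean_a <- numeric(0)
  mean_b <- numeric(0)
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    if (cl$n == 0) next
    ids <- c(ids, sprintf("%s_%04d", ifelse(nm == "spike", "spike",
                                            paste0("mir_", nm)),
                          seq_len(cl$n)))
    cls <- c(cls, rep(nm, cl$n))
    mean_a <- c(mean_a, rep(cl$a, cl$n))
    mean_b <- c(mean_b, rep(cl$b, cl$n))
  }
  r <- config$mirna_replicates
  conds <- config$mirna_conditions
  samples <- c(paste0(conds[1], "_", seq_len(r)),
               paste0(conds[2], "_", seq_len(r)))
  design <- cbind(matrix(rep(mean_a, r), ncol = r),
                  matrix(rep(mean_b, r), ncol = r))
  noise <- matrix(lognormal_noise(length(design), config$noise_sigma),
                  nrow = nrow(design))
  mat <- design * noise
  dimnames(mat) <- list(ids, samples)
  cond <- stats::setNames(rep(conds, each = r), samples)
  tab <- mirna_table(mat, cond, spike_ids = ids[cls == "spike"])
  designed_fold <- ifelse(cls == "spike", NA_real_,
                          ifelse(mean_b > 0, mean_a / mean_b, Inf))
  truth <- data.frame(mirna_id = ids, class = cls,
                      designed_fold = designed_fold,
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Score provenance recovery against simulated truth
#'
#' A `restricted:<g>` gene counts as recovered when its protein's partition
#' label is `exclusive:<g>`. Ubiquitous and silent genes count as correctly
#' handled when labeled `none`: under the median-multiple call rule a flat
#' expression vector fires in no category, so `none` is the rule's correct
#' output for both classes.
#'
#' @param profiles Data.frame with `protein_id` and `partition_label` (as
#'   produced by [run_provenance_pipeline()]; unmapped proteins may be
#'   supplied with label `unmapped`).
#' @param truth Data.frame with `protein_id` and `true_label` (as produced by
#'   [generate_protein_list()]).
#' @return A list with `n`, `overall_accuracy`, `class_accuracy` (named by
#'   true label) and `confusion` (data.frame `true_label`,
#'   `partition_label`, `n`).
#' @export
evaluate_recovery <- function(profiles, truth) {
  if (!setequal(profiles$protein_id, truth$protein_id)) {
    stop("profile and truth protein ids do not match")
  }
  m <- merge(truth[, c("protein_id", "true_label")],
             profiles[, c("protein_id", "partition_label")],
             by = "protein_id")
  expected <- ifelse(grepl("^restricted:", m$true_label),
                     sub("^restricted:", "exclusive:", m$true_label),
                     "none")
  correct <- m$partition_label == expected
  class_acc <- tapply(correct, m$true_label, mean)
  conf <- stats::aggregate(list(n = rep(1L, nrow(m))),
                           by = list(true_label = m$true_label,
                                     partition_label = m$partition_label),
                           FUN = sum)
  conf <- conf[order(conf$true_label, conf$partition_label), ]
  rownames(conf) <- NULL
  list(n = nrow(m), overall_accuracy = mean(correct),
       class_accuracy = class_acc, confusion = conf)
}

#' Write a full simulated data set to disk
#'
#' Emits the files the analysis pipelines read: `atlas.tsv` (probe level),
#' `source_map.tsv`, `proteins.tsv` (with `true_label`),
#' `mirna_intensities.tsv`, `samples.tsv`, plus `truth_genes.json`,
#' `truth_mirna.json` and a run manifest.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `atlas_sim`, `proteins` and `mirna_sim`.
#' @export
write_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_atlas(config)
  proteins <- generate_protein_list(sim)
  mir <- generate_mirna_tables(config)
  write_atlas_table(sim$probes, file.path(out_dir, "atlas.tsv"))
  write_source_map(sim$source_map, file.path(out_dir, "source_map.tsv"))
  write_protein_list(proteins, file.path(out_dir, "proteins.tsv"))
  write_mirna_table(mir$table, file.path(out_dir, "mirna_intensities.tsv"),
                    file.path(out_dir, "samples.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth_genes.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(mir$truth, file.path(out_dir, "truth_mirna.json"),
                       dataframe = "rows", digits = NA)
  write_manifest(file.path(out_dir, "manifest.json"), subcommand = "simulate",
                 params = unclass(config), inputs = character(0))
  invisible(list(atlas_sim = sim, proteins = proteins, mirna_sim = mir))
}
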
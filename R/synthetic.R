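# Synthetic-data generators: purified reference profiles, read pools, and
# case/control bulk cohorts with planted proportion effects. These emulate the
# statistical structure the deconvolution pipeline assumes (marker
# over-expression, multiplicative log-normal sample noise, linear mixing).

#' Configuration for synthetic reference profiles
#'
#' Describes the purified cell-type expression profiles the generator
#' produces: each cell type over-expresses its own marker genes by
#' `marker_fold_change` relative to a common `baseline_expression`, and every
#' entry receives multiplicative log-normal noise `exp(N(0, noise_sigma^2))`.
#'
#' @param n_cell_types Number of cell types (default 4).
#' @param cell_types Cell-type names; defaults to the four major brain types
#'   (`neuron`, `astrocyte`, `oligodendrocyte`, `microglia`).
#' @param n_genes Total number of genes, markers plus background.
#' @param n_markers_per_type Planted marker genes per cell type.
#' @param marker_fold_change Over-expression of a marker in its own type
#'   relative to baseline; must be > 1.
#' @param noise_sigma Standard deviation (log scale) of the multiplicative
#'   noise; >= 0.
#' @param baseline_expression Baseline linear-scale expression (TPM-like).
#' @param n_replicates Purified replicate samples per cell type.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cell_types = 4,
                             cell_types = NULL,
                             n_genes = 1000,
                             n_markers_per_type = 50,
                             marker_fold_change = 20,
                             noise_sigma = 0.2,
                             baseline_expression = 10,
                             n_replicates = 3,
                             seed = 42) {
  assert_count(n_cell_types, "n_cell_types", min = 2)
  assert_count(n_genes, "n_genes")
  assert_count(n_markers_per_type, "n_markers_per_type")
  assert_count(n_replicates, "n_replicates")
  assert_count(seed, "seed", min = 0)
  assert_scalar(marker_fold_change, "marker_fold_change", lower = 1, strict_lower = TRUE)
  assert_scalar(noise_sigma, "noise_sigma", lower = 0)
  assert_scalar(baseline_expression, "baseline_expression", lower = 0, strict_lower = TRUE)
  if (is.null(cell_types)) {
    cell_types <- c("neuron", "astrocyte", "oligodendrocyte", "microglia")[seq_len(min(n_cell_types, 4))]
    if (n_cell_types > 4) {
      cell_types <- c(cell_types, paste0("celltype_", seq_len(n_cell_types - 4) + 4))
    }
  }
  if (length(cell_types) != n_cell_types || anyDuplicated(cell_types)) {
    abort("`cell_types` must hold `n_cell_types` unique names", class = "cortexmix_config_error")
  }
  if (n_markers_per_type * n_cell_types > n_genes) {
    abort(paste0("invariant violated: n_markers_per_type x n_cell_types (",
                 n_markers_per_type * n_cell_types, ") exceeds n_genes (", n_genes, ")"),
          class = "cortexmix_config_error")
  }
  structure(
    list(
      n_cell_types = as.integer(n_cell_types), cell_types = cell_types,
      n_genes = as.integer(n_genes), n_markers_per_type = as.integer(n_markers_per_type),
      marker_fold_change = marker_fold_change, noise_sigma = noise_sigma,
      baseline_expression = baseline_expression, n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Simulate purified cell-type reference profiles
#'
#' Generates a gene-by-sample expression matrix with `n_replicates` purified
#' samples per cell type. A marker gene of type *k* has expected (zero-noise)
#' expression `marker_fold_change * baseline_expression` in type *k* and
#' `baseline_expression` in every other type; background genes sit at baseline
#' everywhere. Multiplicative log-normal noise with log-sd `noise_sigma` is
#' applied per entry. Output is deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#'
#' @return A `reference_profiles` list with elements `expression` (matrix),
#'   `labels` (named character, sample -> cell type), `markers` (tibble with
#'   `gene`, `cell_type`), and `config`.
#' @export
simulate_reference_profiles <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  K <- config$n_cell_types
  types <- config$cell_types
  mpt <- config$n_markers_per_type
  n_bg <- config$n_genes - mpt * K

  marker_genes <- unlist(lapply(types, function(ct) {
    paste0(toupper(substr(ct, 1, 3)), "M", sprintf("%03d", seq_len(mpt)))
  }))
  bg_genes <- if (n_bg > 0) paste0("BGD", sprintf("%04d", seq_len(n_bg))) else character()
  genes <- c(marker_genes, bg_genes)
  markers <- tibble::tibble(gene = marker_genes, cell_type = rep(types, each = mpt))

  sample_ids <- paste0(rep(types, each = config$n_replicates), "_",
                       sprintf("%02d", rep(seq_len(config$n_replicates), K)))
  labels <- setNames(rep(types, each = config$n_replicates), sample_ids)

  base <- config$baseline_expression
  clean <- matrix(base, nrow = length(genes), ncol = length(sample_ids),
                  dimnames = list(genes, sample_ids))
  for (ct in types) {
    rows <- markers$gene[markers$cell_type == ct]
    clean[rows, labels == ct] <- base * config$marker_fold_change
  }

  expr <- withr::with_seed(child_seed(config$seed, "profiles"), {
    clean * matrix(lognormal_noise(length(clean), config$noise_sigma),
                   nrow = nrow(clean))
  })

  structure(
    list(expression = expr, labels = labels, markers = markers, config = config),
    class = "reference_profiles"
  )
}

#' Simulate sequencing read pools from expression profiles
#'
#' Draws `pool_size` gene-tagged reads per sample, multinomially with
#' probability proportional to the sample's expression. Pools are returned as
#' per-sample gene counts (a compact multiset representation); see
#' [write_read_pools()] for the one-read-per-line serialization.
#'
#' @param profiles A `reference_profiles` object or a gene-by-sample matrix.
#' @param pool_size Number of reads per sample (>= 1).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `sample_id`, `gene`, `count`; counts sum to
#'   `pool_size` within each sample. Carries `pool_size` as an attribute.
#' @export
simulate_read_pools <- function(profiles, pool_size, seed = 1) {
  expr <- if (inherits(profiles, "reference_profiles")) profiles$expression else profiles
  assert_expression_matrix(expr, "profiles")
  assert_count(pool_size, "pool_size")
  assert_count(seed, "seed", min = 0)
  zero_cols <- colSums(expr) <= 0
  if (any(zero_cols)) {
    abort(paste0("all-zero expression profile for sample(s): ",
                 paste(colnames(expr)[zero_cols], collapse = ", ")),
          class = "cortexmix_input_error")
  }
  withr::with_seed(child_seed(seed, "pools"), {
    out <- lapply(colnames(expr), function(s) {
      counts <- as.vector(rmultinom(1, pool_size, expr[, s]))
      keep <- counts > 0
      tibble::tibble(sample_id = s, gene = rownames(expr)[keep], count = counts[keep])
    })
    pools <- dplyr::bind_rows(out)
    attr(pools, "pool_size") <- as.integer(pool_size)
    pools
  })
}

#' Specification of a synthetic case/control cohort
#'
#' Describes a two-group bulk cohort whose true cell-type proportions shift
#' with disease status. Control group means default to values typical of
#' cerebral-cortex admixtures; the planted case effects default to the
#' magnitudes reported for temporal-cortex AD contrasts (neuron -0.17,
#' astrocyte +0.23). After adding the planted effects, the case mean vector is
#' returned to the simplex by rebalancing only the cell types *without* an
#' explicit effect (proportionally to their control means), so each planted
#' effect is realized exactly as a case-minus-control mean difference.
#'
#' @param n_cases,n_controls Group sizes.
#' @param effect_per_type Named numeric vector of signed shifts in true mean
#'   proportion for cases (may cover a subset of cell types).
#' @param proportion_noise_sd Per-subject truncated-Gaussian sd around the
#'   group mean proportions (renormalized to the simplex after truncation at 0).
#' @param control_means Named control mean proportions (must lie on the simplex).
#' @param expression_noise_sigma Log-sd of multiplicative noise applied to the
#'   mixed bulk expression.
#' @param covariate_spec Named list of `c(mean, sd)` pairs for Gaussian
#'   covariates recorded in the metadata (defaults: RIN, PMI, age at death).
#' @param seed Integer seed.
#'
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 60,
                        n_controls = 60,
                        effect_per_type = c(neuron = -0.17, astrocyte = 0.23),
                        proportion_noise_sd = 0.05,
                        control_means = c(neuron = 0.35, astrocyte = 0.30,
                                          oligodendrocyte = 0.30, microglia = 0.05),
                        expression_noise_sigma = 0.2,
                        covariate_spec = list(RIN = c(mean = 7, sd = 1),
                                              PMI = c(mean = 12, sd = 6),
                                              age_at_death = c(mean = 85, sd = 8)),
                        seed = 1) {
  assert_count(n_cases, "n_cases")
  assert_count(n_controls, "n_controls")
  assert_scalar(proportion_noise_sd, "proportion_noise_sd", lower = 0)
  assert_scalar(expression_noise_sigma, "expression_noise_sigma", lower = 0)
  assert_count(seed, "seed", min = 0)
  if (is.null(names(control_means)) || anyDuplicated(names(control_means))) {
    abort("`control_means` must be uniquely named by cell type", class = "cortexmix_config_error")
  }
  if (any(control_means < 0) || abs(sum(control_means) - 1) > 1e-9) {
    abort("`control_means` must lie on the probability simplex", class = "cortexmix_config_error")
  }
  if (length(effect_per_type) > 0 &&
      (is.null(names(effect_per_type)) ||
       !all(names(effect_per_type) %in% names(control_means)))) {
    abort("`effect_per_type` names must be a subset of `control_means` names",
          class = "cortexmix_config_error")
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         effect_per_type = effect_per_type, proportion_noise_sd = proportion_noise_sd,
         control_means = control_means, expression_noise_sigma = expression_noise_sigma,
         covariate_spec = covariate_spec, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Shift the control means by the planted effects and restore the simplex by
# rebalancing only types without an explicit effect. Errors (before any
# sampling) if a mean leaves [0, 1].
shift_group_means <- function(control_means, effects) {
  shifted <- control_means
  shifted[names(effects)] <- shifted[names(effects)] + effects
  bad <- shifted < 0 | shifted > 1
  if (any(bad)) {
    abort(paste0("planted effect pushes mean proportion outside [0, 1] for: ",
                 paste(names(shifted)[bad], collapse = ", ")),
          class = "cortexmix_config_error")
  }
  free <- setdiff(names(control_means), names(effects))
  residual <- 1 - sum(shifted)
  if (length(free) == 0) {
    if (abs(residual) > 1e-9) {
      abort("effects must sum to zero when every cell type has an explicit effect",
            class = "cortexmix_config_error")
    }
    return(shifted)
  }
  shifted[free] <- shifted[free] + residual * control_means[free] / sum(control_means[free])
  bad <- shifted < 0 | shifted > 1
  if (any(bad)) {
    abort(paste0("simplex rebalancing pushes mean proportion outside [0, 1] for: ",
                 paste(names(shifted)[bad], collapse = ", ")),
          class = "cortexmix_config_error")
  }
  shifted
}

#' Simulate a case/control bulk cohort with planted proportion effects
#'
#' Each subject receives a true proportion vector drawn as a truncated-Gaussian
#' perturbation (sd `proportion_noise_sd`, truncated at 0, renormalized) around
#' its group mean; the bulk expression column is the proportion-weighted
#' mixture of the per-type mean reference profiles with multiplicative
#' log-normal noise. True proportions are returned for recovery testing.
#'
#' @param profiles A `reference_profiles` object (or list with `expression`
#'   matrix and `labels`).
#' @param spec A [cohort_spec()].
#'
#' @return A list with `expression` (gene x sample matrix), `proportions`
#'   (tibble of true proportions), and `metadata` (tibble with `sample_id`,
#'   `donor_id`, `status`, and covariates).
#' @export
simulate_bulk_cohort <- function(profiles, spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  expr <- profiles$expression
  labels <- profiles$labels
  assert_expression_matrix(expr, "profiles")
  types <- canonical_types(names(spec$control_means))
  if (!all(types %in% labels)) {
    abort(paste0("profiles are missing cell type(s): ",
                 paste(setdiff(types, labels), collapse = ", ")),
          class = "cortexmix_input_error")
  }
  type_means <- vapply(types, function(ct) {
    rowMeans(expr[, names(labels)[labels == ct], drop = FALSE])
  }, numeric(nrow(expr)))

  control_means <- spec$control_means[types]
  case_means <- shift_group_means(control_means, spec$effect_per_type)

  n <- spec$n_cases + spec$n_controls
  status <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  sample_ids <- sprintf("S%04d", seq_len(n))

  withr::with_seed(child_seed(spec$seed, "cohort"), {
    P <- t(vapply(seq_len(n), function(i) {
      mu <- if (status[i] == "case") case_means else control_means
      p <- pmax(mu + rnorm(length(mu), 0, spec$proportion_noise_sd), 0)
      while (sum(p) <= 0) {
        p <- pmax(mu + rnorm(length(mu), 0, spec$proportion_noise_sd), 0)
      }
      p / sum(p)
    }, numeric(length(types))))
    dimnames(P) <- list(sample_ids, types)

    bulk <- type_means %*% t(P)
    colnames(bulk) <- sample_ids
    bulk <- bulk * matrix(lognormal_noise(length(bulk), spec$expression_noise_sigma),
                          nrow = nrow(bulk))

    covs <- lapply(spec$covariate_spec, function(cs) rnorm(n, cs[["mean"]], cs[["sd"]]))
    metadata <- tibble::tibble(
      sample_id = sample_ids,
      donor_id = sample_ids,
      status = factor(status, levels = c("control", "case")),
      batch = factor(rep_len(c("b1", "b2"), n)),
      sex = factor(rep_len(c("F", "M"), n)),
      !!!covs
    )
    list(expression = bulk, proportions = prop_as_tibble(P), metadata = metadata)
  })
}

#' @export
print.reference_profiles <- function(x, ...) {
  cat("Synthetic reference profiles:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples;",
      length(unique(x$labels)), "cell types;",
      nrow(x$markers), "planted markers\n")
  invisible(x)
}
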
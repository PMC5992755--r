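# Accuracy and robustness harness: RMSE scoring, chimeric admixture designs,
# read/expression pooling, chimeric validation with donor hold-out, per-gene
# dropout robustness, and leave-one-out accuracy.

#' Root-mean-square error between proportion matrices
#'
#' `sqrt(mean((estimated - truth)^2))` over all compared entries. Inputs may
#' be proportion tibbles (with `sample_id`), samples-by-types matrices, or
#' `deconvolution_result` objects; rows are aligned by sample id and columns
#' by cell type, and any mismatch in dimensions or labels is an error.
#'
#' @param estimated,truth Proportion containers of matching shape and labels.
#' @return A single non-negative number.
#' @export
rmse <- function(estimated, truth) {
  e <- prop_as_matrix(estimated)
  t_ <- prop_as_matrix(truth)
  if (!identical(dim(e), dim(t_))) {
    abort(paste0("shape mismatch: ", nrow(e), "x", ncol(e), " vs ",
                 nrow(t_), "x", ncol(t_)), class = "cortexmix_input_error")
  }
  if (!identical(colnames(e), colnames(t_))) {
    abort("cell-type labels differ between estimated and truth",
          class = "cortexmix_input_error")
  }
  if (!identical(rownames(e), rownames(t_))) {
    if (!setequal(rownames(e), rownames(t_))) {
      abort("sample ids differ between estimated and truth", class = "cortexmix_input_error")
    }
    t_ <- t_[rownames(e), , drop = FALSE]
  }
  sqrt(mean((e - t_)^2))
}

# Integer allocation of `total` across categories by largest-remainder
# rounding of p * total; conserves the total exactly (ties broken by index).
largest_remainder <- function(p, total) {
  raw <- p * total
  base <- floor(raw)
  shortfall <- round(total - sum(base))
  if (shortfall > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(shortfall)]
    base[idx] <- base[idx] + 1
  }
  out <- as.integer(base)
  names(out) <- names(p)
  out
}

# Default per-type admixture ranges for cerebral-cortex chimeric libraries.
default_chimeric_ranges <- function() {
  list(neuron = c(0.02, 0.36), astrocyte = c(0.22, 0.76),
       oligodendrocyte = c(0.06, 0.62), microglia = c(0.01, 0.05))
}

#' Build a chimeric admixture design
#'
#' Enumerates `repeats x n_distributions` admixture tasks over a set of
#' proportion vectors. If `distributions` are supplied (a matrix/tibble of
#' proportion vectors, one row per distribution) they are validated and used
#' verbatim; otherwise a seeded Latin-hypercube draw inside the per-type
#' ranges, renormalized to the simplex and re-checked against the ranges,
#' produces `n_distributions` vectors. The defaults reproduce the standard
#' 720 x 32 = 23,040-library benchmark with 400,000 pooled reads per library.
#'
#' @param ranges Named list of `c(min, max)` proportion bounds per cell type.
#' @param n_distributions Number of distinct proportion vectors (default 32).
#' @param repeats Times each distribution is re-instantiated with different
#'   donors (default 720).
#' @param total_reads Reads per pooled library in read mode (default 400000).
#' @param seed Integer seed for the distribution draw.
#' @param distributions Optional explicit proportion vectors (matrix or data
#'   frame, one row per distribution, columns named by cell type).
#'
#' @return A `chimeric_design` with `distributions` tibble, `repeats`,
#'   `total_reads`, `ranges`, `seed`, and `n_tasks`.
#' @export
build_chimeric_design <- function(ranges = default_chimeric_ranges(),
                                  n_distributions = 32, repeats = 720,
                                  total_reads = 400000, seed = 1,
                                  distributions = NULL) {
  assert_count(n_distributions, "n_distributions")
  assert_count(repeats, "repeats")
  assert_count(total_reads, "total_reads")
  assert_count(seed, "seed", min = 0)
  types <- canonical_types(names(ranges))
  ranges <- ranges[types]
  mins <- vapply(ranges, `[`, numeric(1), 1)
  maxs <- vapply(ranges, `[`, numeric(1), 2)
  if (any(mins < 0) || any(maxs > 1) || any(mins > maxs)) {
    abort("each range must satisfy 0 <= min <= max <= 1", class = "cortexmix_config_error")
  }
  if (sum(mins) > 1 || sum(maxs) < 1) {
    abort(paste0("infeasible ranges: sum of minima = ", round(sum(mins), 4),
                 ", sum of maxima = ", round(sum(maxs), 4),
                 "; need sum(min) <= 1 <= sum(max)"),
          class = "cortexmix_config_error")
  }
  in_ranges <- function(m) {
    apply(m, 1, function(x) all(x >= mins - 1e-12 & x <= maxs + 1e-12) &&
            abs(sum(x) - 1) <= 1e-9)
  }
  if (!is.null(distributions)) {
    D <- as.matrix(as.data.frame(distributions)[, types, drop = FALSE])
    ok <- in_ranges(D)
    if (any(!ok)) {
      abort(paste0("supplied distribution(s) violate the ranges or the simplex at index: ",
                   paste(which(!ok), collapse = ", ")),
            class = "cortexmix_config_error")
    }
    if (nrow(D) != n_distributions) n_distributions <- nrow(D)
  } else {
    D <- withr::with_seed(child_seed(seed, "design"), {
      acc <- matrix(numeric(0), ncol = length(types))
      attempts <- 0L
      while (nrow(acc) < n_distributions && attempts < 200L) {
        attempts <- attempts + 1L
        u <- lhs::randomLHS(max(4L * n_distributions, 64L), length(types))
        cand <- sweep(sweep(u, 2, maxs - mins, "*"), 2, mins, "+")
        cand <- cand / rowSums(cand)
        acc <- rbind(acc, cand[in_ranges(cand), , drop = FALSE])
      }
      if (nrow(acc) < n_distributions) {
        abort("could not draw enough in-range simplex points; widen the ranges",
              class = "cortexmix_config_error")
      }
      acc[seq_len(n_distributions), , drop = FALSE]
    })
  }
  colnames(D) <- types
  structure(
    list(
      distributions = tibble::as_tibble(D) |>
        dplyr::mutate(distribution = dplyr::row_number(), .before = 1),
      repeats = as.integer(repeats),
      total_reads = as.integer(total_reads),
      ranges = ranges, seed = as.integer(seed),
      cell_types = types,
      n_tasks = as.integer(repeats) * as.integer(n_distributions)
    ),
    class = "chimeric_design"
  )
}

#' @export
print.chimeric_design <- function(x, ...) {
  cat("Chimeric design:", nrow(x$distributions), "distributions x", x$repeats,
      "repeats =", x$n_tasks, "tasks;", x$total_reads, "reads/library\n")
  invisible(x)
}

#' Enumerate the admixture tasks of a chimeric design
#'
#' @param design A `chimeric_design`.
#' @return A tibble with `task`, `distribution`, `rep_id`.
#' @export
design_tasks <- function(design) {
  n_dist <- nrow(design$distributions)
  tibble::tibble(
    task = seq_len(design$n_tasks),
    distribution = rep(seq_len(n_dist), times = design$repeats),
    rep_id = rep(seq_len(design$repeats), each = n_dist)
  )
}

#' Pool one chimeric library at known proportions
#'
#' Builds a synthetic mixed sample from one donor per cell type, with the
#' truth vector attached. In `expression` mode the bulk column is the exact
#' proportion-weighted sum of the donor profiles (the fast desk-scale proxy).
#' In `reads` mode per-type read counts are allocated by largest-remainder
#' rounding of `proportion * total_reads` (so counts sum exactly to
#' `total_reads`) and reads are sampled from the donor's read pool — without
#' replacement when the pool is large enough, with replacement (and a message)
#' otherwise.
#'
#' @param profiles Gene-by-sample matrix or `reference_profiles`.
#' @param labels Named sample -> cell-type labels (taken from `profiles` when
#'   it is a `reference_profiles`).
#' @param donor_ids Named character vector, cell type -> donor sample id.
#' @param proportions Named proportion vector on the simplex.
#' @param total_reads Reads per library (read mode).
#' @param mode `"expression"` or `"reads"`.
#' @param pools Read pools from [simulate_read_pools()] (read mode).
#' @param seed Integer seed (read mode sampling).
#'
#' @return A list with `expression` (named numeric vector; in read mode these
#'   are read counts per gene), `truth`, `donor_ids`, `mode`, and in read mode
#'   `read_counts` (per-type allocation).
#' @export
pool_chimeric_library <- function(profiles, labels = NULL, donor_ids, proportions,
                                  total_reads = 400000,
                                  mode = c("expression", "reads"),
                                  pools = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (inherits(profiles, "reference_profiles")) {
    labels <- profiles$labels
    expr <- profiles$expression
  } else {
    expr <- profiles
  }
  types <- canonical_types(names(proportions))
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must lie on the probability simplex", class = "cortexmix_input_error")
  }
  missing <- setdiff(types, names(donor_ids))
  if (length(missing) > 0) {
    abort(paste0("no donor supplied for cell type(s): ", paste(missing, collapse = ", ")),
          class = "cortexmix_input_error")
  }
  truth <- proportions[types]
  if (mode == "expression") {
    cols <- expr[, unname(donor_ids[types]), drop = FALSE]
    mix <- as.vector(cols %*% truth)
    names(mix) <- rownames(expr)
    return(list(expression = mix, truth = truth, donor_ids = donor_ids[types],
                mode = mode))
  }
  if (is.null(pools)) {
    abort("read mode requires `pools` from simulate_read_pools()",
          class = "cortexmix_input_error")
  }
  alloc <- largest_remainder(truth, total_reads)
  counts <- withr::with_seed(child_seed(seed, "mixing"), {
    acc <- list()
    for (ct in types) {
      if (alloc[[ct]] == 0) next
      pool <- pools[pools$sample_id == donor_ids[[ct]], ]
      if (nrow(pool) == 0) {
        abort(paste0("no read pool for donor '", donor_ids[[ct]], "'"),
              class = "cortexmix_input_error")
      }
      reads <- rep(pool$gene, pool$count)
      replace <- length(reads) < alloc[[ct]]
      if (replace) {
        inform(paste0("donor pool '", donor_ids[[ct]], "' smaller than allocation (",
                      length(reads), " < ", alloc[[ct]], "); sampling with replacement"))
      }
      drawn <- sample(reads, alloc[[ct]], replace = replace)
      acc[[ct]] <- table(drawn)
    }
    acc
  })
  gene_counts <- setNames(numeric(nrow(expr)), rownames(expr))
  for (tb in counts) gene_counts[names(tb)] <- gene_counts[names(tb)] + as.numeric(tb)
  list(expression = gene_counts, truth = truth, donor_ids = donor_ids[types],
       mode = mode, read_counts = alloc)
}

# Deterministic donor rotation: for cell type at position k (canonical order)
# with donors sorted by id, task `t` uses donor ((t - 1 + seed + k) mod n_k) + 1.
donor_assignment <- function(task, types, donors_by_type, seed) {
  vapply(seq_along(types), function(k) {
    d <- donors_by_type[[types[k]]]
    d[((task - 1 + seed + k) %% length(d)) + 1]
  }, character(1))
}

# Shared preparation for chimeric runs: task table with donor assignment,
# mixture matrix (marker rows only), per-combo ssNMF initial bases with
# contributing donors held out, and the truth matrix.
prep_chimeric <- function(profiles, markers, design, holdout, mode, pools,
                          seed, total_reads) {
  panel <- as_reference_panel(profiles)
  types <- design$cell_types
  bad <- setdiff(types, unique(panel$labels))
  if (length(bad) > 0) {
    abort(paste0("profiles lack donors for cell type(s): ", paste(bad, collapse = ", ")),
          class = "cortexmix_input_error")
  }
  donors_by_type <- lapply(setNames(types, types), function(ct) {
    sort(names(panel$labels)[panel$labels == ct])
  })
  if (holdout && any(vapply(donors_by_type, length, integer(1)) < 2)) {
    abort("donor hold-out needs >= 2 donors per cell type so a non-contributing reference remains",
          class = "cortexmix_input_error")
  }
  tasks <- design_tasks(design)
  D <- as.matrix(design$distributions[, types, drop = FALSE])
  assign <- t(vapply(tasks$task, donor_assignment, character(length(types)),
                     types = types, donors_by_type = donors_by_type, seed = seed))
  colnames(assign) <- types
  combo_key <- apply(assign, 1, paste, collapse = "|")

  mk <- markers[markers$gene %in% rownames(panel$expression), , drop = FALSE]
  mk <- mk[mk$cell_type %in% types, , drop = FALSE]
  lost <- setdiff(types, unique(mk$cell_type))
  if (length(lost) > 0) {
    abort(paste0("no marker available for cell type(s): ", paste(lost, collapse = ", ")),
          class = "cortexmix_marker_error")
  }
  mk <- mk[order(match(mk$cell_type, types), mk$gene), ]
  expr_m <- panel$expression[mk$gene, , drop = FALSE]

  # mixture matrix, marker rows x tasks
  V <- matrix(0, nrow = nrow(mk), ncol = nrow(tasks),
              dimnames = list(mk$gene, paste0("task_", tasks$task)))
  truth <- matrix(0, nrow = nrow(tasks), ncol = length(types),
                  dimnames = list(colnames(V), types))
  if (mode == "expression") {
    for (i in seq_len(nrow(tasks))) {
      p <- D[tasks$distribution[i], ]
      V[, i] <- expr_m[, assign[i, ], drop = FALSE] %*% p
      truth[i, ] <- p
    }
  } else {
    for (i in seq_len(nrow(tasks))) {
      p <- D[tasks$distribution[i], ]
      lib <- pool_chimeric_library(panel$expression, panel$labels,
                                   donor_ids = setNames(assign[i, ], types),
                                   proportions = setNames(p, types),
                                   total_reads = total_reads, mode = "reads",
                                   pools = pools, seed = seed + i)
      V[, i] <- lib$expression[mk$gene]
      truth[i, ] <- p
    }
  }

  # per-combo marker-constrained initial basis from non-contributing donors
  combos <- unique(combo_key)
  W0_by_combo <- lapply(setNames(combos, combos), function(key) {
    used <- strsplit(key, "|", fixed = TRUE)[[1]]
    W <- matrix(0, nrow = nrow(mk), ncol = length(types),
                dimnames = list(mk$gene, types))
    for (j in seq_along(types)) {
      ct <- types[j]
      ref <- donors_by_type[[ct]]
      if (holdout) ref <- setdiff(ref, used)
      W[mk$gene[mk$cell_type == ct], ct] <-
        rowMeans(expr_m[mk$gene[mk$cell_type == ct], ref, drop = FALSE])
    }
    W
  })

  list(panel = panel, types = types, tasks = tasks, assign = assign,
       combo_key = combo_key, V = V, truth = truth, markers = mk,
       W0_by_combo = W0_by_combo, donors_by_type = donors_by_type)
}

# Estimate proportions for all chimeric tasks, optionally excluding marker
# rows (`drop_rows`, integer indices into the marker set). ssNMF runs
# per-column against the combo's held-out basis; dsa / mean_profile run
# jointly per combo. `engine` may also be a function(V_markers, truth_types)
# used as an oracle in harness-correctness tests.
estimate_chimeric <- function(prep, engine, opts = list(), drop_rows = integer()) {
  keep <- setdiff(seq_len(nrow(prep$V)), drop_rows)
  mk <- prep$markers[keep, , drop = FALSE]
  lost <- setdiff(prep$types, unique(mk$cell_type))
  if (length(lost) > 0) {
    abort(paste0("gene drop empties cell type(s): ", paste(lost, collapse = ", ")),
          class = "cortexmix_marker_error")
  }
  V <- prep$V[keep, , drop = FALSE]
  n_tasks <- ncol(V)
  K <- length(prep$types)
  P <- matrix(NA_real_, nrow = n_tasks, ncol = K,
              dimnames = list(colnames(V), prep$types))
  if (is.function(engine)) {
    for (i in seq_len(n_tasks)) P[i, ] <- engine(V[, i], prep$truth[i, ])
    return(P)
  }
  o <- modifyList(list(max_iter = 2000, tol = 1e-6), opts)
  if (engine == "ssnmf") {
    for (key in unique(prep$combo_key)) {
      idx <- which(prep$combo_key == key)
      W0 <- prep$W0_by_combo[[key]][keep, , drop = FALSE]
      mask <- W0 == 0
      for (i in idx) {
        v <- V[, i, drop = FALSE]
        H0 <- matrix(sum(v) / mean(colSums(W0)) / K, nrow = K, ncol = 1)
        fit <- ssnmf_core(v, W0, H0, mask, o$max_iter, o$tol)
        h <- fit$H[, 1]
        P[i, ] <- h / sum(h)
      }
    }
  } else if (engine %in% c("dsa", "mean_profile")) {
    res <- deconvolve(V, markers = mk, engine = engine, opts = opts)
    P[] <- prop_as_matrix(res)[rownames(P), prep$types]
  } else {
    abort(paste0("unknown engine '", engine, "'; valid engines: ",
                 paste(VALID_ENGINES, collapse = ", ")),
          class = "cortexmix_config_error")
  }
  P
}

#' Run the chimeric-admixture validation
#'
#' For every task of the design, donors are chosen by a deterministic rotation
#' over each cell type's samples (a fixed function of the task index and the
#' seed), a chimeric sample is built at the task's known proportions, the
#' sample is deconvolved against a reference panel that excludes the
#' contributing donors (when `holdout = TRUE`), and the estimate is scored
#' against the truth.
#'
#' @param profiles A `reference_profiles` object or list with `expression` and
#'   `labels` supplying the donor samples.
#' @param markers Marker tibble (`gene`, `cell_type`).
#' @param design A [build_chimeric_design()].
#' @param engine Deconvolution engine name, or a `function(v, truth)` oracle
#'   returning a proportion vector (used to verify the harness itself).
#' @param holdout Exclude contributing donors from the reference (default TRUE).
#' @param mode `"expression"` (exact linear pooling, the desk-scale default)
#'   or `"reads"` (read-level pooling; requires `pools`).
#' @param pools Read pools for read mode.
#' @param seed Integer seed controlling donor rotation (and read sampling).
#' @param opts Engine options.
#'
#' @return An `evaluation_result`: `errors` (long tibble: `task`,
#'   `distribution`, `rep_id`, `cell_type`, `estimated`, `truth`, `error`),
#'   `per_library` (per-task RMSE), pooled `rmse`, `n` (compared values),
#'   `engine`, `estimated` and `truth` proportion tibbles.
#' @export
run_chimeric_validation <- function(profiles, markers, design, engine = "ssnmf",
                                    holdout = TRUE, mode = c("expression", "reads"),
                                    pools = NULL, seed = 1, opts = list()) {
  mode <- match.arg(mode)
  prep <- prep_chimeric(profiles, markers, design, holdout, mode, pools,
                        seed, design$total_reads)
  P <- estimate_chimeric(prep, engine, opts)
  errs <- P - prep$truth
  errors <- tibble::tibble(
    task = rep(prep$tasks$task, times = ncol(P)),
    distribution = rep(prep$tasks$distribution, times = ncol(P)),
    rep_id = rep(prep$tasks$rep_id, times = ncol(P)),
    cell_type = rep(colnames(P), each = nrow(P)),
    estimated = as.vector(P),
    truth = as.vector(prep$truth),
    error = as.vector(errs)
  )
  per_library <- dplyr::summarise(
    dplyr::group_by(errors, .data$task, .data$distribution, .data$rep_id),
    rmse = sqrt(mean(.data$error^2)), .groups = "drop"
  )
  structure(
    list(errors = errors, per_library = per_library,
         rmse = sqrt(mean(errs^2)), n = length(errs),
         engine = if (is.function(engine)) "oracle" else engine,
         estimated = prop_as_tibble(P), truth = prop_as_tibble(prep$truth),
         mode = mode, holdout = holdout, seed = seed),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Chimeric validation (", x$engine, "): pooled RMSE = ",
      signif(x$rmse, 4), " over ", x$n, " compared values (",
      nrow(x$per_library), " libraries)\n", sep = "")
  invisible(x)
}

#' @export
tidy.evaluation_result <- function(x, ...) x$errors

#' @export
glance.evaluation_result <- function(x, ...) {
  tibble::tibble(engine = x$engine, rmse = x$rmse, n = x$n,
                 n_libraries = nrow(x$per_library), mode = x$mode,
                 holdout = x$holdout)
}

#' Per-gene dropout robustness of the deconvolution
#'
#' Re-runs the chimeric validation with each marker gene removed in turn and
#' records the RMSE between the full-panel proportion estimates and the
#' gene-dropped estimates. A gene whose cell type has a single marker is
#' skipped with a warning (dropping it would empty the type); a requested
#' gene that is not in the marker panel changes nothing and scores 0.
#'
#' @param profiles Donor profiles (as in [run_chimeric_validation()]).
#' @param markers Marker tibble.
#' @param design A [build_chimeric_design()].
#' @param engine Deconvolution engine (default `"ssnmf"`).
#' @param genes Genes to drop (default: every marker present in the profiles).
#' @param holdout Donor hold-out flag (default TRUE).
#' @param seed Integer seed.
#' @param opts Engine options.
#'
#' @return A `dropout_result`: `per_gene` tibble (`gene`, `cell_type`,
#'   `rmse_delta`), `mean`, `sd`, and the `baseline_rmse` against truth.
#' @export
gene_dropout_robustness <- function(profiles, markers, design, engine = "ssnmf",
                                    genes = NULL, holdout = TRUE, seed = 1,
                                    opts = list()) {
  prep <- prep_chimeric(profiles, markers, design, holdout, "expression", NULL,
                        seed, design$total_reads)
  per_type_counts <- table(prep$markers$cell_type)
  if (any(per_type_counts < 2)) {
    warn(paste0("cell type(s) with a single marker: ",
                paste(names(per_type_counts)[per_type_counts < 2], collapse = ", "),
                "; their genes are skipped"))
  }
  if (is.null(genes)) genes <- prep$markers$gene
  full <- estimate_chimeric(prep, engine, opts)
  res <- lapply(genes, function(g) {
    row <- match(g, prep$markers$gene)
    if (is.na(row)) {
      return(tibble::tibble(gene = g, cell_type = NA_character_, rmse_delta = 0))
    }
    ct <- prep$markers$cell_type[row]
    if (per_type_counts[[ct]] < 2) {
      return(tibble::tibble(gene = g, cell_type = ct, rmse_delta = NA_real_))
    }
    dropped <- estimate_chimeric(prep, engine, opts, drop_rows = row)
    tibble::tibble(gene = g, cell_type = ct, rmse_delta = rmse(dropped, full))
  })
  per_gene <- dplyr::bind_rows(res)
  vals <- per_gene$rmse_delta[!is.na(per_gene$rmse_delta)]
  structure(
    list(per_gene = per_gene, mean = mean(vals), sd = sd(vals),
         baseline_rmse = rmse(full, prep$truth), engine = if (is.function(engine)) "oracle" else engine),
    class = "dropout_result"
  )
}

#' @export
print.dropout_result <- function(x, ...) {
  cat("Gene-dropout robustness (", x$engine, "): mean per-gene RMSE delta = ",
      signif(x$mean, 4), ", sd = ", signif(x$sd, 4), " over ",
      sum(!is.na(x$per_gene$rmse_delta)), " genes\n", sep = "")
  invisible(x)
}

#' @export
tidy.dropout_result <- function(x, ...) x$per_gene

#' @export
glance.dropout_result <- function(x, ...) {
  tibble::tibble(mean_rmse_delta = x$mean, sd_rmse_delta = x$sd,
                 n_genes = sum(!is.na(x$per_gene$rmse_delta)),
                 baseline_rmse = x$baseline_rmse, engine = x$engine)
}

#' Leave-one-out accuracy of a reference panel
#'
#' Runs a single leave-one-out pass (no removal): each purified sample is
#' deconvolved as a one-column bulk against the remaining samples, and its
#' predicted proportion for its own labeled type is recorded. Also reports the
#' RMSE of the predicted proportion vectors against one-hot label vectors.
#'
#' @param panel A [reference_panel()] (or coercible object).
#' @param markers Marker tibble.
#' @param engine Deconvolution engine (default `"ssnmf"`).
#' @param opts Engine options.
#'
#' @return A `loocv_result`: `per_sample` (tibble with the full predicted
#'   vector and `self_proportion`), `mean_accuracy`, `sd_accuracy`,
#'   `rmse_onehot`.
#' @export
loocv_accuracy <- function(panel, markers, engine = "ssnmf", opts = list()) {
  panel <- as_reference_panel(panel)
  counts <- table(panel$labels)
  if (any(counts < 2)) {
    abort(paste0("loocv_accuracy needs >= 2 samples per cell type; short: ",
                 paste(names(counts)[counts < 2], collapse = ", ")),
          class = "cortexmix_input_error")
  }
  pass <- loocv_pass(panel, markers, engine = engine, opts = opts)
  types <- panel_cell_types(panel)
  pred <- as.matrix(pass[, types])
  rownames(pred) <- pass$sample_id
  onehot <- matrix(0, nrow = nrow(pred), ncol = ncol(pred),
                   dimnames = dimnames(pred))
  onehot[cbind(seq_len(nrow(pred)), match(pass$cell_type, types))] <- 1
  structure(
    list(per_sample = pass,
         mean_accuracy = mean(pass$self_proportion),
         sd_accuracy = sd(pass$self_proportion),
         rmse_onehot = rmse(pred, onehot),
         engine = engine),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("LOOCV accuracy (", x$engine, "): mean self-type proportion = ",
      sprintf("%.1f%%", 100 * x$mean_accuracy), " (sd ",
      sprintf("%.1f", 100 * x$sd_accuracy), "), one-hot RMSE = ",
      signif(x$rmse_onehot, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.loocv_result <- function(x, ...) x$per_sample

#' @export
glance.loocv_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
                 rmse_onehot = x$rmse_onehot, n_samples = nrow(x$per_sample),
                 engine = x$engine)
}
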
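# Proportion-estimation engines. All three share the same contract: bulk
# expression in (genes x samples), a marker panel mapping genes to cell types,
# and a `deconvolution_result` out, with sample-wise proportions on the
# probability simplex.

VALID_ENGINES <- c("ssnmf", "dsa", "mean_profile")

# Align bulk, markers (and optionally a panel) on a common marker gene set.
# Errors if any cell type is left without a marker in the bulk.
align_marker_input <- function(bulk, markers, panel = NULL) {
  bulk <- as_bulk_matrix(bulk)
  if (!is.data.frame(markers) || !all(c("gene", "cell_type") %in% names(markers))) {
    abort("`markers` must be a tibble with `gene` and `cell_type` columns",
          class = "cortexmix_input_error")
  }
  if (anyDuplicated(markers$gene)) {
    abort("a marker gene is assigned to more than one cell type",
          class = "cortexmix_input_error")
  }
  genes <- intersect(markers$gene, rownames(bulk))
  if (!is.null(panel)) genes <- intersect(genes, rownames(panel$expression))
  mk <- markers[markers$gene %in% genes, , drop = FALSE]
  missing_types <- setdiff(unique(markers$cell_type), unique(mk$cell_type))
  if (length(missing_types) > 0) {
    abort(paste0("no marker present in bulk for cell type(s): ",
                 paste(missing_types, collapse = ", ")),
          class = "cortexmix_marker_error")
  }
  types <- canonical_types(mk$cell_type)
  mk <- mk[order(match(mk$cell_type, types), mk$gene), ]
  list(V = bulk[mk$gene, , drop = FALSE], markers = mk, types = types)
}

# Per-sample mean expression of each cell type's markers (samples x types),
# robust to single-sample input.
marker_type_means <- function(V, markers, types) {
  m <- vapply(types, function(ct) {
    colMeans(V[markers$gene[markers$cell_type == ct], , drop = FALSE])
  }, numeric(ncol(V)))
  if (!is.matrix(m)) {
    m <- matrix(m, nrow = ncol(V), dimnames = list(colnames(V), types))
  } else {
    rownames(m) <- colnames(V)
  }
  m
}

new_deconvolution_result <- function(proportions, engine, cell_types, markers,
                                     signature = NULL, objective_trace = numeric(),
                                     iterations = 0L, converged = TRUE,
                                     relative = FALSE) {
  structure(
    list(proportions = prop_as_tibble(proportions), signature = signature,
         objective_trace = objective_trace, iterations = as.integer(iterations),
         converged = converged, engine = engine, cell_types = cell_types,
         markers = markers, relative = relative),
    class = "deconvolution_result"
  )
}

# ---- ssNMF ----------------------------------------------------------------

# Build the marker-constrained initial basis W0: own-type entries are the
# per-type mean marker expression in the reference panel, off-type entries 0.
# The zero pattern is the semi-supervised constraint; multiplicative updates
# preserve it, and it is re-projected after every W update regardless.
ssnmf_initial_basis <- function(panel, markers, types) {
  W <- matrix(0, nrow = nrow(markers), ncol = length(types),
              dimnames = list(markers$gene, types))
  for (ct in types) {
    cols <- names(panel$labels)[panel$labels == ct]
    if (length(cols) == 0) {
      abort(paste0("reference panel has no sample for cell type '", ct, "'"),
            class = "cortexmix_input_error")
    }
    rows <- markers$gene[markers$cell_type == ct]
    W[rows, ct] <- rowMeans(panel$expression[rows, cols, drop = FALSE])
  }
  if (any(colSums(W) <= 0)) {
    abort("signature has an all-zero cell-type column", class = "cortexmix_input_error")
  }
  W
}

# Frobenius multiplicative updates with hard marker constraints. V is
# genes x samples, W0 genes x types (off-type zeros), H0 types x samples.
ssnmf_core <- function(V, W, H, mask, max_iter, tol) {
  eps <- 1e-12
  trace <- numeric(max_iter)
  f_prev <- Inf
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    W[mask] <- 0
    R <- V - W %*% H
    f <- sqrt(sum(R * R))
    trace[it] <- f
    if (is.finite(f_prev) && abs(f_prev - f) <= tol * max(f_prev, eps)) {
      converged <- TRUE
      break
    }
    f_prev <- f
  }
  list(W = W, H = H, trace = trace[seq_len(it)], iterations = it, converged = converged)
}

#' Marker-constrained semi-supervised NMF deconvolution
#'
#' Factorizes the marker-restricted bulk matrix `V ~ W H` under Frobenius loss
#' with multiplicative updates, where the basis `W` is constrained so that a
#' marker gene of cell type *k* loads only on column *k* (off-type entries are
#' reset to zero after every update). `W` is initialized from the reference
#' panel's per-type mean marker expression and `H` uniformly; iteration stops
#' when the relative objective change falls below `tol` or at `max_iter`.
#' Columns of `H` are renormalized to the simplex only at output.
#'
#' @param bulk Gene-by-sample matrix (or single named column) of non-negative
#'   linear-space expression.
#' @param panel A [reference_panel()] (or coercible) supplying the labeled
#'   purified expression that seeds the basis.
#' @param markers Marker tibble (`gene`, `cell_type`).
#' @param opts List of options: `max_iter` (default 2000), `tol` (default
#'   1e-6), `n_restarts` (default 0 extra seeded multiplicative-noise restarts
#'   of the basis; best objective kept), `seed` (used only when
#'   `n_restarts > 0`).
#'
#' @return A `deconvolution_result` with `proportions`, the fitted `signature`
#'   (`W`), `objective_trace`, `iterations`, and `converged`.
#' @export
ssnmf_deconvolve <- function(bulk, panel, markers, opts = list()) {
  o <- modifyList(list(max_iter = 2000, tol = 1e-6, n_restarts = 0, seed = 1), opts)
  assert_count(o$max_iter, "max_iter")
  assert_scalar(o$tol, "tol", lower = 0, strict_lower = TRUE)
  panel <- as_reference_panel(panel)
  al <- align_marker_input(bulk, markers, panel)
  W0 <- ssnmf_initial_basis(panel, al$markers, al$types)
  mask <- W0 == 0
  H0 <- matrix(colSums(al$V) / mean(colSums(W0)) / length(al$types),
               nrow = length(al$types), ncol = ncol(al$V),
               dimnames = list(al$types, colnames(al$V)))
  H0[H0 <= 0] <- 1e-6
  fit <- ssnmf_core(al$V, W0, H0, mask, o$max_iter, o$tol)
  if (o$n_restarts > 0) {
    jitters <- withr::with_seed(child_seed(o$seed, "restart"), {
      lapply(seq_len(o$n_restarts), function(i) {
        matrix(lognormal_noise(length(W0), 0.2), nrow = nrow(W0))
      })
    })
    for (J in jitters) {
      alt <- ssnmf_core(al$V * 1, W0 * J, H0, mask, o$max_iter, o$tol)
      if (utils::tail(alt$trace, 1) < utils::tail(fit$trace, 1)) fit <- alt
    }
  }
  P <- simplex_rows(t(fit$H))
  new_deconvolution_result(P, "ssnmf", al$types, al$markers,
                           signature = fit$W, objective_trace = fit$trace,
                           iterations = fit$iterations, converged = fit$converged)
}

# ---- DSA ------------------------------------------------------------------

#' Digital-sorting deconvolution from marker means
#'
#' Computes, per sample, the mean expression of each cell type's markers and
#' solves the digital-sorting linear model: the marker-mean signal of type *k*
#' is the product of an unknown type-specific abundance scale and the sample's
#' proportion. The per-type scales are recovered by non-negative least squares
#' against the sum-to-one constraint across samples, and proportions are
#' renormalized to the simplex. Needs no labeled reference expression beyond
#' the marker identities.
#'
#' @param bulk Gene-by-sample matrix of non-negative linear-space expression.
#' @param markers Marker tibble (`gene`, `cell_type`).
#'
#' @return A `deconvolution_result` (no fitted signature).
#' @export
dsa_deconvolve <- function(bulk, markers) {
  al <- align_marker_input(bulk, markers)
  types <- al$types
  M <- marker_type_means(al$V, al$markers, types)  # samples x types
  if (nrow(M) >= length(types) && qr(M)$rank < length(types)) {
    abort(paste0("marker-mean matrix is rank-deficient across samples; ",
                 "add samples or markers to separate the cell types"),
          class = "cortexmix_input_error")
  }
  x <- pracma::lsqnonneg(M, rep(1, nrow(M)))$x
  P <- sweep(M, 2, x, "*")
  zero_rows <- rowSums(P) <= 0
  if (any(zero_rows)) {
    # degenerate scale solution: fall back to raw marker-mean shares
    P[zero_rows, ] <- M[zero_rows, , drop = FALSE]
  }
  P <- simplex_rows(P)
  rownames(P) <- colnames(al$V)
  new_deconvolution_result(P, "dsa", types, al$markers,
                           objective_trace = sqrt(sum((M %*% x - 1)^2)),
                           iterations = 1L, converged = TRUE)
}

# ---- mean profile ---------------------------------------------------------

#' Scaled marker-mean profile estimation
#'
#' Scales each marker gene to unit maximum across samples (so genes of
#' different magnitudes contribute comparably), then estimates each cell
#' type's signal in a sample as the mean of that type's scaled markers, and
#' renormalizes rows to the simplex. The result is a *relative* composition
#' index, not an absolute mRNA proportion, and is flagged as such.
#'
#' @param bulk Gene-by-sample matrix of non-negative linear-space expression.
#' @param markers Marker tibble (`gene`, `cell_type`).
#'
#' @return A `deconvolution_result` with `relative = TRUE`.
#' @export
mean_profile_deconvolve <- function(bulk, markers) {
  al <- align_marker_input(bulk, markers)
  V <- al$V
  mx <- apply(V, 1, max)
  dead <- mx <= 0
  if (any(dead)) {
    warn(paste0("dropping marker(s) with zero expression in all samples: ",
                paste(rownames(V)[dead], collapse = ", ")))
    V <- V[!dead, , drop = FALSE]
    al$markers <- al$markers[!dead, , drop = FALSE]
    lost <- setdiff(al$types, unique(al$markers$cell_type))
    if (length(lost) > 0) {
      abort(paste0("cell type(s) lost all markers: ", paste(lost, collapse = ", ")),
            class = "cortexmix_marker_error")
    }
    mx <- mx[!dead]
  }
  scaled <- sweep(V, 1, mx, "/")
  P <- marker_type_means(scaled, al$markers, al$types)  # samples x types
  zero_rows <- rowSums(P) <= 0
  if (any(zero_rows)) P[zero_rows, ] <- 1 / ncol(P)
  P <- simplex_rows(P)
  new_deconvolution_result(P, "mean_profile", al$types, al$markers,
                           iterations = 1L, converged = TRUE, relative = TRUE)
}

# ---- dispatch facade ------------------------------------------------------

#' Estimate cell-type proportions from bulk expression
#'
#' Single dispatch facade over the three engines: marker-constrained
#' semi-supervised NMF ([ssnmf_deconvolve()]), digital sorting
#' ([dsa_deconvolve()]), and scaled marker-mean profiling
#' ([mean_profile_deconvolve()]). All engines return the same result contract.
#'
#' @param bulk Gene-by-sample matrix of non-negative linear-space expression.
#' @param panel Reference panel (required by `ssnmf`, ignored otherwise).
#' @param markers Marker tibble (`gene`, `cell_type`).
#' @param engine One of `"ssnmf"`, `"dsa"`, `"mean_profile"`.
#' @param opts Engine options (see [ssnmf_deconvolve()]).
#'
#' @return A `deconvolution_result`.
#' @export
deconvolve <- function(bulk, panel = NULL, markers, engine = "ssnmf", opts = list()) {
  if (length(engine) != 1 || !engine %in% VALID_ENGINES) {
    abort(paste0("unknown engine '", paste(engine, collapse = ","),
                 "'; valid engines: ", paste(VALID_ENGINES, collapse = ", ")),
          class = "cortexmix_config_error")
  }
  switch(engine,
    ssnmf = {
      if (is.null(panel)) {
        abort("engine 'ssnmf' requires a reference `panel`", class = "cortexmix_input_error")
      }
      ssnmf_deconvolve(bulk, panel, markers, opts)
    },
    dsa = dsa_deconvolve(bulk, markers),
    mean_profile = mean_profile_deconvolve(bulk, markers)
  )
}

#' Brute-force simplex-grid deconvolution oracle
#'
#' Exhaustively scores every point of a regular grid on the probability
#' simplex against the least-squares mixing model `v ~ S p` and returns the
#' best grid point per sample. Exponentially slow in the number of cell types
#' — intended purely as an independent reference for validating the engines on
#' small problems.
#'
#' @param bulk Gene-by-sample matrix.
#' @param signature Marker-by-type signature matrix (e.g. per-type means).
#' @param step Grid step on the simplex (default 0.01).
#'
#' @return A samples-by-types proportion matrix of grid optima.
#' @export
deconvolve_grid_oracle <- function(bulk, signature, step = 0.01) {
  bulk <- as_bulk_matrix(bulk)
  genes <- intersect(rownames(bulk), rownames(signature))
  V <- bulk[genes, , drop = FALSE]
  S <- signature[genes, , drop = FALSE]
  K <- ncol(S)
  n_steps <- round(1 / step)
  grid <- simplex_grid(K, n_steps)  # (points x K) integer compositions / n_steps
  best_val <- rep(Inf, ncol(V))
  best_idx <- rep(1L, ncol(V))
  ssq_v <- colSums(V^2)
  chunk <- 20000L
  for (start in seq(1, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(grid))
    GP <- S %*% t(grid[idx, , drop = FALSE])      # genes x points
    ssq_gp <- colSums(GP^2)
    cross <- crossprod(V, GP)                     # samples x points
    obj <- outer(ssq_v, ssq_gp, "+") - 2 * cross
    mins <- apply(obj, 1, which.min)
    vals <- obj[cbind(seq_along(mins), mins)]
    improve <- vals < best_val
    best_val[improve] <- vals[improve]
    best_idx[improve] <- idx[mins[improve]]
  }
  P <- grid[best_idx, , drop = FALSE]
  dimnames(P) <- list(colnames(V), colnames(S))
  P
}

# All compositions of n_steps into K parts, scaled to the simplex.
simplex_grid <- function(K, n_steps) {
  if (K == 1) return(matrix(1, 1, 1))
  comps <- function(total, parts) {
    if (parts == 1) return(matrix(total, ncol = 1))
    do.call(rbind, lapply(0:total, function(i) cbind(i, comps(total - i, parts - 1))))
  }
  g <- comps(n_steps, K) / n_steps
  colnames(g) <- NULL
  g
}

#' Simplex-constrained least-squares oracle
#'
#' Solves `min ||v - S p||` subject to `p >= 0`, `sum(p) = 1` per sample via
#' non-negative least squares on a system augmented with a heavily weighted
#' sum-to-one row. Used as an independent reference implementation in tests.
#'
#' @param bulk Gene-by-sample matrix.
#' @param signature Marker-by-type signature matrix.
#' @param weight Weight on the sum-to-one row (default 1e6 times the largest
#'   signature entry).
#'
#' @return A samples-by-types proportion matrix.
#' @export
deconvolve_ls_oracle <- function(bulk, signature, weight = NULL) {
  bulk <- as_bulk_matrix(bulk)
  genes <- intersect(rownames(bulk), rownames(signature))
  V <- bulk[genes, , drop = FALSE]
  S <- signature[genes, , drop = FALSE]
  if (is.null(weight)) weight <- 1e6 * max(S)
  A <- rbind(S, rep(weight, ncol(S)))
  P <- t(vapply(seq_len(ncol(V)), function(j) {
    pracma::lsqnonneg(A, c(V[, j], weight))$x
  }, numeric(ncol(S))))
  P <- simplex_rows(pmax(P, 0))
  dimnames(P) <- list(colnames(V), colnames(S))
  P
}

# ---- methods --------------------------------------------------------------

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("Deconvolution (", x$engine, "): ", nrow(x$proportions), " sample(s) x ",
      length(x$cell_types), " cell types; ", nrow(x$markers), " markers; ",
      x$iterations, " iteration(s)",
      if (x$relative) "; relative index (not absolute proportions)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Tidy a deconvolution result into long format
#'
#' @param x A `deconvolution_result`.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `cell_type`, `proportion`.
#' @export
tidy.deconvolution_result <- function(x, ...) {
  tidyr::pivot_longer(x$proportions, -"sample_id",
                      names_to = "cell_type", values_to = "proportion")
}

#' One-row fit summary of a deconvolution result
#'
#' @param x A `deconvolution_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.deconvolution_result <- function(x, ...) {
  tibble::tibble(
    engine = x$engine,
    n_samples = nrow(x$proportions),
    n_cell_types = length(x$cell_types),
    n_markers = nrow(x$markers),
    iterations = x$iterations,
    converged = x$converged,
    final_objective = if (length(x$objective_trace)) utils::tail(x$objective_trace, 1) else NA_real_,
    relative = x$relative
  )
}
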
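# Shared internal helpers: validation, seed handling, proportion containers.

# Canonical (deterministic) cell-type column order used by every writer and
# every proportion tibble: plain alphabetical sort.
canonical_types <- function(types) sort(unique(as.character(types)))

# One global seed fans out to per-stage child seeds through a fixed affine
# rule (Lehmer multiplier, distinct additive offset per stage), so each stage
# is independently reproducible from the same top-level seed.
child_seed <- function(seed, stream) {
  offsets <- c(
    profiles = 11L, pools = 23L, cohort = 37L, design = 53L, mixing = 67L,
    validation = 83L, loocv = 97L, dropout = 113L, power = 131L,
    pipeline = 149L, restart = 167L
  )
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown seed stream '", stream, "'"), class = "cortexmix_internal_error")
  }
  as.integer((as.double(seed) %% 44488 * 48271 + offsets[[stream]]) %% 2147483647)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(
      paste0("`", name, "` must be a single integer >= ", min, " (got ", deparse(x), ")"),
      class = "cortexmix_config_error"
    )
  }
  invisible(as.integer(x))
}

assert_scalar <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  bad <- !is.numeric(x) || length(x) != 1 || is.na(x) || x > upper ||
    (if (strict_lower) x <= lower else x < lower)
  if (bad) {
    abort(
      paste0("`", name, "` must be a number in ", if (strict_lower) "(" else "[",
             lower, ", ", upper, "] (got ", deparse(x), ")"),
      class = "cortexmix_config_error"
    )
  }
  invisible(x)
}

# Validate a gene-by-sample expression matrix: numeric, finite, non-negative,
# unique row and column identifiers.
assert_expression_matrix <- function(x, name = "expression") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(paste0("`", name, "` must be a numeric matrix (genes x samples)"),
          class = "cortexmix_input_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(paste0("`", name, "` must carry gene rownames and sample colnames"),
          class = "cortexmix_input_error")
  }
  if (anyDuplicated(rownames(x))) {
    abort(paste0("duplicate gene identifiers in `", name, "`"), class = "cortexmix_input_error")
  }
  if (anyDuplicated(colnames(x))) {
    abort(paste0("duplicate sample identifiers in `", name, "`"), class = "cortexmix_input_error")
  }
  if (any(!is.finite(x))) {
    abort(paste0("`", name, "` contains non-finite values"), class = "cortexmix_input_error")
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    abort(
      paste0("negative expression in `", name, "` at gene '", rownames(x)[bad[1]],
             "', sample '", colnames(x)[bad[2]], "'"),
      class = "cortexmix_input_error"
    )
  }
  invisible(x)
}

# Coerce bulk input (matrix or single named column) to a matrix.
as_bulk_matrix <- function(bulk) {
  if (is.numeric(bulk) && !is.matrix(bulk)) {
    if (is.null(names(bulk))) {
      abort("a bulk vector must carry gene names", class = "cortexmix_input_error")
    }
    bulk <- matrix(bulk, ncol = 1, dimnames = list(names(bulk), "bulk_1"))
  }
  assert_expression_matrix(bulk, "bulk")
  bulk
}

# ---- proportion containers ----------------------------------------------

# A proportion table is a tibble with a `sample_id` column plus one numeric
# column per cell type (canonical order). These two helpers convert between
# that tibble and a samples-by-types matrix.
prop_as_matrix <- function(x) {
  if (inherits(x, "deconvolution_result")) x <- x$proportions
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("proportion matrix must have sample rownames and cell-type colnames",
            class = "cortexmix_input_error")
    }
    return(x[, canonical_types(colnames(x)), drop = FALSE])
  }
  if (!is.data.frame(x) || !"sample_id" %in% names(x)) {
    abort("proportions must be a matrix or a tibble with a `sample_id` column",
          class = "cortexmix_input_error")
  }
  types <- canonical_types(setdiff(names(x), "sample_id"))
  m <- as.matrix(x[, types, drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

prop_as_tibble <- function(m) {
  m <- m[, canonical_types(colnames(m)), drop = FALSE]
  tibble::as_tibble(m, rownames = "sample_id")
}

# Renormalize rows of a non-negative matrix onto the probability simplex.
simplex_rows <- function(m) {
  s <- rowSums(m)
  if (any(s <= 0)) {
    abort(paste0("cannot renormalize all-zero proportion row(s): ",
                 paste(rownames(m)[s <= 0], collapse = ", ")),
          class = "cortexmix_input_error")
  }
  sweep(m, 1, s, "/")
}

# Multiplicative log-normal noise, exp(N(0, sigma^2)) per entry.
lognormal_noise <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else exp(rnorm(n, 0, sigma))
}
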
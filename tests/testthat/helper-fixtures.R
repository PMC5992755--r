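# Fixtures built in code. The "exclusive" fixtures give each marker zero
# expression outside its own cell type — the idealization the
# marker-constrained mixing model assumes — and are used for exact-recovery
# checks. Noisy, baseline-background fixtures come from the package's own
# generator.

fixture_types <- c("astrocyte", "microglia", "neuron", "oligodendrocyte")

# Marker-by-type signature with zero off-type expression.
exclusive_signature <- function(markers_per_type = 10, seed = 1,
                                types = fixture_types) {
  withr::with_seed(seed, {
    K <- length(types)
    S <- matrix(0, nrow = K * markers_per_type, ncol = K,
                dimnames = list(sprintf("g%03d", seq_len(K * markers_per_type)), types))
    for (k in seq_len(K)) {
      S[(k - 1) * markers_per_type + seq_len(markers_per_type), k] <-
        runif(markers_per_type, 50, 300)
    }
    S
  })
}

exclusive_markers <- function(S) {
  tibble::tibble(gene = rownames(S),
                 cell_type = colnames(S)[apply(S > 0, 1, which)])
}

# Reference panel whose purified samples are exact copies of the signature
# columns (n_reps per type).
exclusive_panel <- function(S, n_reps = 2) {
  types <- colnames(S)
  expr <- S[, rep(seq_along(types), each = n_reps), drop = FALSE]
  ids <- paste0(rep(types, each = n_reps), "_", rep(seq_len(n_reps), length(types)))
  colnames(expr) <- ids
  reference_panel(expr, setNames(rep(types, each = n_reps), ids))
}

# Noiseless mixtures of the signature columns at given proportions (rows of P).
mix_bulk <- function(S, P, noise_sigma = 0, seed = 1) {
  B <- S %*% t(P)
  colnames(B) <- paste0("mix_", seq_len(nrow(P)))
  if (noise_sigma > 0) {
    B <- withr::with_seed(seed, B * exp(matrix(rnorm(length(B), 0, noise_sigma),
                                               nrow = nrow(B))))
  }
  B
}

random_simplex <- function(n, K, seed = 1) {
  withr::with_seed(seed, {
    P <- matrix(runif(n * K), nrow = n)
    P / rowSums(P)
  })
}
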
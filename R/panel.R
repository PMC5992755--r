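# Reference-panel assembly and curation: species harmonization, marker
# extraction, PCA quality control, and iterative leave-one-out curation.

#' Construct a labeled reference panel
#'
#' A reference panel is a marker-restricted expression matrix of purified
#' samples together with a cell-type label per sample (and optionally the
#' species and free-text provenance of each sample).
#'
#' @param expression Gene-by-sample numeric matrix (linear-space, TPM-like).
#' @param labels Named character vector mapping sample id to cell type, or an
#'   unnamed vector in column order.
#' @param species Optional named character vector (`"human"`/`"mouse"`).
#' @param provenance Optional named character vector of free-text provenance.
#'
#' @return A `reference_panel` object.
#' @export
reference_panel <- function(expression, labels, species = NULL, provenance = NULL) {
  assert_expression_matrix(expression, "expression")
  if (is.null(names(labels))) {
    if (length(labels) != ncol(expression)) {
      abort("unnamed `labels` must have one entry per sample column",
            class = "cortexmix_input_error")
    }
    labels <- setNames(as.character(labels), colnames(expression))
  }
  missing <- setdiff(colnames(expression), names(labels))
  if (length(missing) > 0) {
    abort(paste0("samples without a cell-type label: ", paste(missing, collapse = ", ")),
          class = "cortexmix_input_error")
  }
  labels <- labels[colnames(expression)]
  structure(
    list(expression = expression, labels = labels,
         species = species, provenance = provenance),
    class = "reference_panel"
  )
}

#' Coerce to a reference panel
#'
#' @param x A `reference_panel`, `reference_profiles`, or list with
#'   `expression` and `labels`.
#' @param ... Unused.
#' @return A `reference_panel`.
#' @export
as_reference_panel <- function(x, ...) {
  if (inherits(x, "reference_panel")) return(x)
  if (is.list(x) && !is.null(x$expression) && !is.null(x$labels)) {
    return(reference_panel(x$expression, x$labels, x$species, x$provenance))
  }
  abort("cannot coerce to a reference panel", class = "cortexmix_input_error")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel:", nrow(x$expression), "genes x", ncol(x$expression),
      "samples (", paste(table(x$labels), names(table(x$labels)), collapse = ", "), ")\n")
  invisible(x)
}

panel_cell_types <- function(panel) canonical_types(panel$labels)

subset_panel <- function(panel, samples = NULL, genes = NULL) {
  expr <- panel$expression
  if (!is.null(genes)) expr <- expr[genes, , drop = FALSE]
  if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
  reference_panel(expr, panel$labels[colnames(expr)],
                  panel$species[colnames(expr)], panel$provenance[colnames(expr)])
}

#' Harmonize gene symbols across species
#'
#' Maps gene symbols to a canonical uppercase namespace so mouse-style symbols
#' (`Gfap`) and human symbols (`GFAP`) become comparable. Rows that collapse
#' onto the same canonical symbol are summed (read-count semantics), and the
#' number of remapped symbols is reported. Mapping is by case-insensitive
#' symbol identity only; no orthology tables are consulted.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param species `"human"` or `"mouse"` (recorded only; the mapping rule is
#'   identical).
#' @param markers Optional marker tibble/vector; if supplied, an empty
#'   intersection between the harmonized gene set and the marker namespace is
#'   an error.
#'
#' @return The harmonized expression matrix.
#' @export
harmonize_species <- function(matrix, species = c("human", "mouse"), markers = NULL) {
  species <- match.arg(species)
  assert_expression_matrix(matrix, "matrix")
  canonical <- toupper(rownames(matrix))
  n_remapped <- sum(canonical != rownames(matrix))
  out <- rowsum(matrix, group = canonical, reorder = FALSE)
  out <- out[order(rownames(out)), , drop = FALSE]
  if (n_remapped > 0) {
    inform(paste0("harmonize_species: remapped ", n_remapped, " symbol(s) to the ",
                  "canonical uppercase namespace (", species, " input)"))
  }
  if (!is.null(markers)) {
    marker_genes <- if (is.data.frame(markers)) markers$gene else as.character(markers)
    if (length(intersect(rownames(out), toupper(marker_genes))) == 0) {
      abort("no overlap between harmonized genes and the marker namespace",
            class = "cortexmix_input_error")
    }
  }
  # preserve original row order for already-canonical input (idempotence)
  if (n_remapped == 0 && !anyDuplicated(rownames(matrix))) {
    out <- out[rownames(matrix), , drop = FALSE]
  }
  out
}

#' Filter candidate markers by type specificity in a reference panel
#'
#' Retains the candidate markers whose mean expression in their own cell type
#' is at least `min_specificity` times the largest mean in any other type.
#' Candidates absent from the panel's gene set are dropped; type assignments
#' are never altered and no new markers are invented.
#'
#' @param panel A [reference_panel()] (or coercible object).
#' @param candidates Marker tibble with columns `gene`, `cell_type`.
#' @param min_specificity Required own-type/other-type mean-expression ratio
#'   (default 2).
#'
#' @return The retained subset of `candidates` (same columns, same order).
#' @export
extract_markers <- function(panel, candidates, min_specificity = 2) {
  panel <- as_reference_panel(panel)
  assert_scalar(min_specificity, "min_specificity", lower = 0, strict_lower = TRUE)
  if (!is.data.frame(candidates) || !all(c("gene", "cell_type") %in% names(candidates)) ||
      nrow(candidates) == 0) {
    abort("`candidates` must be a non-empty tibble with `gene` and `cell_type`",
          class = "cortexmix_input_error")
  }
  if (anyDuplicated(candidates$gene)) {
    abort("a candidate gene is assigned to more than one cell type",
          class = "cortexmix_input_error")
  }
  types <- panel_cell_types(panel)
  present <- candidates[candidates$gene %in% rownames(panel$expression), , drop = FALSE]
  type_means <- vapply(types, function(ct) {
    rowMeans(panel$expression[present$gene, panel$labels == ct, drop = FALSE])
  }, numeric(nrow(present)))
  if (nrow(present) == 1) type_means <- matrix(type_means, nrow = 1, dimnames = list(present$gene, types))
  keep <- vapply(seq_len(nrow(present)), function(i) {
    own <- type_means[i, present$cell_type[i]]
    other <- max(type_means[i, setdiff(types, present$cell_type[i])])
    own >= min_specificity * other
  }, logical(1))
  retained <- present[keep, , drop = FALSE]
  lost <- setdiff(unique(candidates$cell_type), unique(retained$cell_type))
  if (length(lost) > 0) {
    abort(paste0("cell type(s) lost all markers at min_specificity = ",
                 min_specificity, ": ", paste(lost, collapse = ", ")),
          class = "cortexmix_marker_error")
  }
  tibble::as_tibble(retained)
}

#' PCA quality control of a reference panel
#'
#' Runs principal component analysis on the marker expression of the panel
#' (columns scaled to a fixed total, then `log(x + 1)`, gene-centered) and
#' scores how well the top-2 component space separates the cell-type labels
#' with the mean silhouette width. Column normalization makes the score
#' invariant to uniform rescaling of all samples.
#'
#' @param panel A [reference_panel()] (or coercible object).
#' @param n_components Number of components to return (default 2).
#'
#' @return A list with `scores` (tibble: `sample_id`, `cell_type`, `PC1`, ...),
#'   `sdev`, `silhouette` (mean width), and `silhouette_by_sample`.
#' @export
qc_pca <- function(panel, n_components = 2) {
  panel <- as_reference_panel(panel)
  types <- panel_cell_types(panel)
  counts <- table(panel$labels)
  if (length(types) < 2) {
    abort("silhouette is undefined with a single cell type", class = "cortexmix_input_error")
  }
  if (any(counts < 2)) {
    abort(paste0("qc_pca needs >= 2 samples per cell type; short: ",
                 paste(names(counts)[counts < 2], collapse = ", ")),
          class = "cortexmix_input_error")
  }
  if (ncol(panel$expression) <= n_components) {
    abort("fewer samples than requested components", class = "cortexmix_input_error")
  }
  # columns scaled to a fixed total (CPM-style), so the score is exactly
  # invariant to uniform rescaling of the input
  totals <- colSums(panel$expression)
  norm <- sweep(panel$expression, 2, totals, "/") * 1e4
  x <- t(log1p(norm))
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pca$x))
  scores <- tibble::tibble(
    sample_id = rownames(pca$x),
    cell_type = unname(panel$labels[rownames(pca$x)])
  )
  for (i in seq_len(k)) scores[[paste0("PC", i)]] <- pca$x[, i]
  cl <- as.integer(factor(panel$labels, levels = types))
  sil <- cluster::silhouette(cl, dist(pca$x[, 1:2, drop = FALSE]))
  list(
    scores = scores,
    sdev = pca$sdev,
    silhouette = mean(sil[, "sil_width"]),
    silhouette_by_sample = setNames(sil[, "sil_width"], rownames(pca$x))
  )
}

# One leave-one-out pass: each sample held out (lexicographic order), the
# engine fit on the rest, and the held-out sample deconvolved as a one-column
# bulk. Returns the full predicted proportion vector per sample.
loocv_pass <- function(panel, markers, engine = "ssnmf", opts = list()) {
  samples <- sort(colnames(panel$expression))
  res <- lapply(samples, function(s) {
    train <- subset_panel(panel, samples = setdiff(colnames(panel$expression), s))
    bulk <- panel$expression[, s, drop = FALSE]
    fit <- deconvolve(bulk, panel = train, markers = markers, engine = engine, opts = opts)
    p <- fit$proportions
    p$sample_id <- s
    p
  })
  preds <- dplyr::bind_rows(res)
  preds$cell_type <- unname(panel$labels[preds$sample_id])
  types <- panel_cell_types(panel)
  preds$self_proportion <- vapply(seq_len(nrow(preds)), function(i) {
    preds[[preds$cell_type[i]]][i]
  }, numeric(1))
  preds[, c("sample_id", "cell_type", types, "self_proportion")]
}

#' Iterative leave-one-out curation of a reference panel
#'
#' Per round, every sample is held out in turn, the deconvolution engine is
#' fit on the remaining samples, and the held-out sample is deconvolved as a
#' one-column bulk. Samples whose predicted proportion for their own labeled
#' type is not strictly greater than `threshold` are removed; removals within
#' a round are simultaneous. Rounds repeat until no sample is removed or
#' `max_rounds` is reached (a single pass is `max_rounds = 1`).
#'
#' @param panel A [reference_panel()] (or coercible object); needs >= 2
#'   samples per cell type.
#' @param markers Marker tibble (`gene`, `cell_type`).
#' @param engine Deconvolution engine (see [deconvolve()]); default `"ssnmf"`.
#' @param threshold Retention threshold on the predicted self-type proportion;
#'   strictly-greater comparison (default 0.80).
#' @param max_rounds Maximum removal rounds (default 10).
#' @param opts Engine options passed to [deconvolve()].
#'
#' @return A `curation_result` list: `panel` (curated), `report` (tibble with
#'   `round`, `sample_id`, `cell_type`, `self_proportion`, `removed`),
#'   `rounds_run`, `retained`, `threshold`. If a cell type drops below 2
#'   samples mid-curation, an error of class `cortexmix_curation_error` is
#'   signalled carrying the partial report in its `report` field.
#' @export
loocv_curate <- function(panel, markers, engine = "ssnmf", threshold = 0.80,
                         max_rounds = 10, opts = list()) {
  panel <- as_reference_panel(panel)
  assert_scalar(threshold, "threshold", lower = 0, upper = 1)
  assert_count(max_rounds, "max_rounds")
  counts <- table(panel$labels)
  if (any(counts < 2)) {
    abort(paste0("loocv_curate needs >= 2 samples per cell type; short: ",
                 paste(names(counts)[counts < 2], collapse = ", ")),
          class = "cortexmix_input_error")
  }
  current <- panel
  report <- tibble::tibble()
  rounds_run <- 0L
  repeat {
    rounds_run <- rounds_run + 1L
    pass <- loocv_pass(current, markers, engine = engine, opts = opts)
    pass$removed <- pass$self_proportion <= threshold  # strict > keeps
    pass$round <- rounds_run
    report <- dplyr::bind_rows(report, pass)
    drop <- pass$sample_id[pass$removed]
    if (length(drop) == 0 || rounds_run >= max_rounds) break
    keep <- setdiff(colnames(current$expression), drop)
    remaining <- table(factor(current$labels[keep], levels = panel_cell_types(panel)))
    if (any(remaining < 2)) {
      abort(
        paste0("curation stopped: cell type(s) dropped below 2 samples: ",
               paste(names(remaining)[remaining < 2], collapse = ", ")),
        class = "cortexmix_curation_error",
        report = report, rounds_run = rounds_run
      )
    }
    current <- subset_panel(current, samples = keep)
    if (length(drop) == 0) break
  }
  final_round <- report[report$round == rounds_run, ]
  retained <- final_round$sample_id[!final_round$removed]
  if (length(retained) == 0) {
    abort("curation removed every sample; lower the threshold or improve the panel",
          class = "cortexmix_curation_error", report = report, rounds_run = rounds_run)
  }
  structure(
    list(panel = subset_panel(current, samples = intersect(colnames(current$expression), retained)),
         report = report[, c("round", "sample_id", "cell_type", "self_proportion", "removed")],
         rounds_run = rounds_run,
         retained = sort(retained),
         threshold = threshold),
    class = "curation_result"
  )
}

#' @export
print.curation_result <- function(x, ...) {
  cat("LOOCV curation:", length(x$retained), "samples retained after",
      x$rounds_run, "round(s) at threshold >", x$threshold, "\n")
  invisible(x)
}

#' @export
tidy.curation_result <- function(x, ...) x$report

#' @export
glance.curation_result <- function(x, ...) {
  tibble::tibble(
    rounds_run = x$rounds_run,
    n_retained = length(x$retained),
    n_removed = sum(x$report$removed[x$report$round == x$rounds_run]),
    threshold = x$threshold,
    mean_self_proportion = mean(x$report$self_proportion[x$report$round == x$rounds_run])
  )
}
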
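# File I/O and the end-to-end pipeline. TSV is the canonical matrix format
# (genes in rows, tab-delimited, '.' decimal); CSV is accepted on read.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample ids and gene identifiers in the first
#' column (genes in rows). Values must be numeric and non-negative; duplicate
#' gene rows are collapsed by sum (read-count semantics) with a warning,
#' duplicate sample ids are an error.
#'
#' @param path File path (`.tsv`/`.txt` tab-delimited, `.csv` comma).
#' @param orientation `"genes_in_rows"` (default), `"samples_in_rows"`, or
#'   `"auto"` (samples-in-rows assumed when the first header field is
#'   `sample_id`).
#'
#' @return A gene-by-sample numeric matrix.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows", "auto")) {
  orientation <- match.arg(orientation)
  df <- readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                          progress = FALSE)
  id_col <- names(df)[1]
  if (orientation == "auto") {
    orientation <- if (identical(id_col, "sample_id")) "samples_in_rows" else "genes_in_rows"
  }
  for (j in seq(2, ncol(df))) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      abort(paste0("non-numeric value in '", path, "' at column '", names(df)[j],
                   "', row ", bad %||% 1), class = "cortexmix_parse_error")
    }
    if (any(df[[j]] < 0, na.rm = TRUE)) {
      bad <- which(df[[j]] < 0)[1]
      abort(paste0("negative value in '", path, "' at column '", names(df)[j],
                   "', id '", df[[1]][bad], "'"), class = "cortexmix_parse_error")
    }
  }
  m <- as.matrix(df[, -1])
  rownames(m) <- as.character(df[[1]])
  if (orientation == "samples_in_rows") m <- t(m)
  if (anyDuplicated(colnames(m))) {
    abort(paste0("duplicate sample ids in '", path, "'"), class = "cortexmix_parse_error")
  }
  if (anyDuplicated(rownames(m))) {
    n_dup <- sum(duplicated(rownames(m)))
    warn(paste0("collapsed ", n_dup, " duplicate gene row(s) by sum in '", path, "'"))
    m <- rowsum(m, group = rownames(m), reorder = FALSE)
  }
  assert_expression_matrix(m, path)
  m
}

#' Write an expression matrix as TSV
#'
#' @param matrix Gene-by-sample numeric matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(matrix, path) {
  assert_expression_matrix(matrix, "matrix")
  df <- tibble::as_tibble(matrix, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a marker panel
#'
#' Accepts a two-column TSV/CSV (`gene`, `cell_type`; alias `gene_symbol`
#' accepted) or a YAML map of cell type to gene list. A gene assigned to more
#' than one cell type is an error quoting both assignments.
#'
#' @param path File path.
#' @return A tibble with `gene` and `cell_type`.
#' @export
read_markers <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    mk <- tibble::tibble(
      gene = unlist(y, use.names = FALSE),
      cell_type = rep(names(y), lengths(y))
    )
  } else {
    df <- readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                            progress = FALSE, comment = "#")
    names(df)[names(df) == "gene_symbol"] <- "gene"
    if (!all(c("gene", "cell_type") %in% names(df))) {
      abort(paste0("marker file '", path, "' must have columns gene (or gene_symbol) and cell_type"),
            class = "cortexmix_parse_error")
    }
    mk <- tibble::tibble(gene = as.character(df$gene),
                         cell_type = as.character(df$cell_type))
  }
  dup <- unique(mk$gene[duplicated(mk$gene)])
  if (length(dup) > 0) {
    g <- dup[1]
    assigns <- mk[mk$gene == g, ]
    abort(paste0("marker '", g, "' assigned to multiple cell types: ",
                 paste0("'", g, " -> ", assigns$cell_type, "'", collapse = " and ")),
          class = "cortexmix_parse_error")
  }
  mk
}

#' Write a marker panel as TSV
#'
#' @param markers Tibble with `gene`, `cell_type`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_markers <- function(markers, path) {
  readr::write_tsv(markers[, c("gene", "cell_type")], path)
  invisible(path)
}

#' Packaged default brain marker panel
#'
#' A compact literature-style list of widely used marker genes for neurons,
#' astrocytes, oligodendrocytes, and microglia, shipped as a convenient
#' default. It is a package-authored stand-in for a study-specific curated
#' marker list, not a reproduction of any published supplementary table.
#'
#' @return A tibble with `gene` and `cell_type`.
#' @export
default_markers <- function() {
  read_markers(system.file("extdata", "markers_brain_default_synthetic.tsv",
                           package = "cortexmix", mustWork = TRUE))
}

#' Write / read proportion tables
#'
#' Proportions are written as TSV with a `sample_id` column followed by one
#' column per cell type in deterministic (alphabetical) order.
#'
#' @param proportions Proportion tibble, matrix, or `deconvolution_result`.
#' @param path Output path.
#' @return `write_proportions`: the path, invisibly. `read_proportions`: a
#'   proportion tibble.
#' @export
write_proportions <- function(proportions, path) {
  readr::write_tsv(prop_as_tibble(prop_as_matrix(proportions)), path)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  df <- readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                          progress = FALSE)
  prop_as_tibble(prop_as_matrix(df))
}

#' Write read pools as a two-column read table or minimal FASTQ stub
#'
#' Expands the compact per-gene counts of [simulate_read_pools()] to one line
#' per read: either a TSV of (`read_id`, `gene`) or a minimal FASTQ whose read
#' names encode sample, gene, and read index.
#'
#' @param pools Tibble from [simulate_read_pools()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"fastq"`.
#' @return The path, invisibly.
#' @export
write_read_pools <- function(pools, path, format = c("tsv", "fastq")) {
  format <- match.arg(format)
  genes <- rep(pools$gene, pools$count)
  samples <- rep(pools$sample_id, pools$count)
  idx <- stats::ave(seq_along(genes), samples, FUN = seq_along)
  read_id <- paste0(samples, ":", genes, ":", idx)
  if (format == "tsv") {
    readr::write_tsv(tibble::tibble(read_id = read_id, gene = genes), path)
  } else {
    seqs <- strrep("ACGT", 10)
    writeLines(paste0("@", read_id, "\n", seqs, "\n+\n", strrep("I", 40)), path)
  }
  invisible(path)
}

# ---- pipeline -------------------------------------------------------------

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Path fields are checked at
#' run time; scalar fields are checked immediately, before any stage runs.
#'
#' @param panel Path to the reference-panel expression TSV.
#' @param panel_labels Path to a CSV/TSV with `sample_id`, `cell_type`.
#' @param markers Path to the marker list (TSV or YAML); `NULL` uses the
#'   packaged default panel.
#' @param bulk Path to the bulk expression TSV.
#' @param metadata Optional path to the sample-metadata CSV.
#' @param out_dir Output directory for the run.
#' @param engine Deconvolution engine (default `"ssnmf"`).
#' @param curation_threshold Self-proportion retention threshold, in (0, 1).
#' @param contrasts Optional list of association contrasts, each a list with
#'   `predictor` and optional `covariates`.
#' @param validate Optional list of chimeric-design parameters
#'   (`n_distributions`, `repeats`) to run the admixture validation.
#' @param seed Global integer seed.
#'
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(panel, panel_labels, markers = NULL, bulk,
                            metadata = NULL, out_dir,
                            engine = "ssnmf", curation_threshold = 0.80,
                            contrasts = NULL, validate = NULL, seed = 42) {
  assert_scalar(curation_threshold, "curation_threshold", lower = 0, upper = 1,
                strict_lower = TRUE)
  if (curation_threshold >= 1) {
    abort("`curation_threshold` must be strictly below 1", class = "cortexmix_config_error")
  }
  assert_count(seed, "seed", min = 0)
  if (!engine %in% VALID_ENGINES) {
    abort(paste0("unknown engine '", engine, "'; valid engines: ",
                 paste(VALID_ENGINES, collapse = ", ")),
          class = "cortexmix_config_error")
  }
  structure(
    list(panel = panel, panel_labels = panel_labels, markers = markers,
         bulk = bulk, metadata = metadata, out_dir = out_dir, engine = engine,
         curation_threshold = curation_threshold, contrasts = contrasts,
         validate = validate, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

read_labels_file <- function(path) {
  df <- readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                          progress = FALSE)
  setNames(as.character(df$cell_type), as.character(df$sample_id))
}

#' Run the end-to-end deconvolution pipeline
#'
#' Executes curation (LOOCV over the reference panel), deconvolution of the
#' bulk samples, optional chimeric validation, and optional association
#' contrasts, writing all stage outputs plus a manifest (package version,
#' seed, config hash, input and output checksums) and a run log into
#' `out_dir`. Re-running with identical configuration and inputs reproduces
#' byte-identical outputs. Any stage failure halts the run with the stage
#' name; outputs of completed stages are preserved.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly. Side effects: files under
#'   `out_dir` (`curation_report.csv`, `proportions.tsv`, `fit.json`,
#'   optionally `validation.json`, `associations.csv`, plus `manifest.json`
#'   and `run.log`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  inputs <- c(panel = config$panel, panel_labels = config$panel_labels,
              markers = config$markers, bulk = config$bulk,
              metadata = config$metadata)
  missing_files <- inputs[!vapply(inputs, file.exists, logical(1))]
  if (length(missing_files) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing_files, collapse = ", ")),
          class = "cortexmix_config_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_stage <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
            class = "cortexmix_pipeline_error", parent = e)
    })
  }
  out <- function(f) file.path(config$out_dir, f)
  written <- character()

  markers <- run_stage("read_inputs", function() {
    if (is.null(config$markers)) default_markers() else read_markers(config$markers)
  })
  panel_expr <- run_stage("read_inputs", function() read_expression(config$panel))
  labels <- run_stage("read_inputs", function() read_labels_file(config$panel_labels))
  bulk <- run_stage("read_inputs", function() read_expression(config$bulk))
  metadata <- if (!is.null(config$metadata)) {
    run_stage("read_inputs", function() {
      readr::read_delim(config$metadata, delim = delim_for(config$metadata),
                        show_col_types = FALSE, progress = FALSE)
    })
  } else NULL
  panel <- reference_panel(panel_expr, labels)
  log_stage("stage read_inputs: ", nrow(panel_expr), " panel genes, ",
            ncol(bulk), " bulk samples, ", nrow(markers), " markers")

  curation <- run_stage("curate", function() {
    loocv_curate(panel, markers, engine = config$engine,
                 threshold = config$curation_threshold)
  })
  readr::write_csv(curation$report, out("curation_report.csv"))
  written <- c(written, "curation_report.csv")
  log_stage("stage curate: retained ", length(curation$retained), " samples in ",
            curation$rounds_run, " round(s)")

  fit <- run_stage("deconvolve", function() {
    deconvolve(bulk, panel = curation$panel, markers = markers,
               engine = config$engine)
  })
  write_proportions(fit, out("proportions.tsv"))
  jsonlite::write_json(glance(fit), out("fit.json"), auto_unbox = TRUE, digits = NA)
  written <- c(written, "proportions.tsv", "fit.json")
  log_stage("stage deconvolve: ", nrow(fit$proportions), " samples, engine ",
            config$engine)

  if (!is.null(config$validate)) {
    val <- run_stage("validate", function() {
      design <- build_chimeric_design(
        n_distributions = config$validate$n_distributions %||% 8,
        repeats = config$validate$repeats %||% 3,
        seed = config$seed
      )
      run_chimeric_validation(
        list(expression = curation$panel$expression, labels = curation$panel$labels),
        markers, design, engine = config$engine, seed = config$seed
      )
    })
    jsonlite::write_json(glance(val), out("validation.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(val$per_library, out("validation_per_library.csv"))
    written <- c(written, "validation.json", "validation_per_library.csv")
    log_stage("stage validate: pooled RMSE ", signif(val$rmse, 4))
  }

  if (!is.null(config$contrasts) && !is.null(metadata)) {
    assoc <- run_stage("associate", function() {
      dplyr::bind_rows(lapply(config$contrasts, function(ctr) {
        fit_association(fit, metadata, predictor = ctr$predictor,
                        covariates = ctr$covariates %||% character())
      }))
    })
    readr::write_csv(assoc, out("associations.csv"))
    written <- c(written, "associations.csv")
    log_stage("stage associate: ", nrow(assoc), " association rows")
  }

  manifest <- list(
    package = "cortexmix",
    version = as.character(packageVersion("cortexmix")),
    seed = config$seed,
    engine = config$engine,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    inputs = as.list(tools::md5sum(unname(inputs))),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, written)))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, out("run.log"))
  invisible(config$out_dir)
}

#' Write a self-contained synthetic demo input set
#'
#' Generates a synthetic reference panel, marker list, case/control bulk
#' cohort with planted effects, metadata, and true proportions, and writes
#' them to `dir` in the pipeline's file formats. Used by the examples and the
#' test-suite as a reproducible end-to-end fixture.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param config A [synthetic_config()] for the reference profiles.
#' @param spec A [cohort_spec()] for the bulk cohort.
#'
#' @return Named list of file paths.
#' @export
write_demo_inputs <- function(dir, seed = 42,
                              config = synthetic_config(seed = seed),
                              spec = cohort_spec(n_cases = 20, n_controls = 20,
                                                 seed = seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- simulate_reference_profiles(config)
  cohort <- simulate_bulk_cohort(profiles, spec)
  paths <- list(
    panel = file.path(dir, "panel_expression.tsv"),
    panel_labels = file.path(dir, "panel_labels.csv"),
    markers = file.path(dir, "markers.tsv"),
    bulk = file.path(dir, "bulk_expression.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    true_proportions = file.path(dir, "true_proportions.tsv")
  )
  write_expression(profiles$expression, paths$panel)
  readr::write_csv(tibble::tibble(sample_id = names(profiles$labels),
                                  cell_type = unname(profiles$labels)),
                   paths$panel_labels)
  write_markers(profiles$markers, paths$markers)
  write_expression(cohort$expression, paths$bulk)
  readr::write_csv(cohort$metadata, paths$metadata)
  write_proportions(cohort$proportions, paths$true_proportions)
  paths
}
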
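# Proportion–phenotype association: linear models, stepwise covariate
# selection, donor/family-clustered mixed models, simulation power estimates,
# and fixed-effect meta-analysis. Outcomes are analyzed as raw proportions
# (no logit transform) so effects are in proportion units.

join_proportions <- function(proportions, metadata) {
  props <- if (inherits(proportions, "deconvolution_result")) {
    proportions$proportions
  } else if (is.matrix(proportions)) {
    prop_as_tibble(proportions)
  } else proportions
  if (!is.data.frame(metadata) || !"sample_id" %in% names(metadata)) {
    abort("`metadata` must be a data frame with a `sample_id` column",
          class = "cortexmix_input_error")
  }
  dplyr::inner_join(props, tibble::as_tibble(metadata), by = "sample_id")
}

# Character predictors become factors; when a (case-insensitive) "control"
# level exists it is made the reference, so effects read as group-minus-control
# regardless of how a metadata file ordered its strings.
normalize_predictor <- function(data, predictor) {
  pv <- data[[predictor]]
  if (is.character(pv)) pv <- factor(pv)
  if (is.factor(pv)) {
    ctrl <- levels(pv)[tolower(levels(pv)) %in% c("control", "ctrl")]
    if (length(ctrl) == 1) pv <- stats::relevel(pv, ref = ctrl)
    data[[predictor]] <- pv
  }
  data
}

assoc_row <- function(fit, cell_type, predictor, covariates, model, n,
                      singular = NA) {
  sm <- summary(fit)
  co <- if (inherits(fit, "lmerMod")) sm$coefficients else sm$coefficients
  idx <- grep(paste0("^", predictor), rownames(co))
  if (length(idx) == 0) {
    abort(paste0("no fitted coefficient for predictor '", predictor, "'"),
          class = "cortexmix_model_error")
  }
  est <- co[idx, "Estimate"]
  se <- co[idx, "Std. Error"]
  tibble::tibble(
    cell_type = cell_type,
    predictor = predictor,
    term = rownames(co)[idx],
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(est / se),
    p_value = unname(2 * pnorm(-abs(est / se))),
    n = n,
    model = model,
    covariates = paste(covariates, collapse = ","),
    singular = singular
  )
}

#' Linear association of cell-type proportions with a predictor
#'
#' Ordinary least squares of each cell type's proportion on the predictor plus
#' covariates, one fit per cell type. Effects are on the raw proportion scale;
#' p-values are two-sided Wald tests.
#'
#' @param proportions Proportion tibble (`sample_id` + one column per cell
#'   type), matrix, or `deconvolution_result`.
#' @param metadata Data frame with `sample_id`, the predictor, and covariates.
#' @param predictor Column name of the predictor of interest.
#' @param covariates Character vector of covariate column names.
#' @param cell_types Cell types to analyze (default: all proportion columns).
#' @param p_adjust Optional multiple-testing correction across cell types
#'   (`"none"`, default, or `"BH"`).
#'
#' @return An `association_result` tibble: one row per cell type and predictor
#'   term, with `estimate`, `std_error`, `statistic`, `p_value`, `n`, `model`,
#'   `covariates`.
#' @export
fit_association <- function(proportions, metadata, predictor,
                            covariates = character(), cell_types = NULL,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  base <- if (inherits(proportions, "deconvolution_result")) {
    proportions$proportions
  } else if (is.matrix(proportions)) prop_as_tibble(proportions) else proportions
  data <- join_proportions(base, metadata)
  if (is.null(cell_types)) {
    cell_types <- canonical_types(setdiff(names(base), "sample_id"))
  }
  vars <- c(predictor, covariates)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(missing_vars, collapse = ", ")),
          class = "cortexmix_input_error")
  }
  data <- normalize_predictor(data, predictor)
  rows <- lapply(cell_types, function(ct) {
    d <- data[complete.cases(data[, c(ct, vars)]), c(ct, vars)]
    if (nrow(d) < length(covariates) + 2) {
      abort(paste0("too few complete cases (", nrow(d), ") for '", ct, "'"),
            class = "cortexmix_input_error")
    }
    pv <- d[[predictor]]
    if ((is.numeric(pv) && var(pv) == 0) ||
        (!is.numeric(pv) && length(unique(pv)) < 2)) {
      abort(paste0("predictor '", predictor, "' has no variation"),
            class = "cortexmix_input_error")
    }
    if (var(d[[ct]]) == 0) {
      abort(paste0("outcome '", ct, "' is constant"), class = "cortexmix_input_error")
    }
    f <- as.formula(paste0("`", ct, "` ~ ", paste(vars, collapse = " + ")))
    fit <- lm(f, data = d)
    if (anyNA(coef(fit))) {
      abort(paste0("collinear design: aliased term(s) ",
                   paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
            class = "cortexmix_model_error")
    }
    assoc_row(fit, ct, predictor, covariates, "ols", nrow(d))
  })
  out <- dplyr::bind_rows(rows)
  if (p_adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  structure(out, class = c("association_result", class(out)))
}

#' Stepwise covariate selection by AIC
#'
#' Bidirectional stepwise search (via `MASS::stepAIC`) starting from the full
#' model of the outcome on all candidate covariates, minimizing AIC. The
#' search is deterministic given the data.
#'
#' @param data Data frame holding outcome and candidates.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate covariate names (an empty
#'   set returns the intercept-only model).
#'
#' @return A list with `selected` (character vector), `formula`, and
#'   `aic_path` (tibble of the step trace).
#' @export
select_covariates <- function(data, outcome, candidates = character()) {
  if (!outcome %in% names(data)) {
    abort(paste0("outcome '", outcome, "' not found"), class = "cortexmix_input_error")
  }
  if (length(candidates) == 0) {
    return(list(selected = character(),
                formula = as.formula(paste0("`", outcome, "` ~ 1")),
                aic_path = tibble::tibble()))
  }
  missing_vars <- setdiff(candidates, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("candidate covariate(s) not found: ",
                 paste(missing_vars, collapse = ", ")),
          class = "cortexmix_input_error")
  }
  d <- data[complete.cases(data[, c(outcome, candidates)]), c(outcome, candidates)]
  full <- lm(as.formula(paste0("`", outcome, "` ~ ",
                               paste(candidates, collapse = " + "))), data = d)
  sel <- MASS::stepAIC(full, direction = "both", trace = 0,
                       scope = list(lower = ~1))
  list(
    selected = labels(terms(sel)),
    formula = stats::formula(sel),
    aic_path = tibble::as_tibble(sel$anova)
  )
}

#' Mixed-model association with donor or family clustering
#'
#' Linear mixed model of each cell type's proportion on the predictor plus
#' covariates with a random intercept per grouping unit (donor or family);
#' optionally random slopes for the predictor. P-values are two-sided Wald
#' tests on the fixed-effect estimates. A singular fit (e.g. zero estimated
#' between-group variance) is flagged in the result, not dropped.
#'
#' @param proportions Proportion container (as in [fit_association()]).
#' @param metadata Data frame with `sample_id`, the grouping column, the
#'   predictor, and covariates.
#' @param predictor Predictor column name.
#' @param covariates Covariate column names.
#' @param grouping Grouping column (default `"donor_id"`).
#' @param cell_types Cell types to analyze (default: all).
#' @param random_slopes Add a random slope for the predictor (default FALSE).
#'
#' @return An `association_result` tibble with a `singular` flag column.
#' @export
fit_mixed_association <- function(proportions, metadata, predictor,
                                  covariates = character(),
                                  grouping = "donor_id", cell_types = NULL,
                                  random_slopes = FALSE) {
  data <- join_proportions(proportions, metadata)
  if (!grouping %in% names(data)) {
    abort(paste0("grouping column '", grouping, "' not found"),
          class = "cortexmix_input_error")
  }
  if (length(unique(data[[grouping]])) < 2) {
    abort("mixed model needs >= 2 grouping units", class = "cortexmix_input_error")
  }
  if (is.null(cell_types)) {
    base <- if (inherits(proportions, "deconvolution_result")) {
      proportions$proportions
    } else if (is.matrix(proportions)) prop_as_tibble(proportions) else proportions
    cell_types <- canonical_types(setdiff(names(base), "sample_id"))
  }
  re <- if (random_slopes) {
    paste0("(1 + ", predictor, " | ", grouping, ")")
  } else {
    paste0("(1 | ", grouping, ")")
  }
  vars <- c(predictor, covariates)
  data <- normalize_predictor(data, predictor)
  rows <- lapply(cell_types, function(ct) {
    d <- data[complete.cases(data[, c(ct, vars, grouping)]), ]
    f <- as.formula(paste0("`", ct, "` ~ ", paste(vars, collapse = " + "), " + ", re))
    ctrl <- lme4::lmerControl(
      check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4),
      check.nobs.vs.nlev = "ignore", check.nobs.vs.rankZ = "ignore",
      check.nobs.vs.nRE = "ignore"
    )
    fit <- suppressMessages(suppressWarnings(lmerTest::lmer(f, data = d, control = ctrl)))
    assoc_row(fit, ct, predictor, covariates, "lmm", nrow(d),
              singular = lme4::isSingular(fit))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("association_result", class(out)))
}

#' Monte-Carlo power for a two-group proportion contrast
#'
#' Simulates `n_sims` datasets in which the two groups' mean proportions
#' differ by `effect` with Gaussian noise of standard deviation `sd`, fits
#' the group contrast by ordinary least squares, and reports the fraction of
#' simulations rejecting at level `alpha`.
#'
#' @param n_per_group Group sizes; a single number (both groups) or a length-2
#'   vector.
#' @param effect Planted group difference (proportion units).
#' @param sd Residual standard deviation (> 0).
#' @param alpha Significance level (default 0.05).
#' @param n_sims Number of simulations (>= 100).
#' @param seed Integer seed.
#'
#' @return A one-row tibble: `power`, `mc_se` (Monte-Carlo standard error),
#'   `effect`, `n1`, `n2`, `sd`, `alpha`, `n_sims`.
#' @export
estimate_power <- function(n_per_group, effect, sd, alpha = 0.05,
                           n_sims = 2000, seed = 1) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  assert_count(n_per_group[1], "n_per_group[1]", min = 2)
  assert_count(n_per_group[2], "n_per_group[2]", min = 2)
  assert_scalar(sd, "sd", lower = 0, strict_lower = TRUE)
  assert_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  assert_count(n_sims, "n_sims", min = 100)
  n1 <- n_per_group[1]; n2 <- n_per_group[2]
  g <- c(rep(0, n1), rep(1, n2))
  X <- cbind(1, g)
  XtXinv <- solve(crossprod(X))
  df <- n1 + n2 - 2
  crit <- qt(1 - alpha / 2, df)
  rej <- withr::with_seed(child_seed(seed, "power"), {
    vapply(seq_len(n_sims), function(i) {
      y <- g * effect + rnorm(n1 + n2, 0, sd)
      b <- XtXinv %*% crossprod(X, y)
      r <- y - X %*% b
      se <- sqrt(sum(r^2) / df * XtXinv[2, 2])
      abs(b[2] / se) > crit
    }, logical(1))
  })
  p <- mean(rej)
  tibble::tibble(power = p, mc_se = sqrt(p * (1 - p) / n_sims),
                 effect = effect, n1 = n1, n2 = n2, sd = sd,
                 alpha = alpha, n_sims = n_sims)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools association results for the same cell type and predictor across
#' studies with inverse-variance weights: the combined effect is the
#' weighted mean, its standard error `1 / sqrt(sum(w))`, and the p-value a
#' two-sided Wald test. A result with infinite standard error receives zero
#' weight.
#'
#' @param results An `association_result` tibble (rows from >= 2 studies,
#'   e.g. via `dplyr::bind_rows`), or a list of them.
#'
#' @return An `association_result` tibble with one pooled row per cell type,
#'   plus a `k_studies` column.
#' @export
meta_analyze <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  needed <- c("cell_type", "predictor", "estimate", "std_error")
  if (!all(needed %in% names(results))) {
    abort(paste0("meta_analyze needs columns: ", paste(needed, collapse = ", ")),
          class = "cortexmix_input_error")
  }
  if (length(unique(results$predictor)) > 1) {
    abort(paste0("mismatched predictors: ",
                 paste(unique(results$predictor), collapse = " vs ")),
          class = "cortexmix_input_error")
  }
  if (any(is.na(results$std_error) | results$std_error <= 0)) {
    abort("standard errors must be positive (Inf allowed for zero weight)",
          class = "cortexmix_input_error")
  }
  if (!"n" %in% names(results)) results$n <- NA_integer_
  pooled <- results |>
    dplyr::group_by(.data$cell_type, .data$predictor) |>
    dplyr::summarise(
      k_studies = dplyr::n(),
      w_sum = sum(1 / .data$std_error^2),
      estimate = sum(.data$estimate / .data$std_error^2) / w_sum,
      std_error = 1 / sqrt(w_sum),
      n = sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      statistic = .data$estimate / .data$std_error,
      p_value = 2 * pnorm(-abs(.data$statistic)),
      model = "fixed_effect_meta",
      term = .data$predictor,
      covariates = NA_character_
    ) |>
    dplyr::select("cell_type", "predictor", "term", "estimate", "std_error",
                  "statistic", "p_value", "n", "model", "covariates", "k_studies")
  bad <- pooled$k_studies < 2
  if (any(bad)) {
    abort(paste0("need >= 2 results per cell type; single result for: ",
                 paste(pooled$cell_type[bad], collapse = ", ")),
          class = "cortexmix_input_error")
  }
  structure(pooled, class = c("association_result", class(pooled)))
}
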
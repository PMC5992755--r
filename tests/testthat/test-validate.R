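test_that("rmse matches hand evaluation, is symmetric, and zero iff equal", {
  one <- function(v) matrix(v, 1, 2, dimnames = list("s1", c("a", "b")))
  expect_equal(rmse(one(c(0.5, 0.5)), one(c(0.3, 0.7))), 0.2)
  expect_equal(rmse(one(c(0.4, 0.6)), one(c(0.4, 0.6))), 0)
  for (seed in 1:5) {
    A <- random_simplex(4, 3, seed = seed)
    B <- random_simplex(4, 3, seed = seed + 100)
    dimnames(A) <- dimnames(B) <- list(paste0("s", 1:4), c("x", "y", "z"))
    expect_equal(rmse(A, B), rmse(B, A))
    expect_gt(rmse(A, B), 0)
  }
  bad <- matrix(0.5, 1, 2, dimnames = list("s1", c("a", "c")))
  expect_error(rmse(one(c(0.5, 0.5)), bad), "labels", class = "cortexmix_input_error")
})

test_that("largest-remainder allocation conserves the read total exactly", {
  for (seed in 1:20) {
    p <- as.vector(random_simplex(1, 4, seed = seed))
    for (total in c(7, 1001, 400000)) {
      alloc <- cortexmix:::largest_remainder(p, total)
      expect_identical(sum(alloc), as.integer(total))
      expect_true(all(alloc >= 0))
      expect_true(all(abs(alloc - p * total) < 1))
    }
  }
})

test_that("the chimeric design respects ranges, enumerates tasks, and is seed-stable", {
  d <- build_chimeric_design(n_distributions = 16, repeats = 5, seed = 3)
  expect_identical(d$n_tasks, 80L)
  expect_identical(nrow(design_tasks(d)), 80L)
  D <- as.matrix(d$distributions[, d$cell_types])
  expect_true(all(abs(rowSums(D) - 1) < 1e-9))
  for (ct in d$cell_types) {
    expect_true(all(D[, ct] >= d$ranges[[ct]][1] - 1e-12))
    expect_true(all(D[, ct] <= d$ranges[[ct]][2] + 1e-12))
  }
  d2 <- build_chimeric_design(n_distributions = 16, repeats = 5, seed = 3)
  expect_identical(d$distributions, d2$distributions)

  expect_error(
    build_chimeric_design(ranges = list(a = c(0.8, 0.9), b = c(0.5, 0.9))),
    "infeasible", class = "cortexmix_config_error"
  )
  # supplied vectors are validated with the violating index
  bad <- rbind(c(0.5, 0.3, 0.15, 0.05))
  colnames(bad) <- names(default_chimeric_ranges())
  expect_error(
    build_chimeric_design(distributions = bad),
    "index: 1", class = "cortexmix_config_error"
  )
  good <- rbind(c(0.3, 0.03, 0.2, 0.47))
  colnames(good) <- c("astrocyte", "microglia", "neuron", "oligodendrocyte")
  dg <- build_chimeric_design(distributions = good, repeats = 2)
  expect_identical(nrow(dg$distributions), 1L)
})

test_that("read-mode pooling conserves reads and degenerates to the donor pool", {
  prof <- simulate_reference_profiles(synthetic_config(n_genes = 60,
                                                       n_markers_per_type = 5,
                                                       seed = 9))
  pools <- simulate_read_pools(prof, pool_size = 5000, seed = 10)
  types <- sort(prof$config$cell_types)
  donors <- setNames(paste0(types, "_01"), types)
  p <- setNames(c(0.47, 0.03, 0.22, 0.28), types)
  lib <- pool_chimeric_library(prof$expression, prof$labels, donors, p,
                               total_reads = 4000, mode = "reads",
                               pools = pools, seed = 11)
  expect_equal(sum(lib$expression), 4000)
  expect_identical(sum(lib$read_counts), 4000L)

  # proportions (1,0,0,0) with allocation equal to the pool size reproduce
  # the donor pool exactly (sampling without replacement exhausts it)
  p_pure <- setNames(c(0, 0, 1, 0), types)
  lib2 <- pool_chimeric_library(prof$expression, prof$labels, donors, p_pure,
                                total_reads = 5000, mode = "reads",
                                pools = pools, seed = 12)
  donor_pool <- pools[pools$sample_id == donors[["neuron"]], ]
  got <- lib2$expression[lib2$expression > 0]
  expect_equal(sort(names(got)), sort(donor_pool$gene))
  expect_equal(unname(got[donor_pool$gene]), as.numeric(donor_pool$count))

  expect_error(
    pool_chimeric_library(prof$expression, prof$labels, donors[-1], p,
                          mode = "reads", pools = pools),
    "no donor", class = "cortexmix_input_error"
  )
})

test_that("expression-mode pooling round-trips through deconvolution on exclusive donors", {
  S <- exclusive_signature(markers_per_type = 10, seed = 13)
  panel <- exclusive_panel(S, n_reps = 2)
  mk <- exclusive_markers(S)
  types <- colnames(S)
  donors <- setNames(paste0(types, "_1"), types)
  p <- setNames(c(0.35, 0.05, 0.3, 0.3), types)
  lib <- pool_chimeric_library(panel$expression, panel$labels, donors, p,
                               mode = "expression")
  bulk <- matrix(lib$expression, ncol = 1,
                 dimnames = list(names(lib$expression), "chimera"))
  fit <- ssnmf_deconvolve(bulk, panel, mk)
  expect_lt(max(abs(prop_as_matrix(fit)[1, types] - p)), 0.01)
})

test_that("the chimeric harness scores an oracle at zero and noiseless donors exactly", {
  S <- exclusive_signature(markers_per_type = 10, seed = 14)
  profiles <- list(expression = exclusive_panel(S, n_reps = 2)$expression,
                   labels = exclusive_panel(S, n_reps = 2)$labels)
  mk <- exclusive_markers(S)
  design <- build_chimeric_design(n_distributions = 6, repeats = 3, seed = 15)

  oracle <- function(v, truth) truth
  val0 <- run_chimeric_validation(profiles, mk, design, engine = oracle, seed = 15)
  expect_equal(val0$rmse, 0)
  expect_identical(val0$n, 6L * 3L * 4L)

  val <- run_chimeric_validation(profiles, mk, design, engine = "ssnmf", seed = 15)
  expect_lte(val$rmse, 0.01)

  # single donor per type makes hold-out impossible
  one <- exclusive_panel(S, n_reps = 1)
  expect_error(
    run_chimeric_validation(list(expression = one$expression, labels = one$labels),
                            mk, design, engine = "ssnmf"),
    "hold-out", class = "cortexmix_input_error"
  )
})

test_that("pooled RMSE does not decrease with donor noise", {
  vals <- vapply(c(0, 0.1, 0.2, 0.4), function(sg) {
    prof <- simulate_reference_profiles(synthetic_config(noise_sigma = sg, seed = 5))
    des <- build_chimeric_design(n_distributions = 8, repeats = 6, seed = 5)
    run_chimeric_validation(prof, prof$markers, des, engine = "ssnmf", seed = 5)$rmse
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("gene dropout scores absent genes at zero and summarizes consistently", {
  prof <- simulate_reference_profiles(synthetic_config(n_genes = 60,
                                                       n_markers_per_type = 5,
                                                       seed = 16))
  design <- build_chimeric_design(n_distributions = 6, repeats = 2, seed = 16)
  dr <- gene_dropout_robustness(prof, prof$markers, design,
                                genes = c(prof$markers$gene[1:6], "NOT_A_MARKER"),
                                seed = 16)
  absent <- dr$per_gene[dr$per_gene$gene == "NOT_A_MARKER", ]
  expect_equal(absent$rmse_delta, 0)
  vals <- dr$per_gene$rmse_delta[!is.na(dr$per_gene$rmse_delta)]
  expect_equal(dr$mean, mean(vals))
  expect_equal(dr$sd, sd(vals))

  # a type with a single marker: its gene is skipped with a warning
  mk1 <- prof$markers[prof$markers$cell_type != "neuron" |
                        prof$markers$gene == prof$markers$gene[prof$markers$cell_type == "neuron"][1], ]
  expect_warning(
    dr1 <- gene_dropout_robustness(prof, mk1, design,
                                   genes = mk1$gene[mk1$cell_type == "neuron"][1],
                                   seed = 16),
    "single marker"
  )
  expect_true(is.na(dr1$per_gene$rmse_delta[1]))
})

test_that("LOOCV accuracy is near-perfect on an exclusive noiseless panel", {
  S <- exclusive_signature(markers_per_type = 10, seed = 18)
  panel <- exclusive_panel(S, n_reps = 3)
  lo <- loocv_accuracy(panel, exclusive_markers(S))
  expect_gte(lo$mean_accuracy, 0.99)
  expect_lt(lo$rmse_onehot, 0.01)
  expect_identical(nrow(lo$per_sample), ncol(panel$expression))
})
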
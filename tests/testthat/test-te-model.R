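make_design <- function(n_rep = 2, conditions = c("ctrl", "trt")) {
  tidyr::expand_grid(assay = c("ribo", "rna"), condition = conditions,
                     replicate = seq_len(n_rep)) %>%
    dplyr::mutate(sample_id = paste(assay, condition, replicate, sep = "_"))
}

# Exact cell-mean count table (integer means, no noise).
mean_counts <- function(design, mu_fun, genes = "g1") {
  out <- tibble::tibble(gene_id = genes)
  for (i in seq_len(nrow(design))) {
    s <- design[i, ]
    out[[s$sample_id]] <- vapply(genes, function(g)
      mu_fun(g, s$assay, s$condition), numeric(1))
  }
  riboage:::new_count_table(out)
}

test_that("size factors implement median-of-ratios", {
  design <- make_design(2)
  cts <- mean_counts(design, function(g, a, c) 100,
                     genes = sprintf("g%d", 1:20))
  sf <- size_factors(cts, design)
  expect_true(all(abs(sf$size_factor - 1) < 1e-12))

  # one library exactly doubled: its factor doubles relative to the rest
  cts2 <- cts
  cts2$ribo_ctrl_1 <- cts2$ribo_ctrl_1 * 2L
  sf2 <- size_factors(cts2, design)
  r <- sf2$size_factor[sf2$sample_id == "ribo_ctrl_1"] /
    sf2$size_factor[sf2$sample_id == "ribo_ctrl_2"]
  expect_equal(r, 2, tolerance = 1e-12)

  # random matrix against a direct median-of-ratios oracle
  withr::local_seed(9)
  m <- matrix(rpois(20 * 4, 50) + 1L, 20, 4)
  cts3 <- tibble::tibble(gene_id = sprintf("g%d", 1:20))
  des3 <- make_design(1)
  for (j in 1:4) cts3[[des3$sample_id[j]]] <- m[, j]
  sf3 <- size_factors(riboage:::new_count_table(cts3), des3,
                      scope = "joint")
  ref <- exp(rowMeans(log(m)))
  oracle <- apply(m, 2, function(col) median(col / ref))
  expect_equal(sf3$size_factor[match(des3$sample_id, sf3$sample_id)],
               unname(oracle), tolerance = 1e-12)
  expect_error(size_factors(
    riboage:::new_count_table(tibble::tibble(gene_id = "g1",
                                             ribo_ctrl_1 = 0L)),
    des3[1, ]), "nonzero")
})

test_that("dispersion estimation recovers alpha and respects the floor", {
  design <- make_design(50, conditions = "ctrl")
  withr::local_seed(11)
  # constant counts: method-of-moments floors at alpha_min
  cts_const <- mean_counts(design, function(g, a, c) 77)
  d <- estimate_dispersion(cts_const, design, method = "per_gene")
  expect_equal(d$dispersion, 1e-8)

  # NB alpha = 0.1, 50 replicates: per-gene MoM lands in [0.05, 0.2]
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    cts <- tibble::tibble(gene_id = "g1")
    for (id in design$sample_id) {
      cts[[id]] <- rnbinom(1, mu = 200, size = 10)
    }
    # one gene x 100 samples is degenerate; use 100 genes instead
    cts <- tibble::tibble(gene_id = sprintf("g%d", 1:50))
    for (id in design$sample_id) {
      cts[[id]] <- rnbinom(50, mu = 200, size = 10)
    }
    d <- estimate_dispersion(riboage:::new_count_table(cts), design,
                             method = "per_gene")
    mean(d$dispersion >= 0.05 & d$dispersion <= 0.2)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)

  # Poisson data: the estimate collapses toward the floor as n grows
  cts_pois <- tibble::tibble(gene_id = sprintf("g%d", 1:50))
  set.seed(12)
  for (id in design$sample_id) cts_pois[[id]] <- rpois(50, 500)
  dp <- estimate_dispersion(riboage:::new_count_table(cts_pois), design,
                            method = "moderated")
  expect_lt(median(dp$dispersion), 0.01)

  expect_error(estimate_dispersion(cts_const, design[1, ]), "replicates")
})

test_that("the interaction term recovers closed-form fold-change ratios", {
  design <- make_design(2)
  # ribo FC 4, rna FC 2 between conditions: interaction = log2(4/2) = 1
  cts <- mean_counts(design, function(g, a, c) {
    base <- if (a == "ribo") 100 else 200
    fc <- if (c == "trt") (if (a == "ribo") 4 else 2) else 1
    base * fc
  })
  sf <- tibble::tibble(sample_id = design$sample_id, assay = design$assay,
                       size_factor = 1)
  disp <- tibble::tibble(gene_id = "g1", dispersion = 1e-8)
  fit <- fit_te_glm(cts, design, size_factors = sf, dispersions = disp)
  expect_equal(fit$results$te_log2fc, 1, tolerance = 1e-6)
  expect_equal(fit$results$rna_log2fc, 1, tolerance = 1e-6)
  expect_equal(fit$results$ribo_log2fc, 2, tolerance = 1e-6)

  # identical change in both assays: no interaction
  cts0 <- mean_counts(design, function(g, a, c) {
    100 * (if (c == "trt") 3 else 1)
  })
  fit0 <- fit_te_glm(cts0, design, size_factors = sf, dispersions = disp)
  expect_equal(fit0$results$te_log2fc, 0, tolerance = 1e-6)
})

test_that("IRLS matches direct NB likelihood maximization", {
  withr::local_seed(13)
  design <- make_design(3)
  X <- cbind(1, as.numeric(design$assay == "ribo"),
             as.numeric(design$condition == "trt"),
             as.numeric(design$assay == "ribo") *
               as.numeric(design$condition == "trt"))
  alpha <- 0.1
  off <- log(runif(nrow(design), 0.5, 2))
  for (rep in 1:5) {
    beta_true <- c(log(150), rnorm(3, 0, 0.7))
    mu <- exp(drop(X %*% beta_true) + off)
    y <- rnbinom(length(mu), mu = mu, size = 1 / alpha)
    if (all(y == 0)) next
    ours <- riboage:::nb_glm_irls(y, X, off, alpha)
    oracle <- brute_nb_fit(y, X, off, alpha)
    expect_true(ours$converged)
    expect_equal(unname(ours$beta), unname(oracle), tolerance = 1e-4)
  }
})

test_that("swapping condition labels negates the TE estimate", {
  withr::local_seed(19)
  design <- make_design(3)
  cts <- tibble::tibble(gene_id = sprintf("g%d", 1:30))
  for (id in design$sample_id) {
    cts[[id]] <- rnbinom(30, mu = 150, size = 20)
  }
  cts <- riboage:::new_count_table(cts)
  f_fwd <- fit_te_glm(cts, design, reference = "ctrl", treatment = "trt")
  f_rev <- fit_te_glm(cts, design, reference = "trt", treatment = "ctrl")
  expect_equal(f_fwd$results$te_log2fc, -f_rev$results$te_log2fc,
               tolerance = 1e-5)
  expect_equal(f_fwd$results$p_value, f_rev$results$p_value,
               tolerance = 1e-5)
})

test_that("scaling one sample is absorbed by its size factor", {
  design <- make_design(2)
  cts <- mean_counts(design, function(g, a, c) {
    200 * (if (c == "trt" && a == "ribo") 3 else 1)
  }, genes = sprintf("g%d", 1:10))
  f1 <- fit_te_glm(cts, design,
                   dispersions = tibble::tibble(
                     gene_id = sprintf("g%d", 1:10), dispersion = 1e-8))
  cts2 <- cts
  cts2$rna_trt_1 <- cts2$rna_trt_1 * 4L
  sf2 <- size_factors(cts2, design)
  expect_equal(sf2$size_factor[sf2$sample_id == "rna_trt_1"] /
                 sf2$size_factor[sf2$sample_id == "rna_trt_2"], 4,
               tolerance = 1e-10)
  f2 <- fit_te_glm(cts2, design,
                   dispersions = tibble::tibble(
                     gene_id = sprintf("g%d", 1:10), dispersion = 1e-8))
  expect_equal(f2$results$te_log2fc, f1$results$te_log2fc,
               tolerance = 1e-6)
})

test_that("null simulations give calibrated tests and BH control", {
  # type-I error at the nominal 0.05 level
  cfg <- sim_config(n_genes = 600, n_replicates = 3,
                    conditions = c("young", "aged"),
                    frac_te_up = 0, frac_te_down = 0, txn_effect_log2 = 0.3,
                    dispersion = 0.05, seed = 202)
  g <- simulate_transcriptome(cfg)
  truth <- simulate_truth(g, cfg)
  fit <- fit_te_glm(simulate_counts(g, truth, cfg), sim_design(cfg))
  res <- dplyr::filter(fit$results, !is.na(fdr))
  rate <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), 3 * se)
  # BH output is monotone in p-rank and never below p
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  o <- order(res$p_value)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))

  # realized FDR under 10% true effects stays below 0.1 across seeds
  fdrs <- vapply(1:6, function(s) {
    cfg_s <- sim_config(n_genes = 300, n_replicates = 3,
                        conditions = c("young", "aged"),
                        frac_te_up = 0.05, frac_te_down = 0.05,
                        te_effect_log2 = 2, dispersion = 0.05,
                        mean_expression = 200, seed = 300 + s)
    g_s <- simulate_transcriptome(cfg_s)
    tr_s <- simulate_truth(g_s, cfg_s)
    f_s <- fit_te_glm(simulate_counts(g_s, tr_s, cfg_s), sim_design(cfg_s))
    called <- dplyr::filter(f_s$results, fdr < 0.05)
    if (nrow(called) == 0) return(0)
    null_ids <- unique(tr_s$gene_id[tr_s$te_class == "null"])
    mean(called$gene_id %in% null_ids)
  }, numeric(1))
  expect_lte(mean(fdrs), 0.1)
})

test_that("per-assay fold changes estimate the transcription effect", {
  cfg <- sim_config(n_genes = 200, n_replicates = 3,
                    conditions = c("young", "aged"),
                    frac_te_up = 0, frac_te_down = 0, txn_effect_log2 = 1,
                    dispersion = 0.02, mean_expression = 400,
                    mean_expression_log_sd = 0.3, seed = 404)
  g <- simulate_transcriptome(cfg)
  truth <- simulate_truth(g, cfg)
  cts <- simulate_counts(g, truth, cfg)
  design <- sim_design(cfg)
  rna <- assay_log2fc(cts, design, "rna")
  ribo <- assay_log2fc(cts, design, "ribo")
  tr <- dplyr::filter(truth, condition == "aged")
  err <- rna$log2fc - tr$txn_log2fc[match(rna$gene_id, tr$gene_id)]
  expect_lt(median(abs(err)), 0.15)
  # with no TE effects both assays estimate the same quantity
  expect_gt(cor(rna$log2fc, ribo$log2fc), 0.9)
})

test_that("twofold classification is strict and count-guarded", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    te_log2fc = c(1.0, 1.2, -1.2, 0.2, 5),
    se = 0.1, wald_stat = 1, p_value = 0.5, fdr = 0.5,
    mean_normalized_count = c(100, 100, 100, 100, 2),
    rna_log2fc = 0, ribo_log2fc = 0, converged = TRUE)
  cls <- classify_te(res)
  expect_equal(cls$class, c("unchanged", "up", "down", "unchanged",
                            "low_count"))
  t <- te_tally(cls)
  expect_equal(c(t$n_up, t$n_down, t$n_unchanged, t$n_low_count),
               c(1L, 1L, 2L, 1L))
})

test_that("classification recovers planted effect tallies", {
  cfg <- sim_config(n_genes = 400, n_replicates = 5,
                    conditions = c("young", "aged"),
                    frac_te_up = 0.1, frac_te_down = 0.1,
                    te_effect_log2 = 1.6, dispersion = 0.05,
                    mean_expression = 500, mean_expression_log_sd = 0.5,
                    seed = 505)
  g <- simulate_transcriptome(cfg)
  truth <- simulate_truth(g, cfg)
  fit <- fit_te_glm(simulate_counts(g, truth, cfg), sim_design(cfg))
  t <- te_tally(fit$results)
  expect_lte(abs(t$n_up - 40), 4)
  expect_lte(abs(t$n_down - 40), 4)
})

test_that("gene-set summaries tally classes over the member table", {
  res <- tibble::tibble(gene_id = sprintf("g%d", 1:10),
                        class = c(rep("down", 4), rep("unchanged", 5),
                                  "up"))
  s <- summarize_gene_set(res, sprintf("g%d", 1:10), "ribosome")
  expect_equal(s$n_down, 4L)
  expect_equal(s$n_up, 1L)
  expect_equal(s$n_genes, 10L)
  expect_equal(nrow(s$members[[1]]), 10)
  expect_true(s$n_up + s$n_down <= s$n_genes)
  expect_warning(s0 <- summarize_gene_set(res, c("x1", "x2"), "absent"),
                 "no members")
  expect_equal(s0$n_genes, 0L)
})

test_that("tidy and glance expose the fit in broom style", {
  design <- make_design(2)
  cts <- mean_counts(design, function(g, a, c) 100,
                     genes = sprintf("g%d", 1:5))
  fit <- fit_te_glm(cts, design,
                    dispersions = tibble::tibble(
                      gene_id = sprintf("g%d", 1:5), dispersion = 0.01))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gene_id", "te_log2fc", "fdr", "class") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_genes, 5L)
})
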
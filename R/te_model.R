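#' Median-of-ratios size factors
#'
#' DESeq-style normalization: the reference profile is the per-gene
#' geometric mean across the samples in scope (genes with any zero are
#' dropped from the reference), and each sample's factor is the median of
#' its count/reference ratios.  With `scope = "per_assay"` (default) the
#' reference and medians are computed separately within each assay, since
#' ribosome-profiling and RNA-Seq libraries have unrelated depths.
#'
#' @param counts A `count_table` (genes x samples).
#' @param design Sample sheet tibble (`sample_id`, `assay`, ...).
#' @param scope `"per_assay"` or `"joint"`.
#' @return A tibble `sample_id`, `assay`, `size_factor`.
#' @export
size_factors <- function(counts, design, scope = c("per_assay", "joint")) {
  scope <- match.arg(scope)
  assert_cols(design, c("sample_id", "assay"), "design")
  m <- count_matrix(counts)
  design <- dplyr::filter(design, .data$sample_id %in% colnames(m))
  groups <- if (scope == "per_assay") split(design$sample_id, design$assay)
            else list(all = design$sample_id)
  sf <- purrr::imap(groups, function(ids, nm) {
    sub <- m[, ids, drop = FALSE]
    log_gm <- rowMeans(log(sub))
    usable <- is.finite(log_gm)
    if (!any(usable)) {
      abort(sprintf(
        "no gene has nonzero counts in every sample of scope '%s'", nm))
    }
    vapply(ids, function(s) {
      stats::median(exp(log(sub[usable, s]) - log_gm[usable]))
    }, numeric(1))
  })
  tibble::tibble(sample_id = unlist(lapply(groups, identity),
                                    use.names = FALSE),
                 size_factor = unname(unlist(sf))) %>%
    dplyr::left_join(dplyr::select(design, "sample_id", "assay"),
                     by = "sample_id") %>%
    dplyr::select("sample_id", "assay", "size_factor") %>%
    dplyr::arrange(match(.data$sample_id, design$sample_id))
}

#' Per-gene negative-binomial dispersion
#'
#' Method-of-moments on normalized counts pooled within each
#' (assay, condition) cell: for a cell with mean `m` and variance `s2`, the
#' raw estimate is `(s2 - m) / m^2`; per-gene cell estimates are combined by
#' a df-weighted mean (df = replicates - 1).  With few replicates the raw
#' per-gene value is extremely noisy, so by default it is moderated toward
#' the df-weighted pooled estimate across all genes with `prior_df` pseudo
#' degrees of freedom before the floor `alpha_min` is applied
#' (`method = "moderated"`).  `method = "per_gene"` floors each cell
#' estimate at `alpha_min` and averages, with no cross-gene pooling.
#'
#' @param counts A `count_table`.
#' @param design Sample sheet with `sample_id`, `assay`, `condition`.
#' @param size_factors Output of [size_factors()] (computed if NULL).
#' @param alpha_min Dispersion floor (default 1e-8).
#' @param method `"moderated"` (default) or `"per_gene"`.
#' @param prior_df Pseudo-df of the pooled prior under moderation.
#' @return A tibble `gene_id`, `dispersion`, `df`.
#' @export
estimate_dispersion <- function(counts, design, size_factors = NULL,
                                alpha_min = 1e-8,
                                method = c("moderated", "per_gene"),
                                prior_df = 25) {
  method <- match.arg(method)
  assert_cols(design, c("sample_id", "assay", "condition"), "design")
  m <- count_matrix(counts)
  design <- dplyr::filter(design, .data$sample_id %in% colnames(m))
  cells <- split(design$sample_id,
                 paste(design$assay, design$condition, sep = "."))
  cells <- cells[vapply(cells, length, integer(1)) >= 2]
  if (!length(cells)) {
    abort(paste("dispersion estimation needs >= 2 replicates in at least",
                "one (assay, condition) cell; supply dispersions directly"))
  }
  if (is.null(size_factors)) size_factors <- size_factors(counts, design)
  sf <- size_factors$size_factor[match(colnames(m),
                                       size_factors$sample_id)]
  norm <- sweep(m, 2, sf, "/")

  raw <- matrix(NA_real_, nrow(m), length(cells))
  dfs <- numeric(length(cells))
  for (j in seq_along(cells)) {
    sub <- norm[, cells[[j]], drop = FALSE]
    mu <- rowMeans(sub)
    s2 <- apply(sub, 1, stats::var)
    raw[, j] <- ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
    dfs[j] <- length(cells[[j]]) - 1
  }
  combine <- function(vals) {   # df-weighted mean over available cells
    ok <- !is.na(vals)
    if (!any(ok)) return(NA_real_)
    sum(vals[ok] * dfs[ok]) / sum(dfs[ok])
  }
  if (method == "per_gene") {
    floored <- pmax(raw, alpha_min)
    alpha <- apply(floored, 1, combine)
  } else {
    gene_raw <- apply(raw, 1, combine)
    pooled <- stats::weighted.mean(
      as.vector(raw), rep(dfs, each = nrow(raw)), na.rm = TRUE)
    pooled <- max(alpha_min, pooled)
    gene_df <- apply(!is.na(raw), 1, function(ok) sum(dfs[ok]))
    alpha <- ifelse(gene_df > 0,
                    (gene_df * ifelse(is.na(gene_raw), 0, gene_raw) +
                       prior_df * pooled) / (gene_df + prior_df),
                    pooled)
  }
  tibble::tibble(gene_id = rownames(m),
                 dispersion = pmax(alpha, alpha_min, na.rm = TRUE),
                 df = apply(!is.na(raw), 1, function(ok) sum(dfs[ok])))
}

# One NB log-link GLM fit by IRLS with known dispersion and per-sample
# log-size-factor offsets.  X is the design matrix, y the counts.
nb_glm_irls <- function(y, X, offset, alpha, tol = 1e-8, max_iter = 100L) {
  nb_dev <- function(mu) {
    if (alpha < 1e-12) {
      2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    } else {
      r <- 1 / alpha
      2 * sum(ifelse(y > 0, y * log(y / mu), 0) -
                (y + r) * log((y + r) / (mu + r)))
    }
  }
  beta <- tryCatch(
    stats::lm.fit(X, log(y + 0.5) - offset)$coefficients,
    error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(
      stats::lm.wfit(X, z, w)$coefficients,
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit)) break
    beta <- fit
    dev_new <- nb_dev(pmax(mu, 1e-12))
    if (is.finite(dev_new) &&
        abs(dev_new - dev) < tol * (abs(dev_new) + 0.1)) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(solve(xtwx))), error = function(e)
    rep(NA_real_, ncol(X)))
  if (any(abs(beta) > 20)) converged <- FALSE
  list(beta = beta, se = se, converged = converged, deviance = dev)
}

# Shared per-gene fitting loop; returns coefficient/SE matrices.
fit_nb_genes <- function(m, X, offset, alpha) {
  p <- ncol(X)
  beta <- matrix(NA_real_, nrow(m), p)
  se <- matrix(NA_real_, nrow(m), p)
  converged <- logical(nrow(m))
  for (g in seq_len(nrow(m))) {
    y <- m[g, ]
    if (all(y == 0)) next
    f <- nb_glm_irls(y, X, offset, alpha[g])
    beta[g, ] <- f$beta
    se[g, ] <- f$se
    converged[g] <- f$converged
  }
  list(beta = beta, se = se, converged = converged)
}

#' Fit the translational-efficiency interaction model
#'
#' Per gene, a negative-binomial log-link GLM with per-sample
#' log-size-factor offsets:
#' \deqn{\log \mu_s = \log sf_s + \beta_0 + \beta_a [ribo] +
#'   \beta_c [treatment] + \beta_i [ribo][treatment]}
#' fitted by iteratively reweighted least squares.  The interaction
#' \eqn{\beta_i} is the change, between conditions, of ribosome-footprint
#' abundance not explained by the RNA change — the translational-efficiency
#' log fold change (reported in log2).  Wald p-values use the normal
#' reference; Benjamini-Hochberg FDR is computed over tested genes (fitted,
#' converged, and passing the mean-count filter).  Classification applies
#' the strict twofold rule of [classify_te()].
#'
#' @param counts A `count_table` containing both assays.
#' @param design Sample sheet (`sample_id`, `assay`, `condition`,
#'   `replicate`).
#' @param reference,treatment Condition labels to contrast; defaults: the
#'   first two conditions in `design` (in order of appearance).
#' @param size_factors Optional precomputed [size_factors()].
#' @param dispersions Optional tibble `gene_id`, `dispersion`; estimated
#'   via [estimate_dispersion()] when NULL.
#' @param lfc_threshold,min_mean_count Classification parameters, see
#'   [classify_te()].
#' @param scope Size-factor scope, see [size_factors()].
#' @return A `ribo_te_fit` object; `tidy()` returns the per-gene results
#'   (`gene_id`, `te_log2fc`, `se`, `wald_stat`, `p_value`, `fdr`,
#'   `mean_normalized_count`, `rna_log2fc`, `ribo_log2fc`, `converged`,
#'   `class`), `glance()` a one-row summary.
#' @export
fit_te_glm <- function(counts, design, reference = NULL, treatment = NULL,
                       size_factors = NULL, dispersions = NULL,
                       lfc_threshold = 1, min_mean_count = 5,
                       scope = "per_assay") {
  assert_cols(design, c("sample_id", "assay", "condition"), "design")
  conds <- unique(design$condition)
  reference <- reference %||% conds[1]
  treatment <- treatment %||% setdiff(conds, reference)[1]
  if (is.na(treatment) || !all(c(reference, treatment) %in% conds)) {
    abort("`reference` and `treatment` must name conditions in the design")
  }
  design <- dplyr::filter(design,
                          .data$condition %in% c(reference, treatment))
  cells <- dplyr::count(design, .data$assay, .data$condition)
  if (nrow(cells) < 4) {
    abort("both assays must be present in both conditions")
  }
  counts_sub <- counts[, c("gene_id", design$sample_id)]
  counts_sub <- new_count_table(counts_sub)
  if (is.null(size_factors)) {
    size_factors <- size_factors(counts_sub, design, scope = scope)
  }
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts_sub, design, size_factors)
  }
  m <- count_matrix(counts_sub)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  alpha <- dispersions$dispersion[match(rownames(m), dispersions$gene_id)]
  if (anyNA(alpha)) abort("`dispersions` must cover every gene")
  des <- design[match(colnames(m), design$sample_id), ]
  is_ribo <- as.numeric(des$assay == "ribo")
  is_trt <- as.numeric(des$condition == treatment)
  X <- cbind(intercept = 1, ribo = is_ribo, treatment = is_trt,
             interaction = is_ribo * is_trt)
  fit <- fit_nb_genes(m, X, log(sf), alpha)

  ln2 <- log(2)
  res <- tibble::tibble(
    gene_id = rownames(m),
    te_log2fc = fit$beta[, 4] / ln2,
    se = fit$se[, 4] / ln2,
    wald_stat = fit$beta[, 4] / fit$se[, 4],
    p_value = 2 * stats::pnorm(-abs(fit$beta[, 4] / fit$se[, 4])),
    mean_normalized_count = rowMeans(sweep(m, 2, sf, "/")),
    rna_log2fc = fit$beta[, 3] / ln2,
    ribo_log2fc = (fit$beta[, 3] + fit$beta[, 4]) / ln2,
    converged = fit$converged)
  tested <- res$converged & !is.na(res$p_value) &
    res$mean_normalized_count >= min_mean_count
  res$fdr <- NA_real_
  res$fdr[tested] <- stats::p.adjust(res$p_value[tested], method = "BH")

  out <- structure(list(results = res, design = design,
                        size_factors = size_factors,
                        dispersions = dispersions,
                        reference = reference, treatment = treatment,
                        lfc_threshold = lfc_threshold,
                        min_mean_count = min_mean_count),
                   class = "ribo_te_fit")
  out$results <- classify_te(res, lfc_threshold = lfc_threshold,
                             min_mean_count = min_mean_count)
  out
}

#' Two-group fold change within a single assay
#'
#' The same NB machinery as [fit_te_glm()] on the reduced design
#' `log mu = log sf + b0 + b1 [treatment]` over one assay's samples —
#' the per-assay fold changes whose agreement (footprint vs transcript)
#' indicates transcription-driven regulation.
#'
#' @inheritParams fit_te_glm
#' @param assay `"ribo"` or `"rna"`.
#' @return A tibble `gene_id`, `log2fc`, `se`, `p_value`, `fdr`,
#'   `mean_normalized_count`, `converged`.
#' @export
assay_log2fc <- function(counts, design, assay = c("ribo", "rna"),
                         reference = NULL, treatment = NULL,
                         size_factors = NULL, dispersions = NULL,
                         min_mean_count = 5) {
  assay <- match.arg(assay)
  conds <- unique(design$condition)
  reference <- reference %||% conds[1]
  treatment <- treatment %||% setdiff(conds, reference)[1]
  design <- dplyr::filter(design, .data$assay == .env$assay,
                          .data$condition %in% c(reference, treatment))
  if (nrow(design) == 0) abort("no samples for the requested assay")
  counts_sub <- new_count_table(counts[, c("gene_id", design$sample_id)])
  if (is.null(size_factors)) {
    size_factors <- size_factors(counts_sub, design, scope = "joint")
  }
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts_sub, design, size_factors)
  }
  m <- count_matrix(counts_sub)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  alpha <- dispersions$dispersion[match(rownames(m), dispersions$gene_id)]
  des <- design[match(colnames(m), design$sample_id), ]
  X <- cbind(intercept = 1,
             treatment = as.numeric(des$condition == treatment))
  fit <- fit_nb_genes(m, X, log(sf), alpha)
  ln2 <- log(2)
  res <- tibble::tibble(
    gene_id = rownames(m),
    log2fc = fit$beta[, 2] / ln2,
    se = fit$se[, 2] / ln2,
    p_value = 2 * stats::pnorm(-abs(fit$beta[, 2] / fit$se[, 2])),
    mean_normalized_count = rowMeans(sweep(m, 2, sf, "/")),
    converged = fit$converged)
  tested <- res$converged & !is.na(res$p_value) &
    res$mean_normalized_count >= min_mean_count
  res$fdr <- NA_real_
  res$fdr[tested] <- stats::p.adjust(res$p_value[tested], method = "BH")
  res
}

#' Twofold classification of TE changes
#'
#' Applies the strict greater-than-twofold rule to the interaction point
#' estimate: `up` when `te_log2fc > lfc_threshold`, `down` when
#' `te_log2fc < -lfc_threshold` (a gene at exactly the threshold is
#' `unchanged`).  Genes with `mean_normalized_count < min_mean_count`, an
#' all-zero fit, or a non-converged fit are classed `low_count` and never
#' called.
#'
#' @param x A `ribo_te_fit` or its results tibble.
#' @param lfc_threshold Absolute log2 threshold (default 1 = twofold).
#' @param min_mean_count Minimum mean normalized count (default 5).
#' @return The results tibble with a `class` column; see [te_tally()].
#' @export
classify_te <- function(x, lfc_threshold = 1, min_mean_count = 5) {
  res <- if (inherits(x, "ribo_te_fit")) x$results else x
  low <- is.na(res$te_log2fc) | !res$converged |
    res$mean_normalized_count < min_mean_count
  res$class <- dplyr::case_when(
    low ~ "low_count",
    res$te_log2fc > lfc_threshold ~ "up",
    res$te_log2fc < -lfc_threshold ~ "down",
    TRUE ~ "unchanged")
  res
}

#' Tally classified TE results
#'
#' @param results A classified results tibble (from [classify_te()] or
#'   `tidy()` on a fit).
#' @return A one-row tibble `n_up`, `n_down`, `n_unchanged`, `n_low_count`.
#' @export
te_tally <- function(results) {
  if (inherits(results, "ribo_te_fit")) results <- results$results
  tibble::tibble(
    n_up = sum(results$class == "up"),
    n_down = sum(results$class == "down"),
    n_unchanged = sum(results$class == "unchanged"),
    n_low_count = sum(results$class == "low_count"))
}

#' Summarize TE classes over a gene set
#'
#' @param results Classified results tibble.
#' @param genes Character vector of member gene ids.
#' @param set_name Label for the set.
#' @return A one-row tibble `set`, `n_genes` (members with results), `n_up`,
#'   `n_down`, with the member-level table nested in `members`.
#' @export
summarize_gene_set <- function(results, genes, set_name = "set") {
  if (inherits(results, "ribo_te_fit")) results <- results$results
  members <- dplyr::filter(results, .data$gene_id %in% genes)
  if (nrow(members) == 0) {
    warn(sprintf("gene set '%s' has no members with TE results", set_name))
  }
  tibble::tibble(
    set = set_name,
    n_genes = nrow(members),
    n_up = sum(members$class == "up"),
    n_down = sum(members$class == "down"),
    members = list(members))
}

#' @export
print.ribo_te_fit <- function(x, ...) {
  t <- te_tally(x$results)
  cat(sprintf(
    "Translational-efficiency fit: %s vs %s (reference)\n", x$treatment,
    x$reference))
  cat(sprintf("  %d genes; up: %d, down: %d, unchanged: %d, low_count: %d\n",
              nrow(x$results), t$n_up, t$n_down, t$n_unchanged,
              t$n_low_count))
  cat(sprintf("  twofold threshold |log2FC| > %g; min mean count %g\n",
              x$lfc_threshold, x$min_mean_count))
  invisible(x)
}

#' Tidy a translational-efficiency fit
#'
#' @param x A `ribo_te_fit`.
#' @param ... Unused.
#' @return The per-gene results tibble.
#' @export
tidy.ribo_te_fit <- function(x, ...) x$results

#' One-row summary of a translational-efficiency fit
#'
#' @param x A `ribo_te_fit`.
#' @param ... Unused.
#' @return A one-row tibble with contrast labels, gene tallies and the
#'   median dispersion.
#' @export
glance.ribo_te_fit <- function(x, ...) {
  t <- te_tally(x$results)
  tibble::tibble(
    reference = x$reference, treatment = x$treatment,
    n_genes = nrow(x$results),
    n_tested = sum(!is.na(x$results$fdr)),
    n_up = t$n_up, n_down = t$n_down,
    median_dispersion = stats::median(x$dispersions$dispersion))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
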
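# In-code fixtures shared across the suite.

tiny_genes <- function(n = 2, utr5 = 30L, n_codons = 30L, utr3 = 30L,
                       coding = TRUE) {
  tibble::tibble(
    gene_id = sprintf("t%02d", seq_len(n)),
    length = utr5 + 3L * n_codons + utr3,
    cds_start = utr5,
    cds_end = utr5 + 3L * n_codons,
    coding = coding,
    intron_start = NA_integer_,
    intron_end = NA_integer_,
    family_id = NA_character_)
}

tiny_reads <- function(transcript_id, five_prime, length = 28L,
                       sample_id = "s1", assay = "ribo",
                       spans_intron_junction = FALSE) {
  tibble::tibble(transcript_id = transcript_id,
                 five_prime = as.integer(five_prime),
                 length = as.integer(length),
                 sample_id = sample_id, assay = assay,
                 spans_intron_junction = spans_intron_junction)
}

# Independent per-read counting oracle used against count_cds().
brute_count_cds <- function(reads, genes, offsets, exclude_codons) {
  coding <- genes[genes$coding, ]
  samples <- sort(unique(reads$sample_id))
  mat <- matrix(0L, nrow(coding), length(samples),
                dimnames = list(coding$gene_id, samples))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    g <- coding[coding$gene_id == r$transcript_id, ]
    if (nrow(g) == 0) next
    o <- offsets$offset[match(r$length, offsets$length)]
    if (is.na(o) && any(is.na(offsets$length))) {
      o <- offsets$offset[is.na(offsets$length)][1]
    }
    if (is.na(o)) next
    site <- r$five_prime + o
    if (site < g$cds_start || site >= g$cds_end) next
    codon <- (site - g$cds_start) %/% 3L
    n_codons <- (g$cds_end - g$cds_start) %/% 3L
    if (codon < exclude_codons || codon > n_codons - 1L - exclude_codons) next
    mat[r$transcript_id, r$sample_id] <- mat[r$transcript_id, r$sample_id] + 1L
  }
  mat
}

# Upper-tail hypergeometric probability by direct combinatorial summation.
brute_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Direct NB log-likelihood maximization: the independent GLM oracle.
brute_nb_fit <- function(y, X, offset, alpha) {
  nll <- function(beta) {
    mu <- exp(pmin(drop(X %*% beta) + offset, 30))
    -sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  init <- stats::lm.fit(X, log(y + 0.5) - offset)$coefficients
  init[is.na(init)] <- 0
  stats::optim(init, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))$par
}
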
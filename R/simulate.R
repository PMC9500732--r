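#' Configuration for the synthetic Ribo-seq/RNA-Seq generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_transcriptome()], [simulate_truth()], [simulate_counts()] and
#' [simulate_reads()].  The defaults describe a deeply sequenced budding-yeast
#' style experiment: a bimodal footprint length distribution with modes at
#' 28 nt (A-site tRNA occupied) and 21 nt (empty A-site), the published
#' length-dependent digestion offsets, strong triplet periodicity, a marked
#' initiation peak, and log-normal expression with negative-binomial
#' replicate noise.
#'
#' @param n_genes Number of ordinary coding genes.
#' @param cds_codon_range Integer pair: min/max CDS length in codons
#'   (uniformly drawn, stop codon included).
#' @param n_replicates Replicates per condition per assay.
#' @param conditions Ordered condition labels; the first is the reference.
#' @param length_dist Named numeric vector mapping footprint length (nt) to
#'   probability; must sum to 1 and every length must appear in
#'   `true_offsets`.
#' @param true_offsets Ground-truth A-site offsets used to place footprint
#'   5' ends: a named vector or a tibble as returned by
#'   [standard_offsets()] (the default).
#' @param frame_fidelity Probability that a footprint's A-site is left
#'   exactly on a codon first nucleotide.  With probability
#'   `1 - frame_fidelity` the A-site is perturbed by a shift drawn uniformly
#'   from \{-1, 0, +1\} nt, so the expected frame-0 fraction is
#'   `frame_fidelity + (1 - frame_fidelity) / 3`.
#' @param start_enrichment Multiplicative occupancy weight on the initiating
#'   position (A-site on codon 2) relative to any internal codon.
#' @param mean_expression Median expected RNA count per gene at size
#'   factor 1.
#' @param mean_expression_log_sd Standard deviation of log baseline
#'   expression (natural log of a log-normal).
#' @param dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2).
#' @param frac_te_up,frac_te_down Fractions of ordinary genes given a
#'   positive/negative translational-efficiency effect in non-reference
#'   conditions.
#' @param te_effect_log2 Magnitude (log2) of the TE effect on affected genes.
#' @param txn_effect_log2 Standard deviation (log2) of per-gene
#'   transcription-level changes in non-reference conditions.
#' @param library_sizes Optional named vector of per-sample depth scalings;
#'   defaults to 1 for every sample.
#' @param rna_fragment_length RNA-Seq fragment length in nt.
#' @param rna_fragment_offset Offset used downstream to assign RNA fragments
#'   to transcript positions (recorded here as the generator's truth).
#' @param utr5,utr3 Untranslated leader/trailer lengths in nt.
#' @param n_ncrna Number of non-coding transcripts appended (they receive
#'   reads but carry no truth entry and are removed by [filter_ncrna()]).
#' @param intron_gene Optional [intron_spec()] describing one
#'   intron-containing gene.
#' @param element_family Optional [family_spec()] describing a multi-copy
#'   element family with two overlapping ORFs joined by a +1 frameshift.
#' @param seed Integer seed; every downstream draw is derived from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       cds_codon_range = c(100L, 400L),
                       n_replicates = 3,
                       conditions = c("young", "middle", "aged"),
                       length_dist = c(
                         "21" = 0.15, "22" = 0.07, "26" = 0.08, "27" = 0.25,
                         "28" = 0.28, "29" = 0.09, "30" = 0.05, "31" = 0.03),
                       true_offsets = standard_offsets(),
                       frame_fidelity = 0.9,
                       start_enrichment = 10,
                       mean_expression = 100,
                       mean_expression_log_sd = 1,
                       dispersion = 0.05,
                       frac_te_up = 0.03,
                       frac_te_down = 0.06,
                       te_effect_log2 = 1.5,
                       txn_effect_log2 = 0.5,
                       library_sizes = NULL,
                       rna_fragment_length = 50,
                       rna_fragment_offset = 15,
                       utr5 = 60,
                       utr3 = 60,
                       n_ncrna = 0,
                       intron_gene = NULL,
                       element_family = NULL,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    cds_codon_range = as.integer(cds_codon_range),
    n_replicates = as.integer(n_replicates),
    conditions = as.character(conditions),
    length_dist = length_dist,
    true_offsets = as_offset_table(true_offsets),
    frame_fidelity = frame_fidelity,
    start_enrichment = start_enrichment,
    mean_expression = mean_expression,
    mean_expression_log_sd = mean_expression_log_sd,
    dispersion = dispersion,
    frac_te_up = frac_te_up,
    frac_te_down = frac_te_down,
    te_effect_log2 = te_effect_log2,
    txn_effect_log2 = txn_effect_log2,
    library_sizes = library_sizes,
    rna_fragment_length = as.integer(rna_fragment_length),
    rna_fragment_offset = as.integer(rna_fragment_offset),
    utr5 = as.integer(utr5),
    utr3 = as.integer(utr3),
    n_ncrna = as.integer(n_ncrna),
    intron_gene = intron_gene,
    element_family = element_family,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  assert_positive_int(cfg$n_genes, "n_genes")
  assert_positive_int(cfg$n_replicates, "n_replicates")
  if (length(cfg$cds_codon_range) != 2 ||
      cfg$cds_codon_range[1] > cfg$cds_codon_range[2] ||
      cfg$cds_codon_range[1] < 3) {
    abort(paste("configuration error: `cds_codon_range` must be an ordered",
                "pair of integers >= 3 codons"),
          class = "riboage_config_error")
  }
  if (length(cfg$conditions) < 1 || anyDuplicated(cfg$conditions)) {
    abort("configuration error: `conditions` must be distinct labels",
          class = "riboage_config_error")
  }
  ld <- cfg$length_dist
  if (is.null(names(ld)) || any(ld < 0) || abs(sum(ld) - 1) > 1e-9) {
    abort(paste("configuration error: `length_dist` must be a named",
                "non-negative vector summing to 1"),
          class = "riboage_config_error")
  }
  emitted <- as.integer(names(ld))[ld > 0]
  known <- cfg$true_offsets$length
  if (!all(emitted %in% known)) {
    abort(sprintf(
      "configuration error: `length_dist` emits lengths without a true offset: %s",
      paste(setdiff(emitted, known), collapse = ", ")),
      class = "riboage_config_error")
  }
  assert_prob(cfg$frame_fidelity, "frame_fidelity")
  assert_prob(cfg$frac_te_up, "frac_te_up")
  assert_prob(cfg$frac_te_down, "frac_te_down")
  if (cfg$frac_te_up + cfg$frac_te_down > 1) {
    abort("configuration error: `frac_te_up` + `frac_te_down` must be <= 1",
          class = "riboage_config_error")
  }
  for (f in c("start_enrichment", "mean_expression", "te_effect_log2")) {
    if (cfg[[f]] <= 0) {
      abort(sprintf("configuration error: `%s` must be positive", f),
            class = "riboage_config_error")
    }
  }
  for (f in c("dispersion", "mean_expression_log_sd")) {
    if (cfg[[f]] < 0) {
      abort(sprintf("configuration error: `%s` must be non-negative", f),
            class = "riboage_config_error")
    }
  }
  if (!is.null(cfg$element_family)) {
    fam <- cfg$element_family
    if (((fam$orf_b[1] - fam$orf_a[1]) %% 3L) != 1L) {
      abort(paste("configuration error: element_family ORF-B frame must be",
                  "(ORF-A frame + 1) mod 3"),
            class = "riboage_config_error")
    }
    if (fam$frameshift < max(fam$orf_a[1], fam$orf_b[1]) ||
        fam$frameshift >= min(fam$orf_a[2], fam$orf_b[2])) {
      abort("configuration error: element_family frameshift must lie in the ORF overlap",
            class = "riboage_config_error")
    }
  }
  cfg
}

#' Specification of a synthetic intron-containing gene
#'
#' Describes one gene whose RNA is drawn from a mixture of unspliced and
#' spliced templates, emulating a transcript under splicing-mediated control.
#' The intron is placed in the 3' trailer, `gap` nt downstream of the stop
#' codon; its location only matters to RNA fragment counting.
#'
#' @param unspliced_fraction Named numeric vector (one entry per condition)
#'   or a single number: fraction of RNA fragments drawn from the unspliced
#'   template.
#' @param intron_length Intron length in nt.
#' @param gap Distance from the CDS end to the intron start, nt.
#' @param n_codons CDS length in codons.
#' @param te_log2fc TE effect (log2) of this gene in non-reference
#'   conditions; the default mirrors a strong translational shutdown.
#' @return A list of class `intron_spec`.
#' @export
intron_spec <- function(unspliced_fraction = 0.3, intron_length = 120L,
                        gap = 10L, n_codons = 250L, te_log2fc = -3) {
  structure(list(unspliced_fraction = unspliced_fraction,
                 intron_length = as.integer(intron_length),
                 gap = as.integer(gap),
                 n_codons = as.integer(n_codons),
                 te_log2fc = te_log2fc),
            class = "intron_spec")
}

#' Specification of a synthetic multi-copy element family
#'
#' A family of near-identical transcripts generated by independent point
#' mutations from one ancestor (no indels, so the copies are trivially
#' column-aligned).  The ancestor carries two overlapping ORFs: ribosomes
#' translate ORF-A in its own frame up to `frameshift`, then continue in the
#' +1 frame of ORF-B — the programmed +1 frameshift geometry of copia-type
#' retrotransposons.
#'
#' @param n_copies Number of copies emitted.
#' @param mutation_rate Per-base substitution probability per copy.
#' @param orf_a,orf_b 0-based half-open intervals of the two ORFs on the
#'   element; `orf_b` must start in frame (ORF-A frame + 1) mod 3.
#' @param frameshift 0-based position at which the ribosome shifts +1;
#'   must lie inside the ORF overlap.
#' @param utr Leader length upstream of `orf_a` start is implied by
#'   `orf_a[1]`; `utr` is the trailer appended after `orf_b`.
#' @param te_log2fc TE effect (log2) of every copy in non-reference
#'   conditions (element families are translationally repressed with age).
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_copies = 4L, mutation_rate = 0.02,
                        orf_a = c(60L, 960L), orf_b = c(874L, 1774L),
                        frameshift = 916L, utr = 60L, te_log2fc = -1.5) {
  structure(list(n_copies = as.integer(n_copies),
                 mutation_rate = mutation_rate,
                 orf_a = as.integer(orf_a), orf_b = as.integer(orf_b),
                 frameshift = as.integer(frameshift),
                 utr = as.integer(utr), te_log2fc = te_log2fc),
            class = "family_spec")
}

# Codons that do not terminate translation, used to fill CDS interiors.
nonstop_codons <- function() {
  all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1, paste0, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(nonstop_codons(), n_codons - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

#' Simulate a synthetic transcriptome
#'
#' Generates `n_genes` coding transcripts (CDS starting ATG, ending with a
#' stop codon, flanked by fixed-length leader and trailer), plus the optional
#' intron-containing gene, element-family copies, and non-coding transcripts.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per transcript and columns `gene_id`,
#'   `length`, `cds_start`, `cds_end` (0-based half-open), `coding`,
#'   `intron_start`, `intron_end`, `family_id`, `sequence`.
#' @export
#' @examples
#' genes <- simulate_transcriptome(sim_config(n_genes = 3, seed = 42))
#' genes[, 1:5]
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "transcriptome"), {
    n <- config$n_genes
    codons <- sample(seq(config$cds_codon_range[1], config$cds_codon_range[2]),
                     n, replace = TRUE)
    rows <- purrr::map2(seq_len(n), codons, function(i, nc) {
      cds_len <- 3L * nc
      len <- config$utr5 + cds_len + config$utr3
      tibble::tibble(
        gene_id = sprintf("g%04d", i), length = len,
        cds_start = config$utr5, cds_end = config$utr5 + cds_len,
        coding = TRUE, intron_start = NA_integer_, intron_end = NA_integer_,
        family_id = NA_character_,
        sequence = paste0(random_nt(config$utr5), random_cds(nc),
                          random_nt(config$utr3)))
    })
    genes <- dplyr::bind_rows(rows)

    if (!is.null(config$intron_gene)) {
      sp <- config$intron_gene
      cds_len <- 3L * sp$n_codons
      istart <- config$utr5 + cds_len + sp$gap
      iend <- istart + sp$intron_length
      len <- iend + config$utr3
      genes <- dplyr::bind_rows(genes, tibble::tibble(
        gene_id = "intron1", length = len,
        cds_start = config$utr5, cds_end = config$utr5 + cds_len,
        coding = TRUE, intron_start = istart, intron_end = iend,
        family_id = NA_character_,
        sequence = paste0(random_nt(config$utr5), random_cds(sp$n_codons),
                          random_nt(sp$gap), random_nt(sp$intron_length),
                          random_nt(len - iend))))
    }

    if (!is.null(config$element_family)) {
      fam <- config$element_family
      len <- fam$orf_b[2] + fam$utr
      ancestor <- strsplit(paste0(random_nt(fam$orf_a[1]),
                                  random_cds((fam$orf_a[2] - fam$orf_a[1]) %/% 3L),
                                  random_nt(len - fam$orf_a[2])), "")[[1]]
      copies <- purrr::map(seq_len(fam$n_copies), function(k) {
        seq_k <- ancestor
        hit <- which(stats::runif(len) < fam$mutation_rate)
        if (length(hit)) {
          seq_k[hit] <- vapply(seq_k[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        tibble::tibble(
          gene_id = sprintf("fam1_copy%d", k), length = len,
          cds_start = fam$orf_a[1], cds_end = fam$orf_a[2],
          coding = TRUE, intron_start = NA_integer_, intron_end = NA_integer_,
          family_id = "fam1", sequence = paste(seq_k, collapse = ""))
      })
      genes <- dplyr::bind_rows(genes, dplyr::bind_rows(copies))
      attr(genes, "family_ancestor") <- paste(ancestor, collapse = "")
    }

    if (config$n_ncrna > 0) {
      nc_rows <- purrr::map(seq_len(config$n_ncrna), function(i) {
        len <- 400L
        tibble::tibble(gene_id = sprintf("nc%02d", i), length = len,
                       cds_start = 0L, cds_end = len, coding = FALSE,
                       intron_start = NA_integer_, intron_end = NA_integer_,
                       family_id = NA_character_, sequence = random_nt(len))
      })
      genes <- dplyr::bind_rows(genes, dplyr::bind_rows(nc_rows))
    }
    genes
  })
}

#' Ground-truth expression and effect table
#'
#' Assigns each coding gene a log-normal baseline expression, a per-condition
#' transcription change, and a per-condition translational-efficiency change.
#' Ordinary genes are partitioned into TE classes `up` / `down` / `null`
#' according to `frac_te_up` / `frac_te_down`; the intron gene and element
#' copies receive the effects declared in their specs.  The reference
#' condition has all effects at 0, and `null`-class genes have TE log2FC
#' exactly 0 everywhere.
#'
#' @param genes Transcriptome tibble from [simulate_transcriptome()].
#' @param config The same [sim_config()].
#' @return A tibble with one row per coding gene x condition: `gene_id`,
#'   `condition`, `baseline`, `txn_log2fc`, `te_log2fc`, `te_class`.
#' @export
simulate_truth <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  coding <- dplyr::filter(genes, .data$coding)
  with_seed(derive_seed(config$seed, "truth"), {
    core <- coding$gene_id[is.na(coding$family_id) &
                             coding$gene_id != "intron1"]
    n_up <- round(config$frac_te_up * length(core))
    n_down <- round(config$frac_te_down * length(core))
    picked <- sample(core, n_up + n_down)
    class_map <- rep("null", nrow(coding))
    names(class_map) <- coding$gene_id
    class_map[picked[seq_len(n_up)]] <- "up"
    if (n_down > 0) class_map[picked[n_up + seq_len(n_down)]] <- "down"
    if (!is.null(config$element_family)) {
      fam_ids <- coding$gene_id[!is.na(coding$family_id)]
      class_map[fam_ids] <- if (config$element_family$te_log2fc < 0) "down"
                            else if (config$element_family$te_log2fc > 0) "up"
                            else "null"
    }
    if (!is.null(config$intron_gene) && "intron1" %in% coding$gene_id) {
      class_map["intron1"] <- if (config$intron_gene$te_log2fc < 0) "down"
                              else if (config$intron_gene$te_log2fc > 0) "up"
                              else "null"
    }
    baseline <- stats::rlnorm(nrow(coding),
                              meanlog = log(config$mean_expression),
                              sdlog = config$mean_expression_log_sd)
    names(baseline) <- coding$gene_id

    te_for <- function(gid) {
      if (!is.na(coding$family_id[match(gid, coding$gene_id)])) {
        config$element_family$te_log2fc
      } else if (gid == "intron1" && !is.null(config$intron_gene)) {
        config$intron_gene$te_log2fc
      } else {
        switch(class_map[[gid]],
               up = config$te_effect_log2,
               down = -config$te_effect_log2,
               0)
      }
    }

    purrr::map(config$conditions, function(cond) {
      is_ref <- cond == config$conditions[1]
      tibble::tibble(
        gene_id = coding$gene_id,
        condition = cond,
        baseline = unname(baseline[coding$gene_id]),
        txn_log2fc = if (is_ref) 0 else
          stats::rnorm(nrow(coding), 0, config$txn_effect_log2),
        te_log2fc = if (is_ref) 0 else
          vapply(coding$gene_id, te_for, numeric(1)),
        te_class = unname(class_map[coding$gene_id]))
    }) %>% dplyr::bind_rows()
  })
}

#' Sample sheet implied by a simulation configuration
#'
#' @param config A [sim_config()].
#' @return A tibble with `sample_id`, `assay`, `condition`, `replicate`,
#'   `library_size` — the design used by [simulate_reads()] and expected by
#'   the counting and modelling functions.
#' @export
sim_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- tidyr::expand_grid(assay = c("ribo", "rna"),
                             condition = config$conditions,
                             replicate = seq_len(config$n_replicates))
  grid <- dplyr::mutate(grid,
    sample_id = paste(.data$assay, .data$condition, .data$replicate, sep = "_"))
  ls <- config$library_sizes
  grid$library_size <- if (is.null(ls)) 1 else {
    out <- unname(ls[grid$sample_id])
    out[is.na(out)] <- 1
    out
  }
  dplyr::select(grid, "sample_id", "assay", "condition", "replicate",
                "library_size")
}

# Expected counts per gene for one sample: the NB mean layer shared by
# simulate_counts() and simulate_reads().
sample_means <- function(truth_cond, assay, library_size) {
  mu <- truth_cond$baseline * 2^truth_cond$txn_log2fc
  if (assay == "ribo") mu <- mu * 2^truth_cond$te_log2fc
  mu * library_size
}

draw_nb <- function(n, mu, alpha) {
  if (alpha < 1e-10) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate gene-level counts directly from the generative model
#'
#' Draws the per-gene, per-sample negative-binomial totals of the read
#' generator without emitting individual reads — the count-level marginal of
#' [simulate_reads()], convenient for studying the inference layer at scale.
#'
#' @inheritParams simulate_truth
#' @param truth Output of [simulate_truth()].
#' @param design Optional sample sheet; defaults to [sim_design()].
#' @return A `count_table` tibble (genes x samples) as produced by
#'   [count_cds()], without a read-accounting sidecar.
#' @export
simulate_counts <- function(genes, truth, config, design = NULL) {
  stopifnot(inherits(config, "sim_config"))
  design <- design %||% sim_design(config)
  coding <- dplyr::filter(genes, .data$coding)
  out <- tibble::tibble(gene_id = coding$gene_id)
  for (i in seq_len(nrow(design))) {
    s <- design[i, ]
    tr <- dplyr::filter(truth, .data$condition == s$condition)
    tr <- tr[match(coding$gene_id, tr$gene_id), ]
    if (anyNA(tr$gene_id)) {
      abort(sprintf("truth table lacks entries for: %s",
                    paste(coding$gene_id[is.na(tr$gene_id)], collapse = ", ")))
    }
    mu <- sample_means(tr, s$assay, s$library_size)
    out[[s$sample_id]] <- with_seed(
      derive_seed(config$seed, paste0("counts/", s$sample_id)),
      draw_nb(nrow(coding), mu, config$dispersion))
  }
  new_count_table(out, design = design)
}

# A-site landing positions and weights for one gene.  Ordinary genes expose
# codons 2..(n-1) in the CDS frame with `start_enrichment` weight on codon 2;
# element copies follow ORF-A frame up to the frameshift, then the +1 frame
# of ORF-B.
asite_sites <- function(gene, config) {
  fam <- config$element_family
  if (!is.na(gene$family_id) && !is.null(fam)) {
    pre <- seq.int(fam$orf_a[1] + 3L, fam$frameshift - 1L, by = 3L)
    post_first <- fam$frameshift +
      ((fam$orf_a[1] + 1L - fam$frameshift) %% 3L)
    post <- seq.int(post_first, fam$orf_b[2] - 4L, by = 3L)
    pos <- c(pre, post)
  } else {
    n_codons <- (gene$cds_end - gene$cds_start) %/% 3L
    pos <- gene$cds_start + 3L * seq.int(1L, n_codons - 2L)
  }
  list(pos = pos,
       w = c(config$start_enrichment, rep(1, length(pos) - 1L)))
}

# Emit n ribosome footprints for one gene (vectorized; overhanging reads are
# redrawn so the length distribution stays exact).
emit_footprints <- function(n, gene, sites, config, off_lengths, off_values) {
  if (n == 0) return(NULL)
  draw <- function(k) {
    a <- sites$pos[sample.int(length(sites$pos), k, replace = TRUE,
                              prob = sites$w)]
    off_frame <- stats::runif(k) >= config$frame_fidelity
    shift <- integer(k)
    if (any(off_frame)) {
      shift[off_frame] <- sample(c(-1L, 0L, 1L), sum(off_frame),
                                 replace = TRUE)
    }
    len <- off_lengths[sample.int(length(off_lengths), k, replace = TRUE,
                                  prob = config$length_dist)]
    fp <- a + shift - off_values[as.character(len)]
    list(fp = fp, len = len)
  }
  d <- draw(n)
  bad <- d$fp < 0L | d$fp + d$len > gene$length
  guard <- 0L
  while (any(bad) && guard < 50L) {
    r <- draw(sum(bad))
    d$fp[bad] <- r$fp
    d$len[bad] <- r$len
    bad <- d$fp < 0L | d$fp + d$len > gene$length
    guard <- guard + 1L
  }
  tibble::tibble(five_prime = as.integer(d$fp), length = as.integer(d$len),
                 spans_intron_junction = FALSE)
}

# Emit n RNA fragments for one gene; the intron gene draws from a
# spliced/unspliced template mixture.
emit_fragments <- function(n, gene, config, unspliced_fraction = NULL) {
  if (n == 0) return(NULL)
  flen <- min(config$rna_fragment_length, gene$length)
  if (!is.na(gene$intron_start) && !is.null(unspliced_fraction)) {
    ilen <- gene$intron_end - gene$intron_start
    unspliced <- stats::runif(n) < unspliced_fraction
    fp <- integer(n); spans <- logical(n)
    if (any(unspliced)) {
      fp[unspliced] <- sample.int(gene$length - flen + 1L, sum(unspliced),
                                  replace = TRUE) - 1L
    }
    if (any(!unspliced)) {
      spliced_len <- gene$length - ilen
      pos <- sample.int(spliced_len - flen + 1L, sum(!unspliced),
                        replace = TRUE) - 1L
      spans[!unspliced] <- pos < gene$intron_start &
        pos + flen > gene$intron_start
      fp[!unspliced] <- ifelse(pos < gene$intron_start, pos, pos + ilen)
    }
    tibble::tibble(five_prime = as.integer(fp), length = flen,
                   spans_intron_junction = spans)
  } else {
    fp <- sample.int(gene$length - flen + 1L, n, replace = TRUE) - 1L
    tibble::tibble(five_prime = as.integer(fp), length = flen,
                   spans_intron_junction = FALSE)
  }
}

#' Simulate aligned reads for every sample of the design
#'
#' For each sample, per-gene totals are drawn NB(mean = library size x
#' baseline x 2^txn (x 2^TE for Ribo-seq), dispersion alpha).  Ribosome
#' footprints place an A-site on a codon (initiation-weighted, frame noise
#' per `frame_fidelity`), draw a length from `length_dist` and set the 5'
#' end at `A-site - true_offset[length]`; fragments that would overhang the
#' transcript are redrawn.  RNA fragments are uniform over valid positions;
#' the intron gene mixes unspliced and spliced templates, flagging
#' junction-crossing spliced fragments.  Non-coding transcripts, if present,
#' receive baseline-level reads in both assays.
#'
#' @inheritParams simulate_counts
#' @return A tibble of read alignments in transcript coordinates:
#'   `transcript_id`, `five_prime` (0-based), `length`, `sample_id`,
#'   `assay`, `spans_intron_junction`.
#' @export
simulate_reads <- function(genes, truth, config, design = NULL) {
  stopifnot(inherits(config, "sim_config"))
  design <- design %||% sim_design(config)
  coding <- dplyr::filter(genes, .data$coding)
  noncoding <- dplyr::filter(genes, !.data$coding)
  off_lengths <- as.integer(names(config$length_dist))
  off_map <- lookup_offsets(off_lengths, config$true_offsets)
  names(off_map) <- as.character(off_lengths)
  sites <- purrr::map(seq_len(nrow(coding)),
                      function(i) asite_sites(coding[i, ], config))

  unspliced_for <- function(cond) {
    sp <- config$intron_gene
    if (is.null(sp)) return(NULL)
    u <- sp$unspliced_fraction
    if (!is.null(names(u))) unname(u[cond]) else u[1]
  }

  out <- purrr::map(seq_len(nrow(design)), function(i) {
    s <- design[i, ]
    tr <- dplyr::filter(truth, .data$condition == s$condition)
    tr <- tr[match(coding$gene_id, tr$gene_id), ]
    if (anyNA(tr$gene_id)) {
      abort(sprintf("truth table lacks entries for: %s",
                    paste(coding$gene_id[is.na(tr$gene_id)], collapse = ", ")))
    }
    with_seed(derive_seed(config$seed, paste0("reads/", s$sample_id)), {
      mu <- sample_means(tr, s$assay, s$library_size)
      counts <- draw_nb(nrow(coding), mu, config$dispersion)
      recs <- purrr::map(seq_len(nrow(coding)), function(g) {
        gene <- coding[g, ]
        r <- if (s$assay == "ribo") {
          emit_footprints(counts[g], gene, sites[[g]], config,
                          off_lengths, off_map)
        } else {
          emit_fragments(counts[g], gene, config,
                         unspliced_fraction = unspliced_for(s$condition))
        }
        if (is.null(r)) return(NULL)
        r$transcript_id <- gene$gene_id
        r
      })
      if (nrow(noncoding) > 0) {
        nc_counts <- draw_nb(nrow(noncoding), config$mean_expression *
                               s$library_size, config$dispersion)
        nc <- purrr::map(seq_len(nrow(noncoding)), function(g) {
          r <- emit_fragments(nc_counts[g], noncoding[g, ], config)
          if (is.null(r)) return(NULL)
          r$transcript_id <- noncoding$gene_id[g]
          r
        })
        recs <- c(recs, nc)
      }
      res <- dplyr::bind_rows(recs)
      if (nrow(res) == 0) return(NULL)
      res$sample_id <- s$sample_id
      res$assay <- s$assay
      res
    })
  }) %>% dplyr::bind_rows()
  dplyr::select(out, "transcript_id", "five_prime", "length", "sample_id",
                "assay", "spans_intron_junction")
}
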
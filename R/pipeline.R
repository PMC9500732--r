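#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC -> offset calibration -> counting ->
#' TE inference -> classification -> optional gene-set enrichment, writing
#' every stage product under `outdir` together with a machine-readable JSON
#' run report.  Identical configuration and seed give byte-identical
#' outputs.
#'
#' Input is either a [sim_config()] (synthetic mode) or a list with
#' `annotation` and `reads` paths (and optionally `design`) pointing at
#' files in the package's TSV dialects (consume mode).
#'
#' @param config A `sim_config`, a list of file paths, or the path of a
#'   YAML file holding [sim_config()] fields.
#' @param outdir Output directory (created if needed).
#' @param offsets_source `"calibrate"` (infer offsets from the start-codon
#'   metagene) or `"fixed"` (install the published offset table).
#' @param lfc_threshold,fdr_threshold,min_mean_count Classification and
#'   reporting thresholds.
#' @param exclude_codons Edge-codon exclusion for counting.
#' @param min_reads Minimum reads per length for calibration.
#' @param terms Optional term table for [enrich()].
#' @param seed Overrides `config$seed` when given.
#' @return The run report (a list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config, outdir,
                         offsets_source = c("calibrate", "fixed"),
                         lfc_threshold = 1, fdr_threshold = 0.05,
                         min_mean_count = 5, exclude_codons = 5L,
                         min_reads = 500L, terms = NULL, seed = NULL) {
  offsets_source <- match.arg(offsets_source)
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config))
    }
    fields <- yaml::read_yaml(config)
    config <- do.call(sim_config, fields)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list())

  if (inherits(config, "sim_config")) {
    if (!is.null(seed)) {
      config$seed <- as.integer(seed)
      config <- validate_sim_config(config)
    }
    genes <- simulate_transcriptome(config)
    truth <- simulate_truth(genes, config)
    design <- sim_design(config)
    reads <- simulate_reads(genes, truth, config, design)
    write_transcriptome_fasta(genes, file.path(outdir, "transcriptome.fa"))
    write_annotation(genes, file.path(outdir, "annotation.tsv"))
    write_truth(truth, file.path(outdir, "truth.tsv"))
    write_reads(reads, file.path(outdir, "reads.tsv"))
    write_design(design, file.path(outdir, "design.tsv"))
    report$stages$simulate <- list(
      n_transcripts = nrow(genes), n_reads = nrow(reads),
      seed = config$seed)
  } else {
    for (p in c("annotation", "reads")) {
      if (is.null(config[[p]]) || !file.exists(config[[p]])) {
        abort(sprintf("input path missing or not found: %s",
                      config[[p]] %||% p))
      }
    }
    genes <- read_annotation(config$annotation)
    reads <- read_reads(config$reads)
    design <- if (!is.null(config$design)) read_design(config$design) else {
      dplyr::distinct(reads, .data$sample_id, .data$assay) %>%
        dplyr::mutate(condition = "all", replicate = 1L)
    }
    truth <- NULL
    report$stages$load <- list(n_transcripts = nrow(genes),
                               n_reads = nrow(reads))
  }

  ribo_reads <- dplyr::filter(reads, .data$assay == "ribo")
  hist <- length_histogram(ribo_reads)
  readr::write_tsv(hist, file.path(outdir, "length_histogram.tsv"))
  profile <- metagene_profile(ribo_reads, genes, anchor = "start",
                              window = c(-30L, 30L))
  readr::write_tsv(tibble::as_tibble(profile),
                   file.path(outdir, "metagene_start.tsv"))
  report$stages$qc <- list(
    n_lengths = nrow(hist),
    metagene_reads = attr(profile, "n_reads"),
    out_of_window = attr(profile, "out_of_window"))

  offsets <- if (offsets_source == "calibrate") {
    calibrate_offsets(profile, min_reads = min_reads)
  } else {
    standard_offsets()
  }
  if (nrow(offsets) == 0) {
    abort(paste("offset calibration produced no usable lengths;",
                "lower `min_reads` or use offsets_source = \"fixed\""))
  }
  write_offsets(offsets, file.path(outdir, "offsets.tsv"))
  report$stages$offsets <- list(
    source = offsets_source,
    table = stats::setNames(as.list(offsets$offset),
                            as.character(offsets$length)))

  frames <- frame_report(ribo_reads, genes, offsets)
  readr::write_tsv(frames, file.path(outdir, "frame_report.tsv"))

  ribo_counts <- count_cds(reads, genes, offsets, assay = "ribo",
                           exclude_codons = exclude_codons,
                           samples = design$sample_id[design$assay == "ribo"])
  rna_counts <- count_cds(reads, genes, assay = "rna",
                          exclude_codons = exclude_codons,
                          samples = design$sample_id[design$assay == "rna"])
  write_counts(ribo_counts, file.path(outdir, "counts_ribo.tsv"))
  write_counts(rna_counts, file.path(outdir, "counts_rna.tsv"))
  side <- dplyr::bind_rows(sidecar(ribo_counts), sidecar(rna_counts))
  jsonlite::write_json(side, file.path(outdir, "read_accounting.json"),
                       dataframe = "rows")
  report$stages$count <- list(accounting = side)

  combined <- dplyr::inner_join(
    tibble::as_tibble(ribo_counts), tibble::as_tibble(rna_counts),
    by = "gene_id")
  combined <- new_count_table(combined)

  conditions <- unique(design$condition)
  reference <- conditions[1]
  fits <- list()
  tallies <- list()
  if (length(conditions) >= 2 &&
      min(table(design$assay, design$condition)) >= 2) {
    for (trt in conditions[-1]) {
      fit <- fit_te_glm(combined, design, reference = reference,
                        treatment = trt, lfc_threshold = lfc_threshold,
                        min_mean_count = min_mean_count)
      readr::write_tsv(fit$results,
                       file.path(outdir, sprintf("te_%s_vs_%s.tsv", trt,
                                                 reference)))
      fits[[trt]] <- fit
      tallies[[trt]] <- as.list(te_tally(fit$results))
    }
  }
  report$stages$te <- tallies

  if (!is.null(terms) && length(fits)) {
    fit1 <- fits[[1]]
    background <- fit1$results$gene_id[!is.na(fit1$results$fdr)]
    up <- fit1$results$gene_id[fit1$results$class == "up"]
    if (length(up) && length(background)) {
      enr <- enrich(intersect(up, background), background, terms)
      readr::write_tsv(enr, file.path(outdir, "enrichment.tsv"))
      report$stages$enrichment <- utils::head(
        dplyr::select(enr, "term_id", "fold_enrichment", "p_value"), 10)
    }
  }

  if (inherits(config, "sim_config") && !is.null(config$intron_gene)) {
    ic <- count_intron_reads(dplyr::filter(reads, .data$assay == "rna"),
                             genes)
    readr::write_tsv(ic, file.path(outdir, "intron_counts.tsv"))
    report$stages$intron <- ic
  }
  if (inherits(config, "sim_config") && !is.null(config$element_family)) {
    fam <- config$element_family
    fam_reads <- project_family_reads(
      dplyr::filter(reads, .data$assay == "ribo"), genes)
    fc <- count_family(fam_reads, fam$orf_a, fam$orf_b, offsets)
    readr::write_tsv(fc, file.path(outdir, "family_counts.tsv"))
    report$stages$family <- fc
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(report)
}
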
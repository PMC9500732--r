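test_that("non-coding reads are removed and tallied", {
  genes <- dplyr::bind_rows(tiny_genes(2),
                            dplyr::mutate(tiny_genes(1), gene_id = "nc01",
                                          coding = FALSE))
  reads <- tiny_reads(c(rep("t01", 10), rep("t02", 5), rep("nc01", 5)),
                      rep(35L, 20))
  out <- filter_ncrna(reads, genes)
  expect_equal(nrow(out), 15)
  expect_equal(attr(out, "n_removed"), 5L)
  expect_true(all(out$transcript_id != "nc01"))

  none <- filter_ncrna(reads[0, ], genes)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_removed"), 0L)

  expect_error(filter_ncrna(tiny_reads("ghost", 0L), genes),
               "unknown transcript.*ghost")
})

test_that("count_cds applies the A-site rule and edge exclusion", {
  genes <- tiny_genes(1, n_codons = 30)
  # one 28-nt read with its A-site on every codon (offset 15)
  fp <- genes$cds_start + 3L * (0:29) - 15L
  reads <- tiny_reads(rep("t01", 30), fp)
  cts <- count_cds(reads, genes, standard_offsets(), exclude_codons = 5)
  expect_equal(cts$s1, 30L - 2L * 5L)
  side <- sidecar(cts)
  expect_equal(side$edge_excluded, 10L)
  expect_equal(side$counted, 20L)

  # an A-site on codon 3 (1-based) falls in the excluded leading edge
  r3 <- tiny_reads("t01", genes$cds_start + 3L * 2L - 15L)
  expect_equal(count_cds(r3, genes, standard_offsets())$s1, 0L)

  # empty input keeps consistent axes
  empty <- count_cds(reads[0, ], genes, standard_offsets(),
                     samples = "s1")
  expect_equal(empty$gene_id, "t01")
  expect_equal(empty$s1, 0L)
})

test_that("count_cds guards degenerate inputs", {
  genes <- tiny_genes(1, n_codons = 30)
  reads <- tiny_reads("t01", genes$cds_start)
  expect_error(count_cds(reads, genes, standard_offsets(),
                         exclude_codons = -1), "exclude_codons")
  short <- tiny_genes(1, n_codons = 8)
  expect_warning(cts <- count_cds(reads, short, standard_offsets()),
                 "fully edge-excluded")
  expect_equal(cts$s1, 0L)
})

test_that("count_cds matches a brute-force per-read oracle exactly", {
  withr::local_seed(101)
  offsets <- standard_offsets()
  for (case in 1:10) {
    n_genes <- sample(5:30, 1)
    n_codons <- sample(15:60, n_genes, replace = TRUE)
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", seq_len(n_genes)),
      length = 60L + 3L * n_codons + 60L,
      cds_start = 60L, cds_end = 60L + 3L * n_codons,
      coding = sample(c(TRUE, FALSE), n_genes, replace = TRUE,
                      prob = c(0.85, 0.15)),
      intron_start = NA_integer_, intron_end = NA_integer_,
      family_id = NA_character_)
    n_reads <- sample(500:3000, 1)
    reads <- tibble::tibble(
      transcript_id = sample(genes$gene_id, n_reads, replace = TRUE),
      length = sample(c(21L, 26L, 28L, 31L, 33L), n_reads, replace = TRUE),
      sample_id = sample(c("a", "b"), n_reads, replace = TRUE),
      assay = "ribo")
    reads$five_prime <- sample.int(200L, n_reads, replace = TRUE) - 1L
    reads$five_prime <- pmin(reads$five_prime,
      genes$length[match(reads$transcript_id, genes$gene_id)] - reads$length)
    reads$spans_intron_junction <- FALSE
    ex <- sample(0:6, 1)
    cts <- suppressWarnings(
      count_cds(reads, genes, offsets, exclude_codons = ex,
                samples = c("a", "b")))
    oracle <- brute_count_cds(reads, genes, offsets, ex)
    expect_identical(unname(count_matrix(cts)), unname(oracle * 1.0))
    # sidecar categories partition the input reads exactly
    side <- sidecar(cts)
    expect_equal(sum(side$total), n_reads)
    expect_equal(side$total,
                 side$ncrna_filtered + side$no_offset_length +
                   side$outside_cds + side$edge_excluded + side$counted)
  }
})

test_that("increasing the edge exclusion never increases a count", {
  withr::local_seed(33)
  genes <- tiny_genes(4, n_codons = 40)
  reads <- tiny_reads(sample(genes$gene_id, 2000, replace = TRUE),
                      sample(20:120, 2000, replace = TRUE))
  prev <- NULL
  for (ex in c(0, 2, 5, 8)) {
    m <- count_matrix(count_cds(reads, genes, standard_offsets(),
                                exclude_codons = ex))
    if (!is.null(prev)) expect_true(all(m <= prev))
    prev <- m
  }
})

test_that("RNA counting uses the fixed 15-nt wildcard offset", {
  genes <- tiny_genes(1, n_codons = 30)
  # 50-nt fragment: site = 5' + 15 regardless of length
  reads <- tiny_reads("t01", genes$cds_start + 18L - 15L, length = 50L,
                      assay = "rna")
  cts <- count_cds(reads, genes, assay = "rna")
  expect_equal(cts$s1, 1L)
  # length <= offset is still assignable (only the 5' end matters)
  short <- tiny_reads("t01", genes$cds_start + 18L - 15L, length = 12L,
                      assay = "rna")
  expect_equal(count_cds(short, genes, assay = "rna")$s1, 1L)
})

test_that("intron read counting distinguishes overlap, containment, junctions", {
  genes <- tiny_genes(1) %>%
    dplyr::mutate(gene_id = "hac", intron_start = 60L, intron_end = 90L,
                  length = 180L)
  mk <- function(fp, len = 28L, spans = FALSE)
    tiny_reads("hac", fp, length = len, assay = "rna",
               spans_intron_junction = spans)
  reads <- dplyr::bind_rows(
    mk(62, len = 20),  # fully inside the intron
    mk(32),            # ends at 60: abuts, no overlap (half-open)
    mk(40),            # crosses the boundary: 1+ nt overlap
    mk(88),            # overlaps the tail
    mk(30, spans = TRUE))  # spliced junction read
  ov <- count_intron_reads(reads, genes, "hac", mode = "overlap")
  expect_equal(ov$intron_containing, 3L)
  expect_equal(ov$junction_spanning, 1L)
  cont <- count_intron_reads(reads, genes, "hac", mode = "contained")
  expect_equal(cont$intron_containing, 1L)
  expect_error(count_intron_reads(reads, tiny_genes(1), "t01"), "intron")
})

test_that("intron fraction matches the fragment-placement expectation", {
  u <- 0.3
  cfg <- sim_config(n_genes = 1, n_replicates = 1, conditions = "young",
                    mean_expression = 12000, mean_expression_log_sd = 0,
                    intron_gene = intron_spec(unspliced_fraction = u),
                    seed = 17)
  g <- simulate_transcriptome(cfg)
  reads <- simulate_reads(g, simulate_truth(g, cfg), cfg)
  rna <- dplyr::filter(reads, assay == "rna", transcript_id == "intron1")
  expect_gt(nrow(rna), 10000)
  ic <- count_intron_reads(rna, g)
  gi <- g[g$gene_id == "intron1", ]
  flen <- cfg$rna_fragment_length
  # brute-force enumeration of fragment start positions on each template
  starts_u <- 0:(gi$length - flen)
  p_overlap <- mean(starts_u < gi$intron_end &
                      starts_u + flen > gi$intron_start)
  spliced_len <- gi$length - (gi$intron_end - gi$intron_start)
  starts_s <- 0:(spliced_len - flen)
  p_junction <- mean(starts_s < gi$intron_start &
                       starts_s + flen > gi$intron_start)
  p_cond <- u * p_overlap / (u * p_overlap + (1 - u) * p_junction)
  n_evt <- ic$intron_containing + ic$junction_spanning
  obs <- ic$intron_containing / n_evt
  se <- sqrt(p_cond * (1 - p_cond) / n_evt)
  expect_lt(abs(obs - p_cond), 3 * se)
})

test_that("frame_in_window reveals the programmed +1 frameshift", {
  fam <- family_spec()
  cfg <- sim_config(n_genes = 1, n_replicates = 1, conditions = "young",
                    frame_fidelity = 1, mean_expression = 4000,
                    mean_expression_log_sd = 0, element_family = fam,
                    seed = 23)
  g <- simulate_transcriptome(cfg)
  reads <- simulate_reads(g, simulate_truth(g, cfg), cfg)
  cons <- project_family_reads(dplyr::filter(reads, assay == "ribo"), g)
  cons_genes <- tibble::tibble(gene_id = "consensus",
                               length = g$length[!is.na(g$family_id)][1],
                               cds_start = fam$orf_a[1],
                               cds_end = fam$orf_a[2], coding = TRUE)
  # upstream of the shift: pure frame 0
  up <- frame_in_window(cons, cons_genes, "consensus", standard_offsets(),
                        c(fam$orf_a[1] + 30L, fam$frameshift - 30L))
  expect_equal(up$fraction[up$frame == 0], 1)
  # downstream of the shift, frames still anchored to ORF-A: frame 1
  down <- frame_in_window(cons, cons_genes, "consensus", standard_offsets(),
                          c(fam$orf_b[1] + 120L, fam$orf_b[2] - 30L))
  expect_equal(down$fraction[down$frame == 1], 1)
  # a window straddling the shift mixes the two frames; check the tally
  # against a brute-force per-read computation
  win <- c(fam$frameshift - 90L, fam$frameshift + 90L)
  mix <- frame_in_window(cons, cons_genes, "consensus", standard_offsets(),
                         win)
  omap <- setNames(standard_offsets()$offset, standard_offsets()$length)
  a <- cons$five_prime + omap[as.character(cons$length)]
  a <- a[a >= win[1] & a < win[2]]
  brute <- tabulate(((a - fam$orf_a[1]) %% 3L) + 1L, nbins = 3L)
  expect_equal(mix$n, as.integer(brute))
  expect_true(all(mix$n[1:2] > 0))
  expect_equal(mix$n[3], 0L)

  expect_error(frame_in_window(cons, cons_genes, "consensus",
                               standard_offsets(), c(50L, 50L)),
               "non-empty")
})
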
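test_that("simulation is deterministic under a seed and varies across seeds", {
  cfg1 <- simulation_config(n_genes = 30, seed = 1)
  cfg2 <- simulation_config(n_genes = 30, seed = 2)
  g1 <- simulate_annotation(cfg1)
  expect_identical(g1, simulate_annotation(cfg1))
  expect_false(identical(g1, simulate_annotation(cfg2)))

  tr1 <- simulate_truth(g1, cfg1)
  expect_identical(tr1, simulate_truth(g1, cfg1))
  w1 <- simulate_wave(g1, tr1, 5, cfg1)
  expect_identical(w1, simulate_wave(g1, tr1, 5, cfg1))
  expect_false(identical(w1, simulate_wave(g1, tr1, 5, cfg1, replicate = 2)))

  ct <- simulate_count_tables(g1, tr1, cfg1)
  expect_identical(ct, simulate_count_tables(g1, tr1, cfg1))
})

test_that("simulated annotations respect config bounds and pass validation", {
  cfg <- simulation_config(n_genes = 120, gene_length_range = c(25000, 60000),
                           genes_per_chrom = 50, seed = 5)
  genes <- simulate_annotation(cfg)
  expect_equal(nrow(genes), 120)
  expect_true(all(genes$length >= 25000 & genes$length <= 60000))
  expect_silent(validate_gene_set(genes))
  expect_true(all(genes$n_exons >= 2 & genes$n_exons <= 10))
  # genes do not overlap within a chromosome
  overlaps <- gene_body(genes) |>
    mutate(chrom = genes$chrom) |>
    group_by(chrom) |>
    arrange(start, .by_group = TRUE) |>
    summarise(ok = all(start[-1] >= head(end, -1)), .groups = "drop")
  expect_true(all(overlaps$ok))

  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(gene_length_range = c(500, 2000)), "1 kb")
})

test_that("wave fragments live on the 4sU-labeled segment of the advancing wave", {
  offsets_from_tss <- function(fr, genes) {
    gi <- match(fr$gene_id, genes$gene_id)
    ifelse(genes$strand[gi] == "+",
           fr$start - genes$tss[gi],
           genes$tss[gi] - 1 - (fr$end - 1))
  }

  # pulse longer than release time: support [TSS, TSS + v t)
  cfg <- simulation_config(n_genes = 10, gene_length_range = c(35000, 60000),
                           rate_model = rate_constant(3), background = 0,
                           seed = 9)
  genes <- simulate_annotation(cfg)
  truth <- simulate_truth(genes, cfg)
  off <- offsets_from_tss(simulate_wave(genes, truth, 5, cfg), genes)
  expect_true(all(off >= 0 & off < 15000))

  # release beyond the pulse: trailing window [v (t - w), v t)
  cfg15 <- simulation_config(n_genes = 10, gene_length_range = c(35000, 60000),
                             rate_model = rate_constant(2), background = 0,
                             time_points = c(0, 5, 15), seed = 9)
  g15 <- simulate_annotation(cfg15)
  t15 <- simulate_truth(g15, cfg15)
  off <- offsets_from_tss(simulate_wave(g15, t15, 15, cfg15), g15)
  expect_true(all(off >= 10000 & off < 30000))

  expect_error(simulate_wave(g15, t15, 45, cfg15), "time point")
})

test_that("the 0-min control is exon-restricted background only", {
  cfg <- simulation_config(n_genes = 8, seed = 13)
  genes <- simulate_annotation(cfg)
  truth <- simulate_truth(genes, cfg)
  fr <- simulate_wave(genes, truth, 0, cfg)
  expect_true(all(fr$origin == "background"))
  gi <- match(fr$gene_id, genes$gene_id)
  pos <- ifelse(genes$strand[gi] == "+", fr$start, fr$end - 1)
  in_exon <- vapply(seq_along(pos), function(k) {
    ex <- genes$exons[[gi[k]]]
    any(pos[k] >= ex[, 1] & pos[k] < ex[, 2])
  }, logical(1))
  expect_true(all(in_exon))
})

test_that("the wave front position converges to the true rate at high depth", {
  cfg <- simulation_config(n_genes = 10, gene_length_range = c(35000, 60000),
                           rate_model = rate_constant(3), depth = 1e4,
                           background = 0, seed = 17)
  genes <- simulate_annotation(cfg)
  truth <- simulate_truth(genes, cfg)
  fr <- simulate_wave(genes, truth, 5, cfg)
  gi <- match(fr$gene_id, genes$gene_id)
  off <- ifelse(genes$strand[gi] == "+",
                fr$start - genes$tss[gi],
                genes$tss[gi] - 1 - (fr$end - 1))
  front <- tapply(off, fr$gene_id, max) / 5  # bp per minute
  expect_true(all(abs(front - 3000) / 3000 < 0.02))
})

test_that("count tables encode the spike-in design and known m6A enrichments", {
  cfg <- simulation_config(n_genes = 50, spike_in_true_factor = 1,
                           m6a_model = m6a_constant(1), seed = 21)
  genes <- simulate_annotation(cfg)
  truth <- simulate_truth(genes, cfg)
  ct <- simulate_count_tables(genes, truth, cfg)
  # factor 1: mouse/human total ratios agree across conditions (Poisson noise)
  ratios <- ct$ledger |>
    mutate(r = mouse_reads / human_reads) |>
    group_by(condition) |>
    summarise(r = mean(r), .groups = "drop")
  expect_lt(abs(diff(ratios$r)) / mean(ratios$r), 0.05)
  # null enrichment: depth-normalized IP/input ratios close to 1 on average
  lv <- m6a_level(ct$merip, ct$merip_totals)
  expect_lt(abs(mean(lv$level, na.rm = TRUE) - 1), 0.05)
})

test_that("emitted files round-trip through the pipeline readers", {
  cfg <- simulation_config(n_genes = 10, seed = 23)
  genes <- simulate_annotation(cfg)
  truth <- simulate_truth(genes, cfg)
  fr <- simulate_wave(genes, truth, 5, cfg)

  tsv <- tempfile(fileext = ".tsv")
  write_fragments(fr, tsv)
  expect_equal(as.data.frame(read_fragments(tsv)), as.data.frame(fr))

  bg <- tempfile(fileext = ".bedGraph")
  write_bedgraph(fr, bg, bin_size = 200)
  tab <- readr::read_tsv(bg, col_names = c("chrom", "start", "end", "value"),
                         show_col_types = FALSE)
  expect_equal(sum(tab$value), nrow(fr))  # every fragment binned once
  expect_true(all(tab$end - tab$start == 200))

  ct <- simulate_count_tables(genes, truth, cfg)
  lj <- tempfile(fileext = ".json")
  write_spike_ledger(ct$ledger, lj)
  expect_equal(as.data.frame(read_spike_ledger(lj)), as.data.frame(ct$ledger))

  gt <- tempfile(fileext = ".json")
  write_ground_truth(truth, gt)
  back <- read_ground_truth(gt)
  expect_equal(back$spike_factor, truth$spike_factor)
  expect_equal(back$genes$true_rate, truth$genes$true_rate)
})
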
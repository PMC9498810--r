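test_that("fragments land in the bin of their 5'-most position, strand-oriented", {
  g <- make_gene("g1", strand = "+", start = 1000, length = 20000)
  fr <- tibble(chrom = "chr1", start = c(1150, 1180), end = c(1225, 1255),
               gene_id = "g1")
  tr <- bin_coverage(fr, g, bin_size = 100, total_reads = 10)
  expect_equal(tr$count[tr$bin == 1], 2)
  expect_equal(tr$coverage[tr$bin == 1], 2 / 10)
  expect_equal(sum(tr$count), 2)
  expect_equal(nrow(tr), 200)  # ceil(extent / bin_size) bins

  # empty fragment set: all-zero track, not an error
  z <- bin_coverage(fr[0, ], g, bin_size = 100, total_reads = 10)
  expect_true(all(z$count == 0))

  # mirrored fragments on a minus-strand gene give identical oriented bins
  gm <- make_gene("gm", strand = "-", start = 1000, length = 20000)  # tss 21000
  frm <- tibble(chrom = "chr1",
                start = c(21000 - 150 - 75, 21000 - 180 - 75),
                end = c(21000 - 150, 21000 - 180), gene_id = "gm")
  trm <- bin_coverage(frm, gm, bin_size = 100, total_reads = 10)
  expect_equal(trm$count, tr$count)
})

test_that("wave signal subtracts the control, masks exons, and smooths", {
  g <- make_gene("g1", strand = "+", start = 0, length = 4000)
  mk <- function(cov) tibble(gene_id = "g1", bin = 0:19,
                             count = cov, coverage = cov)
  # identical tracks cancel
  s <- wave_signal(mk(rep(2, 20)), mk(rep(2, 20)), smooth_bins = 1)
  expect_true(all(s$signal == 0))

  # a clean step passes through unsmoothed
  step <- c(rep(1, 10), rep(0, 10))
  s <- wave_signal(mk(step), mk(rep(0, 20)), smooth_bins = 1)
  expect_equal(s$signal, step)

  # an exonic spike present only in the control is removed by
  # subtraction; one in the release track is removed by masking
  spike <- rep(0, 20); spike[16] <- 5  # bin 15 (0-based)
  s <- wave_signal(mk(step), mk(spike), smooth_bins = 1)
  expect_equal(s$signal, step)
  s <- wave_signal(mk(step + spike), mk(rep(0, 20)),
                   exon_mask = tibble(gene_id = "g1", bin = 15L),
                   smooth_bins = 1)
  expect_equal(s$signal, step)  # imputed from flat zero neighbors

  # masked bin with no unmasked neighbor within 5 bins falls back to 0
  s <- wave_signal(mk(step + spike), mk(rep(0, 20)),
                   exon_mask = tibble(gene_id = "g1", bin = 10:20),
                   smooth_bins = 1)
  expect_equal(s$signal[16], 0)

  expect_error(wave_signal(mk(step), mk(rep(0, 20))[1:10, ]), "geometry")
})

test_that("changepoint detection finds step boundaries and rejects flat signals", {
  step <- c(rep(1, 75), rep(0, 75))
  expect_equal(detect_boundary(step, 200), 15000)
  expect_equal(boundary_oracle(step, 200), 15000)

  expect_true(is.na(detect_boundary(rep(1, 50), 200)))   # flat nonzero
  expect_true(is.na(detect_boundary(rep(0, 50), 200)))   # all zero
  # contrast gate: a shallow step (left mean <= 2x right mean) is rejected
  expect_true(is.na(detect_boundary(c(rep(1.5, 40), rep(1, 40)), 200)))
  expect_error(detect_boundary(rep(1, 5), 200), "10 bins")
})

test_that("changepoint detector agrees with the exhaustive-search oracle", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(10:300, 1)
    x <- switch(sample(3, 1),
      runif(n),                                              # pure noise
      {k <- sample(n - 1, 1)
       c(runif(k, 1, 2), runif(n - k, 0, 1))},               # uniform step
      {k <- sample(n - 1, 1)
       c(rnorm(k, 1, 0.1), rnorm(n - k, 0, 0.1))})           # gaussian step
    expect_equal(detect_boundary(x, 200), boundary_oracle(x, 200))
  }
})

test_that("through-origin fit converts boundaries to kb/min", {
  expect_equal(estimate_rate(c("5" = 15000)), 3.0)
  expect_equal(estimate_rate(c("5" = 10000, "15" = 30000)), 2.0)
  expect_equal(estimate_rate(c("5" = 2400)), 0.48)
  expect_true(is.na(estimate_rate(c("5" = NA))))
  # closed form sum(t b)/sum(t^2) for unequal residuals
  expect_equal(estimate_rate(c("5" = 12000, "15" = 30000)),
               (5 * 12000 + 15 * 30000) / (25 + 225) / 1000)
  # intercept fit matches the OLS slope over the anchored points
  tt <- c(0, 5, 15); bb <- c(0, 11000, 31000)
  expect_equal(estimate_rate(c("5" = 11000, "15" = 31000), intercept = TRUE),
               stats::cov(tt, bb) / stats::var(tt) / 1000, tolerance = 1e-9)
})

test_that("QC filters flag genes independently and a rate at the cutoff is excluded", {
  genes <- bind_rows(lapply(1:10, function(i)
    make_gene(sprintf("g%02d", i), start = i * 1e5,
              length = if (i == 1) 15000 else 30000)))
  est <- tibble(
    gene_id = genes$gene_id,
    rate_kb_min = c(3, 3, 0.4, 3, 3, 3, 3, 3, 3, 3),
    coverage_20kb = c(10, 0.2, 10, 10, 10, 10, 10, 10, 10, 10)
  )
  other <- tibble(gene_id = genes$gene_id[-4],
                  rate_kb_min = rep(3, 9))  # g04 absent in other condition
  out <- apply_rate_filters(est, genes, other_rates = other)
  expect_equal(sum(out$retained), 6)
  expect_match(out$qc[1], "too_short")
  expect_match(out$qc[2], "low_coverage")
  expect_match(out$qc[3], "too_slow")
  expect_match(out$qc[4], "missing_in_other_condition")

  # "<= 0.5" is exclusive of retention: exactly 0.5 kb/min is dropped
  est2 <- est |> mutate(rate_kb_min = replace(rate_kb_min, 5, 0.5))
  out2 <- apply_rate_filters(est2, genes)
  expect_match(out2$qc[5], "too_slow")
  out3 <- apply_rate_filters(est |> mutate(rate_kb_min =
                                             replace(rate_kb_min, 5, 0.501)),
                             genes)
  expect_false(grepl("too_slow", out3$qc[5]))
})

test_that("three-quantile speed classes split at type-7 tertiles with ties to lower", {
  cls <- assign_speed_groups(1:9)
  expect_equal(as.character(cls),
               rep(c("slow", "medium", "fast"), each = 3))
  expect_error(assign_speed_groups(rep(2, 10)), "degenerate")
  expect_error(assign_speed_groups(c(1, 2)), "at least 3")

  set.seed(8)
  r <- runif(100, 1, 5)
  sizes <- table(assign_speed_groups(r))
  expect_true(max(sizes) - min(sizes) <= 1)
  # class rate ranges are ordered slow < medium < fast
  expect_lt(max(r[assign_speed_groups(r) == "slow"]),
            min(r[assign_speed_groups(r) == "medium"]))
  expect_lt(max(r[assign_speed_groups(r) == "medium"]),
            min(r[assign_speed_groups(r) == "fast"]))
})

test_that("metagene profiles are strand-symmetric and pass uniform coverage through", {
  g <- make_gene("g1", strand = "+", start = 5000, length = 1000)
  fr <- tibble(chrom = "chr1", start = 5000 + seq(0, 980, 20) ,
               end = 5000 + seq(0, 980, 20) + 75, gene_id = "g1")
  prof <- metagene_profile(fr, g, upstream = 0, downstream = 1000,
                           bin_size = 20, total_reads = 1)
  expect_equal(nrow(prof), 50)
  expect_true(all(prof$coverage == 1))

  gm <- make_gene("gm", strand = "-", start = 5000, length = 1000)  # tss 6000
  frm <- tibble(chrom = "chr1", start = 6000 - seq(0, 980, 20) - 75,
                end = 6000 - seq(0, 980, 20), gene_id = "gm")
  profm <- metagene_profile(frm, gm, upstream = 0, downstream = 1000,
                            bin_size = 20, total_reads = 1)
  expect_equal(profm$coverage, prof$coverage)

  # genes shorter than the window contribute only their covered bins
  both <- bind_rows(g, make_gene("g2", start = 50000, length = 400))
  prof2 <- metagene_profile(fr, both, upstream = 0, downstream = 1000,
                            bin_size = 20, total_reads = 1)
  expect_equal(prof2$n_genes[prof2$position < 400], rep(2, 20))
  expect_equal(prof2$n_genes[prof2$position >= 400], rep(1, 30))
})

test_that("rates are recovered exactly without noise and robustly with noise", {
  # noiseless: boundary within one bin of truth for every gene
  cfg <- simulation_config(n_genes = 20, gene_length_range = c(35000, 60000),
                           rate_model = rate_values(1:5), depth = 1e4,
                           background = 0, seed = 3)
  genes <- simulate_annotation(cfg)
  truth <- simulate_truth(genes, cfg)
  fit <- estimate_rates(simulate_timecourse(genes, truth, cfg), genes,
                        mask_exons = FALSE)
  est <- tidy(fit) |> left_join(truth$genes, by = "gene_id")
  expect_true(all(abs(est$rate_kb_min - est$true_rate) <= 200 / 5000))

  # noisy: median absolute error over 200 genes stays below 0.25 kb/min
  cfgn <- simulation_config(n_genes = 200, gene_length_range = c(30000, 60000),
                            rate_model = rate_values(seq(1, 5, length.out = 200)),
                            depth = 500, background = 50, seed = 4)
  gn <- simulate_annotation(cfgn)
  tn <- simulate_truth(gn, cfgn)
  en <- tidy(estimate_rates(simulate_timecourse(gn, tn, cfgn), gn)) |>
    left_join(tn$genes, by = "gene_id") |>
    filter(retained)
  expect_lte(median(abs(en$rate_kb_min - en$true_rate)), 0.25)
})

test_that("median estimated rate is monotone in the true rate", {
  grid <- 1:5
  med <- vapply(grid, function(v) {
    cfg <- simulation_config(n_genes = 50, gene_length_range = c(30000, 60000),
                             rate_model = rate_constant(v), depth = 500,
                             background = 50, seed = 100 + v)
    g <- simulate_annotation(cfg)
    tr <- simulate_truth(g, cfg)
    e <- tidy(estimate_rates(simulate_timecourse(g, tr, cfg), g))
    median(e$rate_kb_min[e$retained])
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("rate_fit provides tidy, glance, print and autoplot views", {
  cfg <- simulation_config(n_genes = 30, seed = 19)
  g <- simulate_annotation(cfg)
  tr <- simulate_truth(g, cfg)
  fit <- estimate_rates(simulate_timecourse(g, tr, cfg), g)
  td <- tidy(fit)
  expect_true(all(c("gene_id", "boundary_bp", "rate_kb_min", "qc",
                    "retained", "speed_class") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_genes, 30)
  expect_equal(gl$n_slow + gl$n_medium + gl$n_fast, gl$n_retained)
  expect_output(print(fit), "rate_fit")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_class_boxplot(td |> filter(retained), "rate_kb_min"),
                  "ggplot")
})
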
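#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' reproduce the study design the package targets: a DRB release with
#' nascent-RNA labeling at 0 and 5 min after release, a 10-min 4sU pulse
#' (so the 5-min wave is labeled over its whole extent), two biological
#' replicates, two conditions (wild-type-like and H1-triple-knockout-like),
#' genes of 30-60 kb, a bimodal per-gene elongation-rate distribution with
#' modes at 2.0 and 3.5 kb/min, 2000 expected labeled fragments per gene
#' and time point, and 100 expected exon-restricted mature-RNA background
#' fragments per gene.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Length-2 vector, gene length bounds in bp
#'   (uniform draw). Lower bound below 1 kb is an error.
#' @param rate_model Per-gene true elongation-rate model; see
#'   [rate_constant()], [rate_bimodal()], [rate_values()].
#' @param time_points Minutes after DRB release at which coverage is
#'   simulated; must include 0 (the unreleased control).
#' @param label_window Duration of the 4sU pulse in minutes; labeled signal
#'   covers the trailing `label_window` minutes of polymerization.
#' @param depth Expected labeled fragments per gene per positive time point.
#' @param background Expected exonic mature-RNA fragments per gene per time
#'   point (present at all time points, including 0 min).
#' @param n_replicates Biological replicates per condition.
#' @param conditions Condition labels; the second is treated as the
#'   spike-in-corrected knockout-like condition.
#' @param spike_in_true_factor True value of the spike-in correction factor
#'   that the dual-genome ledger should recover downstream.
#' @param m6a_model Per-gene true IP/input enrichment model; see
#'   [m6a_constant()], [m6a_levels()], [m6a_lognormal()].
#' @param m6a_tko_log2_shift Global log2 shift applied to knockout-like
#'   m6A enrichments relative to wild-type-like truth (0 = null).
#' @param chip_depth Expected total mouse-aligned ChIP reads per
#'   wild-type-like sample.
#' @param spike_fraction Human spike-in chromatin fraction (1/20 as in a
#'   1:20 spike).
#' @param cherna_depth Expected total aligned chromatin-RNA reads per sample.
#' @param merip_depth Expected total aligned reads per MeRIP IP and input
#'   library.
#' @param fragment_length Simulated fragment length in bp.
#' @param genes_per_chrom Genes placed per synthetic chromosome.
#' @param intergenic_gap Gap between consecutive genes in bp.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 300,
                              gene_length_range = c(30000, 60000),
                              rate_model = rate_bimodal(),
                              time_points = c(0, 5),
                              label_window = 10,
                              depth = 2000,
                              background = 100,
                              n_replicates = 2,
                              conditions = c("WT", "TKO"),
                              spike_in_true_factor = 1,
                              m6a_model = m6a_lognormal(),
                              m6a_tko_log2_shift = 0,
                              chip_depth = 1e6,
                              spike_fraction = 1 / 20,
                              cherna_depth = 1e6,
                              merip_depth = 1e5,
                              fragment_length = 75,
                              genes_per_chrom = 50,
                              intergenic_gap = 10000,
                              seed = 1) {
  if (n_genes <= 0) abort("n_genes must be > 0")
  if (length(gene_length_range) != 2 || gene_length_range[1] < 1000 ||
      gene_length_range[2] < gene_length_range[1])
    abort("gene_length_range must be increasing with lower bound >= 1 kb")
  if (!0 %in% time_points) abort("time_points must include the 0-min control")
  if (any(time_points < 0) || label_window <= 0)
    abort("time points and label_window must be non-negative")
  if (depth <= 0 || background < 0 || n_replicates <= 0 ||
      chip_depth <= 0 || cherna_depth <= 0 || merip_depth <= 0)
    abort("depths and replicate counts must be positive")
  if (spike_in_true_factor <= 0) abort("spike_in_true_factor must be > 0")
  structure(list(
    n_genes = as.integer(n_genes),
    gene_length_range = gene_length_range,
    rate_model = rate_model,
    time_points = sort(unique(time_points)),
    label_window = label_window,
    depth = depth,
    background = background,
    n_replicates = as.integer(n_replicates),
    conditions = conditions,
    spike_in_true_factor = spike_in_true_factor,
    m6a_model = m6a_model,
    m6a_tko_log2_shift = m6a_tko_log2_shift,
    chip_depth = chip_depth,
    spike_fraction = spike_fraction,
    cherna_depth = cherna_depth,
    merip_depth = merip_depth,
    fragment_length = as.integer(fragment_length),
    genes_per_chrom = as.integer(genes_per_chrom),
    intergenic_gap = as.integer(intergenic_gap),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Rate and enrichment models for the generator
#'
#' `rate_constant()` gives every gene the same true speed; `rate_values()`
#' recycles an explicit vector over genes in order; `rate_bimodal()` draws
#' from a two-component log-normal mixture parameterized by its modes,
#' emulating a slow (~2.0 kb/min) and a fast (~3.5 kb/min) transcription
#' class. `m6a_constant()`, `m6a_levels()` and `m6a_lognormal()` are the
#' analogous models for true per-gene m6A IP/input enrichments
#' (`m6a_levels()` assigns values block-wise in gene order, giving known
#' enrichment groups).
#'
#' @param value Single true value.
#' @param values Vector of true values, recycled over genes.
#' @param modes Modes of the two log-normal components, kb/min.
#' @param weights Mixture weights, summing to 1.
#' @param sdlog Log-scale spread of each component.
#' @param meanlog Log-scale mean for `m6a_lognormal()`.
#' @return A model specification list consumed by [simulate_truth()].
#' @name generator_models
NULL

#' @rdname generator_models
#' @export
rate_constant <- function(value) {
  stopifnot(value > 0)
  list(type = "constant", value = value)
}

#' @rdname generator_models
#' @export
rate_values <- function(values) {
  stopifnot(all(values > 0))
  list(type = "values", values = values)
}

#' @rdname generator_models
#' @export
rate_bimodal <- function(modes = c(2.0, 3.5), weights = c(1 / 3, 2 / 3),
                         sdlog = 0.2) {
  stopifnot(length(modes) == 2, all(modes > 0), sum(weights) > 0)
  list(type = "bimodal", modes = modes, weights = weights / sum(weights),
       sdlog = sdlog)
}

#' @rdname generator_models
#' @export
m6a_constant <- function(value = 1) list(type = "constant", value = value)

#' @rdname generator_models
#' @export
m6a_levels <- function(values = c(0.5, 1, 2, 4)) {
  stopifnot(all(values > 0))
  list(type = "levels", values = values)
}

#' @rdname generator_models
#' @export
m6a_lognormal <- function(meanlog = 0, sdlog = 0.3) {
  list(type = "lognormal", meanlog = meanlog, sdlog = sdlog)
}

draw_model <- function(model, n) {
  switch(model$type,
    constant = rep(model$value, n),
    values = rep_len(model$values, n),
    levels = {
      # contiguous blocks of equal truth, in gene order
      k <- length(model$values)
      model$values[ceiling(seq_len(n) / (n / k))]
    },
    bimodal = {
      comp <- sample.int(2, n, replace = TRUE, prob = model$weights)
      # log-normal parameterized by its mode: mu = log(mode) + sdlog^2
      rlnorm(n, meanlog = log(model$modes[comp]) + model$sdlog^2,
             sdlog = model$sdlog)
    },
    lognormal = rlnorm(n, model$meanlog, model$sdlog),
    abort(paste0("unknown model type: ", model$type))
  )
}

#' Simulate a gene annotation
#'
#' Places `n_genes` non-overlapping genes on synthetic chromosomes
#' (`genes_per_chrom` per chromosome, separated by `intergenic_gap`),
#' with lengths uniform in `gene_length_range`, random strand, and 2-10
#' exons per gene whose first and last blocks touch the gene ends (valid
#' BED12 structure). Deterministic under `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A gene-model table (see [read_annotation()]).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  lens <- round(runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom_idx <- (seq_len(n) - 1) %/% cfg$genes_per_chrom + 1
  starts <- numeric(n)
  pos <- cfg$intergenic_gap
  for (i in seq_len(n)) {
    if (i > 1 && chrom_idx[i] != chrom_idx[i - 1]) pos <- cfg$intergenic_gap
    starts[i] <- pos
    pos <- pos + lens[i] + cfg$intergenic_gap
  }
  exons <- map2(starts, lens, simulate_exons)
  tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = paste0("chrS", chrom_idx),
    strand = strand,
    tss = ifelse(strand == "+", starts, starts + lens),
    tts = ifelse(strand == "+", starts + lens, starts),
    length = lens,
    exons = exons,
    n_exons = vapply(exons, nrow, integer(1))
  )
}

simulate_exons <- function(start, len) {
  n_ex <- sample(2:max(2, min(10, len %/% 3000)), 1)
  w <- round(runif(n_ex, 200, 1500))
  cap <- 0.3 * len  # keep exonic fraction modest: mature background stays sparse
  if (sum(w) > cap) w <- pmax(50, round(w * cap / sum(w)))
  intron_total <- len - sum(w)
  gi <- rep(intron_total %/% (n_ex - 1), n_ex - 1)
  gi[n_ex - 1] <- intron_total - sum(gi[-(n_ex - 1)])
  off_start <- cumsum(c(0, head(w, -1) + gi))
  cbind(start = start + off_start, end = start + off_start + w)
}

#' Simulate per-gene ground truth
#'
#' Draws the hidden quantities every downstream estimator is tested
#' against: true elongation rate (kb/min), relative expression, promoter
#' and gene-body RNAPII occupancy (promoter = body times a log-normal
#' pausing multiplier), and per-condition true m6A IP/input enrichment.
#'
#' @param genes Gene-model table from [simulate_annotation()].
#' @param cfg A [simulation_config()].
#' @return List with `genes` (tibble keyed like the annotation: `gene_id`,
#'   `true_rate`, `expression`, `body_occ`, `promoter_occ`, `m6a_wt`,
#'   `m6a_tko`) and `spike_factor` (the true Eq.-style correction factor).
#' @export
simulate_truth <- function(genes, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(genes)
  expression <- rlnorm(n, 0, 0.5)
  body_occ <- rlnorm(n, 0, 0.5)
  pausing <- rlnorm(n, log(3), 0.5)
  m6a_wt <- draw_model(cfg$m6a_model, n)
  list(
    genes = tibble(
      gene_id = genes$gene_id,
      true_rate = draw_model(cfg$rate_model, n),
      expression = expression,
      body_occ = body_occ,
      promoter_occ = body_occ * pausing,
      m6a_wt = m6a_wt,
      m6a_tko = m6a_wt * 2^cfg$m6a_tko_log2_shift
    ),
    spike_factor = cfg$spike_in_true_factor
  )
}

#' Simulate nascent-RNA wave fragments for one time point
#'
#' Models the post-DRB transcription wave with a sharp front and uniform
#' occupancy behind it: at `t` minutes after release, the 4sU-labeled
#' fragment 5' ends of gene `g` are uniform on
#' `[TSS + max(0, v_g (t - label_window)) kb, TSS + v_g t kb)` clipped to
#' the gene body, with Poisson-distributed counts of mean `cfg$depth`. An
#' independent exon-restricted background of mean `cfg$background`
#' fragments per gene (mature-RNA contamination) is added at every time
#' point; at `t = 0` only background is emitted. Deterministic given
#' `cfg$seed`, `t`, `replicate` and `condition`.
#'
#' @param genes Gene-model table.
#' @param truth Ground truth from [simulate_truth()].
#' @param t Time point in minutes; must be in `cfg$time_points`.
#' @param cfg A [simulation_config()].
#' @param replicate,condition Sample labels (alter the random stream).
#' @return Fragment tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `gene_id`, `time_point`, `replicate`, `condition`, `origin`
#'   (`"signal"`/`"background"`).
#' @export
simulate_wave <- function(genes, truth, t, cfg, replicate = 1,
                          condition = "WT") {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!t %in% cfg$time_points)
    abort(sprintf("time point %s not in cfg$time_points", t))
  cond_i <- match(condition, cfg$conditions)
  if (is.na(cond_i)) abort(paste0("unknown condition: ", condition))
  set.seed(cfg$seed + 100000L * as.integer(round(t * 10)) +
             1000L * as.integer(replicate) + 10L * cond_i)
  tr <- truth$genes[match(genes$gene_id, truth$genes$gene_id), ]

  sig <- NULL
  if (t > 0) {
    lo <- pmax(0, tr$true_rate * (t - cfg$label_window)) * 1000
    hi <- pmin(tr$true_rate * t * 1000, genes$length)
    n_sig <- rpois(nrow(genes), ifelse(hi > lo, cfg$depth, 0))
    idx <- rep.int(seq_len(nrow(genes)), n_sig)
    off <- floor(runif(length(idx), lo[idx], hi[idx]))
    sig <- fragment_rows(genes, idx, off, cfg$fragment_length, "signal")
  }

  bg <- NULL
  if (cfg$background > 0) {
    n_bg <- rpois(nrow(genes), cfg$background)
    idx <- rep.int(seq_len(nrow(genes)), n_bg)
    off <- exonic_offsets(genes, idx)
    bg <- fragment_rows(genes, idx, off, cfg$fragment_length, "background")
  }

  out <- bind_rows(sig, bg)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  gene_id = character(), origin = character())
  }
  out |>
    mutate(time_point = t, replicate = as.integer(replicate),
           condition = condition) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
}

# offsets are bp from the TSS in transcription direction; convert to a
# genomic fragment whose 5'-most base (in transcription direction) is there
fragment_rows <- function(genes, idx, off, flen, origin) {
  if (length(idx) == 0) return(NULL)
  plus <- genes$strand[idx] == "+"
  pos <- ifelse(plus, genes$tss[idx] + off, genes$tss[idx] - 1 - off)
  start <- ifelse(plus, pos, pmax(0, pos - flen + 1))
  end <- ifelse(plus, pos + flen, pos + 1)
  tibble(chrom = genes$chrom[idx], start = start, end = end,
         gene_id = genes$gene_id[idx], origin = origin)
}

# uniform over exonic bases, expressed as offsets from the TSS in
# transcription direction
exonic_offsets <- function(genes, idx) {
  if (length(idx) == 0) return(numeric(0))
  vapply(idx, function(i) {
    ex <- genes$exons[[i]]
    w <- ex[, 2] - ex[, 1]
    j <- sample.int(nrow(ex), 1, prob = w)
    p <- floor(runif(1, ex[j, 1], ex[j, 2]))
    if (genes$strand[i] == "+") p - genes$tss[i] else genes$tss[i] - 1 - p
  }, numeric(1))
}

#' Simulate ChIP, CheRNA and MeRIP count tables with a spike-in ledger
#'
#' Emits Poisson read-count tables around the ground truth for every
#' condition and replicate: RNAPII ChIP counts over promoter (TSS±500 bp)
#' and gene body, chromatin-RNA (CheRNA) counts, MeRIP IP and input
#' counts over the extended transcript, and the dual-genome spike-in
#' ledger. Knockout-like mouse totals are scaled by
#' `1 / spike_in_true_factor` so that the spike-in correction factor
#' computed downstream recovers `cfg$spike_in_true_factor`. IP libraries
#' are generated at the calibrated depth recorded in `merip_totals`, so
#' depth-normalized IP/input ratios estimate the true per-gene enrichment.
#'
#' @param genes Gene-model table.
#' @param truth Ground truth from [simulate_truth()].
#' @param cfg A [simulation_config()].
#' @return List of tibbles: `chip` (`gene_id`, `condition`, `replicate`,
#'   `promoter_count`, `body_count`), `ledger` (`condition`, `replicate`,
#'   `mouse_reads`, `human_reads`), `cherna` (+ `count`), `cherna_totals`,
#'   `merip` (`ip_count`, `input_count`), `merip_totals`.
#' @export
simulate_count_tables <- function(genes, truth, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 2L)
  tr <- truth$genes[match(genes$gene_id, truth$genes$gene_id), ]
  n <- nrow(genes)
  f <- truth$spike_factor
  occ_tot <- sum(tr$promoter_occ + tr$body_occ)
  expr_share <- tr$expression / sum(tr$expression)

  samples <- tidyr::expand_grid(condition = cfg$conditions,
                                replicate = seq_len(cfg$n_replicates))
  chip <- list(); cherna <- list(); merip <- list()
  ledger <- list(); cherna_totals <- list(); merip_totals <- list()
  for (k in seq_len(nrow(samples))) {
    cond <- samples$condition[k]; rep_i <- samples$replicate[k]
    is_tko <- cond != cfg$conditions[1]
    mouse_nominal <- cfg$chip_depth * if (is_tko) 1 / f else 1
    human_nominal <- cfg$chip_depth * cfg$spike_fraction
    ledger[[k]] <- tibble(condition = cond, replicate = rep_i,
                          mouse_reads = rpois(1, mouse_nominal),
                          human_reads = rpois(1, human_nominal))
    chip[[k]] <- tibble(
      gene_id = genes$gene_id, condition = cond, replicate = rep_i,
      promoter_count = rpois(n, tr$promoter_occ / occ_tot * mouse_nominal),
      body_count = rpois(n, tr$body_occ / occ_tot * mouse_nominal)
    )
    cherna[[k]] <- tibble(
      gene_id = genes$gene_id, condition = cond, replicate = rep_i,
      count = rpois(n, expr_share * cfg$cherna_depth)
    )
    cherna_totals[[k]] <- tibble(condition = cond, replicate = rep_i,
                                 total_reads = cfg$cherna_depth)
    m6a <- if (is_tko) tr$m6a_tko else tr$m6a_wt
    merip[[k]] <- tibble(
      gene_id = genes$gene_id, condition = cond, replicate = rep_i,
      ip_count = rpois(n, expr_share * m6a * cfg$merip_depth),
      input_count = rpois(n, expr_share * cfg$merip_depth)
    )
    merip_totals[[k]] <- tibble(condition = cond, replicate = rep_i,
                                ip_total = cfg$merip_depth,
                                input_total = cfg$merip_depth)
  }
  list(chip = bind_rows(chip), ledger = bind_rows(ledger),
       cherna = bind_rows(cherna), cherna_totals = bind_rows(cherna_totals),
       merip = bind_rows(merip), merip_totals = bind_rows(merip_totals))
}

#' Fragment-table and bedGraph input/output
#'
#' `write_fragments()`/`read_fragments()` round-trip the tidy fragment
#' table as TSV. `write_bedgraph()` aggregates fragment 5' starts into
#' fixed genomic bins and writes 4-column bedGraph.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`, `gene_id`, ...).
#' @param path File path.
#' @param bin_size Genomic bin width in bp for bedGraph output.
#' @return `path` (writers, invisibly) or the fragment tibble (reader).
#' @name fragment_io
NULL

#' @rdname fragment_io
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(fragments, path)
  invisible(path)
}

#' @rdname fragment_io
#' @export
read_fragments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname fragment_io
#' @export
write_bedgraph <- function(fragments, path, bin_size = 200) {
  fragments |>
    mutate(bin = floor(.data$start / bin_size)) |>
    count(.data$chrom, .data$bin) |>
    transmute(.data$chrom, start = .data$bin * bin_size,
              end = (.data$bin + 1) * bin_size, value = .data$n) |>
    arrange(.data$chrom, .data$start) |>
    readr::write_tsv(path, col_names = FALSE)
  invisible(path)
}

#' Spike-in ledger and ground-truth JSON input/output
#'
#' @param ledger Spike-in ledger tibble (`condition`, `replicate`,
#'   `mouse_reads`, `human_reads`).
#' @param truth Ground-truth list from [simulate_truth()].
#' @param path File path.
#' @return `path` (writers, invisibly) or the reconstructed object (readers).
#' @name ledger_io
NULL

#' @rdname ledger_io
#' @export
write_spike_ledger <- function(ledger, path) {
  jsonlite::write_json(ledger, path, digits = NA)
  invisible(path)
}

#' @rdname ledger_io
#' @export
read_spike_ledger <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname ledger_io
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(genes = truth$genes,
                            spike_factor = truth$spike_factor),
                       path, digits = NA)
  invisible(path)
}

#' @rdname ledger_io
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(genes = as_tibble(x$genes), spike_factor = x$spike_factor)
}
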
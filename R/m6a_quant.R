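#' Per-gene m6A level from IP and input counts
#'
#' m6A methylation level of chromatin-associated RNA, per gene and
#' condition: each replicate's IP and input counts over the extended
#' transcript interval (TSS−2 kb to TTS+2 kb) are depth-normalized by
#' their library totals; the level is the replicate mean of the
#' IP/input ratio. Genes lacking data (missing row or `NA` count) in any
#' replicate of a condition are excluded (level `NA`), as are replicates
#' with zero input signal.
#'
#' @param merip Tibble `gene_id`, `condition`, `replicate`, `ip_count`,
#'   `input_count`.
#' @param totals Tibble `condition`, `replicate`, `ip_total`,
#'   `input_total` (> 0).
#' @return Tibble `gene_id`, `condition`, `ip_signal`, `input_signal`
#'   (replicate-mean depth-normalized signals), `level`,
#'   `n_replicates_used`.
#' @export
m6a_level <- function(merip, totals) {
  if (any(totals$ip_total <= 0) || any(totals$input_total <= 0))
    abort("library totals must be > 0")
  n_rep <- totals |>
    group_by(.data$condition) |>
    summarise(n_rep = dplyr::n_distinct(.data$replicate), .groups = "drop")
  merip |>
    inner_join(totals, by = c("condition", "replicate")) |>
    mutate(ip_sig = .data$ip_count / .data$ip_total,
           input_sig = .data$input_count / .data$input_total,
           rep_level = ifelse(.data$input_sig > 0,
                              .data$ip_sig / .data$input_sig, NA_real_)) |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(ip_signal = mean(.data$ip_sig),
              input_signal = mean(.data$input_sig),
              level = mean(.data$rep_level),
              n_replicates_used = sum(!is.na(.data$ip_count) &
                                        !is.na(.data$input_count)),
              .groups = "drop") |>
    inner_join(n_rep, by = "condition") |>
    mutate(level = ifelse(.data$n_replicates_used == .data$n_rep,
                          .data$level, NA_real_)) |>
    select(-"n_rep")
}

#' Cross-condition m6A log2 ratio
#'
#' `log2(tko_level / wt_level)` per gene, joining two condition tables
#' from [m6a_level()]; genes with undefined or zero level in either
#' condition are excluded.
#'
#' @param tko,wt [m6a_level()] tables for the knockout-like and reference
#'   conditions.
#' @return Tibble `gene_id`, `level_tko`, `level_wt`, `log2_ratio`.
#' @export
m6a_condition_ratio <- function(tko, wt) {
  inner_join(
    tko |> select("gene_id", level_tko = "level"),
    wt |> select("gene_id", level_wt = "level"),
    by = "gene_id"
  ) |>
    filter(!is.na(.data$level_tko), !is.na(.data$level_wt),
           .data$level_tko > 0, .data$level_wt > 0) |>
    mutate(log2_ratio = log2(.data$level_tko / .data$level_wt))
}

#' m6A change across quartiles of promoter-proximal histone H1
#'
#' Splits genes into four quartiles of H1 occupancy (type-7 quantiles,
#' boundary ties to the lower quartile) and reports, per quartile, the
#' median cross-condition log2 m6A ratio together with the one-sample
#' Wilcoxon signed-rank test of the ratios against 0. An all-zero
#' quartile is degenerate and reported with p = 1 by convention; an empty
#' quartile (degenerate quantiles) is an error.
#'
#' @param data Tibble with one row per gene.
#' @param h1_col Column holding promoter-proximal H1 occupancy.
#' @param ratio_col Column holding the log2 condition ratio.
#' @return Tibble `quartile` (1 = lowest H1), `n`, `median_ratio`,
#'   `statistic`, `p_value`.
#' @export
h1_quartile_ratio_analysis <- function(data, h1_col = "h1_occupancy",
                                       ratio_col = "log2_ratio") {
  d <- data |>
    filter(!is.na(.data[[h1_col]]), !is.na(.data[[ratio_col]]))
  if (nrow(d) < 8)
    abort("h1_quartile_ratio_analysis needs at least 8 complete genes")
  br <- quantile(d[[h1_col]], probs = seq(0, 1, 0.25), type = 7,
                 names = FALSE)
  if (anyDuplicated(br)) abort("degenerate H1 quantiles: empty quartile")
  d$quartile <- as.integer(cut(d[[h1_col]], breaks = br,
                               include.lowest = TRUE, right = TRUE))
  d |>
    group_by(.data$quartile) |>
    summarise(
      n = dplyr::n(),
      median_ratio = median(.data[[ratio_col]]),
      test = list(one_sample_wilcoxon(.data[[ratio_col]])),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("test")
}

one_sample_wilcoxon <- function(x, mu = 0) {
  if (all(x == mu)) return(list(statistic = NA_real_, p_value = 1))
  w <- suppressWarnings(wilcox.test(x, mu = mu))
  list(statistic = unname(w$statistic), p_value = w$p.value)
}

#' Classify m6A peaks by TSS/TTS window
#'
#' Assigns each peak to a gene by overlap with the extended transcript
#' interval (TSS−2 kb to TTS+2 kb; the gene with the largest overlap wins,
#' ties to the lexicographically first gene id), then classifies it by
#' whether its midpoint falls in the TSS±2 kb window, the TTS±2 kb window,
#' both (short genes), or neither.
#'
#' @param peaks Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param genes Gene-model table.
#' @param halfwidth Window half-width around TSS/TTS in bp.
#' @return `peaks` with `assigned_gene` (`NA` if no overlap) and
#'   `window_class` (factor `TSS`/`TTS`/`both`/`neither`, `NA` for
#'   unassigned peaks).
#' @export
classify_peak_windows <- function(peaks, genes, halfwidth = 2000) {
  body <- gene_body(genes)
  g_ext <- GenomicRanges::GRanges(
    body$chrom,
    IRanges::IRanges(pmax(body$start - halfwidth, 0) + 1,
                     body$end + halfwidth))
  p_rng <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  hits <- GenomicRanges::findOverlaps(p_rng, g_ext)
  ov <- tibble(
    peak = S4Vectors::queryHits(hits),
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    width = IRanges::width(IRanges::pintersect(
      IRanges::ranges(p_rng)[S4Vectors::queryHits(hits)],
      IRanges::ranges(g_ext)[S4Vectors::subjectHits(hits)]))
  ) |>
    arrange(.data$peak, desc(.data$width), .data$gene_id) |>
    group_by(.data$peak) |>
    slice(1) |>
    ungroup()
  assigned <- rep(NA_character_, nrow(peaks))
  assigned[ov$peak] <- ov$gene_id
  gi <- match(assigned, genes$gene_id)
  mid <- floor((peaks$start + peaks$end) / 2)
  in_win <- function(anchor) {
    !is.na(gi) & mid >= anchor - halfwidth & mid < anchor + halfwidth
  }
  tss_hit <- in_win(genes$tss[gi])
  tts_hit <- in_win(genes$tts[gi])
  cls <- dplyr::case_when(
    is.na(gi) ~ NA_character_,
    tss_hit & tts_hit ~ "both",
    tss_hit ~ "TSS",
    tts_hit ~ "TTS",
    TRUE ~ "neither"
  )
  peaks |>
    mutate(assigned_gene = assigned,
           window_class = factor(cls,
                                 levels = c("TSS", "TTS", "both", "neither")))
}

#' Peak window fractions per speed class
#'
#' Summarizes [classify_peak_windows()] output per elongation speed class:
#' the fraction of assigned peaks whose midpoint falls in the TSS window,
#' the TTS window, both, or neither.
#'
#' @param peak_calls Output of [classify_peak_windows()].
#' @param speed_classes Tibble `gene_id`, `speed_class`.
#' @return Tibble `speed_class`, `n_peaks`, `frac_tss`, `frac_tts`,
#'   `frac_both`, `frac_neither`.
#' @export
peak_window_fractions <- function(peak_calls, speed_classes) {
  peak_calls |>
    filter(!is.na(.data$assigned_gene)) |>
    inner_join(speed_classes |> select(assigned_gene = "gene_id",
                                       "speed_class"),
               by = "assigned_gene") |>
    group_by(.data$speed_class) |>
    summarise(
      n_peaks = dplyr::n(),
      frac_tss = mean(.data$window_class %in% c("TSS", "both")),
      frac_tts = mean(.data$window_class %in% c("TTS", "both")),
      frac_both = mean(.data$window_class == "both"),
      frac_neither = mean(.data$window_class == "neither"),
      .groups = "drop"
    )
}
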
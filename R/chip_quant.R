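#' Dual-genome spike-in correction factor
#'
#' Computes, per replicate, the correction factor applied to the
#' knockout-like condition's read-normalized ChIP signal:
#' `factor = (mouse_WT / human_WT) / (mouse_TKO / human_TKO)`,
#' where the counts are total reads aligned to the mouse (experimental)
#' and human (spike-in) genomes. The spike-in-normalized signal is the
#' read-normalized signal multiplied by this factor.
#'
#' @param ledger Tibble `condition`, `replicate`, `mouse_reads`,
#'   `human_reads`, containing both conditions.
#' @param wt,tko Condition labels of the reference and corrected samples.
#' @return Tibble `replicate`, `spike_factor`.
#' @examples
#' ledger <- tibble::tibble(condition = c("WT", "TKO"), replicate = 1,
#'                          mouse_reads = c(100, 200), human_reads = 10)
#' spike_in_factor(ledger)  # 0.5
#' @export
spike_in_factor <- function(ledger, wt = "WT", tko = "TKO") {
  if (any(ledger$mouse_reads <= 0))
    abort("spike_in_factor: mouse read totals must be > 0")
  if (any(ledger$human_reads <= 0))
    abort("spike_in_factor: human (spike-in) read totals must be > 0")
  w <- ledger |> filter(.data$condition == wt)
  k <- ledger |> filter(.data$condition == tko)
  if (nrow(w) == 0 || nrow(k) == 0)
    abort("ledger must contain both conditions")
  inner_join(
    w |> transmute(.data$replicate,
                   wt_ratio = .data$mouse_reads / .data$human_reads),
    k |> transmute(.data$replicate,
                   tko_ratio = .data$mouse_reads / .data$human_reads),
    by = "replicate"
  ) |>
    transmute(.data$replicate,
              spike_factor = .data$wt_ratio / .data$tko_ratio)
}

#' Length- and depth-normalized region occupancy
#'
#' RPKM-style signal: `count / (region_len / 1000) / (total_reads / 1e6)`,
#' multiplied by an optional spike-in correction factor. Vectorized.
#'
#' @param count Reads in the region.
#' @param region_len Region length in bp (> 0).
#' @param total_reads Total aligned reads of the library (> 0).
#' @param factor Spike-in correction factor (1 = none).
#' @return Normalized signal (reads per kb per million reads).
#' @export
region_occupancy <- function(count, region_len, total_reads, factor = 1) {
  if (any(region_len <= 0)) abort("region_len must be > 0")
  if (any(total_reads <= 0)) abort("total_reads must be > 0")
  count / (region_len / 1000) / (total_reads / 1e6) * factor
}

#' RNAPII pausing index
#'
#' Ratio of RNAPII occupancy at the promoter (TSS±500 bp) to occupancy in
#' the gene body. Genes with zero body signal get `NA` (they cannot enter
#' downstream rank statistics). Vectorized.
#'
#' @param promoter,body Non-negative normalized signals.
#' @return `promoter / body`, `NA` where `body == 0`.
#' @export
pausing_index <- function(promoter, body) {
  if (any(promoter < 0, na.rm = TRUE) || any(body < 0, na.rm = TRUE))
    abort("pausing_index inputs must be non-negative")
  ifelse(body > 0, promoter / body, NA_real_)
}

#' Spike-in-corrected occupancy and pausing table
#'
#' Chains the module: per-replicate spike factors from the ledger (1 for
#' the reference condition), RPKM-style promoter (TSS±500 bp) and gene-body
#' (TSS+500 to TTS) occupancies normalized by the mouse-aligned totals,
#' replicate means per condition, and the promoter/body pausing index
#' computed from the replicate-mean signals.
#'
#' @param chip Tibble `gene_id`, `condition`, `replicate`,
#'   `promoter_count`, `body_count`.
#' @param ledger Spike-in ledger (see [spike_in_factor()]).
#' @param genes Gene-model table.
#' @param promoter_halfwidth Promoter half-width around the TSS in bp.
#' @param wt,tko Condition labels.
#' @return Tibble `gene_id`, `condition`, `promoter_signal`, `body_signal`
#'   (replicate means), `pausing_index`.
#' @export
pausing_table <- function(chip, ledger, genes, promoter_halfwidth = 500,
                          wt = "WT", tko = "TKO") {
  factors <- spike_in_factor(ledger, wt = wt, tko = tko) |>
    mutate(condition = tko) |>
    bind_rows(tibble(replicate = unique(ledger$replicate),
                     spike_factor = 1, condition = wt))
  totals <- ledger |> select("condition", "replicate", "mouse_reads")
  geom <- genes |>
    transmute(.data$gene_id,
              promoter_len = 2 * promoter_halfwidth,
              body_len = .data$length - promoter_halfwidth)
  chip |>
    inner_join(factors, by = c("condition", "replicate")) |>
    inner_join(totals, by = c("condition", "replicate")) |>
    inner_join(geom, by = "gene_id") |>
    filter(.data$body_len > 0) |>
    mutate(
      promoter_signal = region_occupancy(.data$promoter_count,
                                         .data$promoter_len,
                                         .data$mouse_reads,
                                         .data$spike_factor),
      body_signal = region_occupancy(.data$body_count, .data$body_len,
                                     .data$mouse_reads, .data$spike_factor)
    ) |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(promoter_signal = mean(.data$promoter_signal),
              body_signal = mean(.data$body_signal), .groups = "drop") |>
    mutate(pausing_index = pausing_index(.data$promoter_signal,
                                         .data$body_signal))
}

#' Chromatin-RNA transcriptional output
#'
#' Per-gene chromatin-enriched RNA output: reads normalized by library
#' total and transcript size (RPKM-style) per replicate, then averaged
#' across replicates within each condition.
#'
#' @param cherna Tibble `gene_id`, `condition`, `replicate`, `count`.
#' @param totals Tibble `condition`, `replicate`, `total_reads`.
#' @param genes Gene-model table (supplies transcript lengths).
#' @return Tibble `gene_id`, `condition`, `output`, `n_replicates`.
#' @export
cherna_output <- function(cherna, totals, genes) {
  cherna |>
    inner_join(totals, by = c("condition", "replicate")) |>
    inner_join(genes |> select("gene_id", "length"), by = "gene_id") |>
    mutate(rpkm = region_occupancy(.data$count, .data$length,
                                   .data$total_reads)) |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(output = mean(.data$rpkm),
              n_replicates = dplyr::n(), .groups = "drop")
}

#' Filter and trim mononucleosomal fragment pairs
#'
#' Keeps fragments delimited by read pairs mapping to the same chromosome
#' and spanning fewer than `max_span` bp (strict), trims `trim` bp from
#' both ends, and drops fragments whose trimmed length is not positive.
#'
#' @param pairs Tibble with `chrom` (or `chrom_1`/`chrom_2` for the two
#'   mates), `start`, `end` (0-based half-open outer fragment span).
#' @param max_span Maximum fragment span in bp (exclusive).
#' @param trim Bases removed from each fragment end.
#' @return Tibble `chrom`, `start`, `end` of trimmed fragments.
#' @export
mnase_fragment_filter <- function(pairs, max_span = 250, trim = 25) {
  if (all(c("chrom_1", "chrom_2") %in% names(pairs))) {
    pairs <- pairs |>
      filter(.data$chrom_1 == .data$chrom_2) |>
      mutate(chrom = .data$chrom_1)
  }
  pairs |>
    filter(.data$end - .data$start < max_span) |>
    transmute(.data$chrom, start = .data$start + trim,
              end = .data$end - trim) |>
    filter(.data$end - .data$start > 0)
}
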
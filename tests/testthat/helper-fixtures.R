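suppressMessages(library(dplyr))

# single-gene model row; default exons touch the gene ends (valid BED12)
make_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 1000, length = 20000, exons = NULL) {
  end <- start + length
  if (is.null(exons)) {
    exons <- cbind(start = c(start, end - 500), end = c(start + 500, end))
  }
  ne <- nrow(exons)
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tss = if (strand == "+") start else end,
    tts = if (strand == "+") end else start,
    length = length, exons = list(exons), n_exons = ne
  )
}

# independent exhaustive-search changepoint oracle: direct two-segment
# least squares with mean()/sum(), no shared code with detect_boundary()
boundary_oracle <- function(signal, bin_size) {
  n <- length(signal)
  if (all(signal == 0)) return(NA_real_)
  best_c <- NA_integer_
  best_cost <- Inf
  for (cp in 1:(n - 1)) {
    left <- signal[1:cp]
    right <- signal[(cp + 1):n]
    if (mean(left) <= mean(right)) next
    cost <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (cost <= best_cost) {  # ties: keep the largest changepoint
      best_cost <- cost
      best_c <- cp
    }
  }
  if (is.na(best_c)) return(NA_real_)
  left <- signal[1:best_c]
  right <- signal[(best_c + 1):n]
  if (!(mean(left) > 2 * mean(right))) return(NA_real_)
  best_c * bin_size
}

# pooled 0-min + release fragments for a simulation config
simulate_timecourse <- function(genes, truth, cfg) {
  bind_rows(lapply(cfg$time_points, function(t)
    simulate_wave(genes, truth, t, cfg)))
}
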
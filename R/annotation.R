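#' Read a gene annotation into a gene-model table
#'
#' Parses BED (6- or 12-column) or minimal GTF annotations into the tidy
#' gene-model table used throughout the package. All coordinates are stored
#' 0-based half-open (BED convention); GTF records (1-based closed) are
#' converted on read. The TSS is always the 5' end with respect to strand,
#' so for a minus-strand gene `tss > tts`.
#'
#' BED records that are malformed (fewer than 6 fields, non-numeric or
#' inverted coordinates, strand not `+`/`-`) are skipped with a message
#' reporting how many were dropped. A file with zero valid records is an
#' error.
#'
#' @param path Path to a BED or GTF file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return A tibble with one row per record: `gene_id`, `chrom`, `strand`,
#'   `tss`, `tts`, `length` (bp, `= abs(tts - tss)`), `exons` (list column
#'   of two-column matrices of 0-based half-open genomic intervals) and
#'   `n_exons`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t1000\t21000\tgA\t0\t+",
#'              "chr1\t40000\t70000\tgB\t0\t-"), bed)
#' read_annotation(bed)
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  genes <- if (format == "bed") read_bed_genes(path) else read_gtf_genes(path)
  if (nrow(genes) == 0) abort(paste0("no valid records in ", path))
  validate_gene_set(genes)
  genes
}

read_bed_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  fields <- strsplit(lines, "\t")
  ok <- vapply(fields, function(f) {
    length(f) >= 6 &&
      !is.na(suppressWarnings(s <- as.numeric(f[2]))) &&
      !is.na(suppressWarnings(e <- as.numeric(f[3]))) &&
      s >= 0 && e > s && f[6] %in% c("+", "-")
  }, logical(1))
  if (any(!ok)) {
    inform(sprintf("read_annotation: skipped %d malformed BED record(s)",
                   sum(!ok)))
  }
  if (!any(ok)) return(empty_gene_set())
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp))
  writeLines(lines[ok], tmp)
  gr <- rtracklayer::import(tmp, format = "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  exons <- if (!is.null(gr$blocks)) {
    map2(as.list(gr$blocks), start0, function(bl, s0) {
      cbind(start = s0 + IRanges::start(bl) - 1L, end = s0 + IRanges::end(bl))
    })
  } else {
    map2(start0, end0, function(s, e) cbind(start = s, end = e))
  }
  tibble(
    gene_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", start0, end0),
    tts = ifelse(strand == "+", end0, start0),
    length = end0 - start0,
    exons = exons,
    n_exons = vapply(exons, nrow, integer(1))
  )
}

read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  id <- gr$transcript_id %||% gr$gene_id
  if (is.null(id)) abort("GTF lacks transcript_id/gene_id attributes")
  ex <- gr[!is.na(id) & tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0) ex <- gr[!is.na(id)]
  ex_id <- (ex$transcript_id %||% ex$gene_id)
  ex_tbl <- tibble(
    gene_id = as.character(ex_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start0 = GenomicRanges::start(ex) - 1L,  # 1-based closed -> 0-based half-open
    end0 = GenomicRanges::end(ex)
  ) |>
    filter(.data$strand %in% c("+", "-"))
  ex_tbl |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    arrange(.data$start0, .by_group = TRUE) |>
    summarise(
      exons = list(cbind(start = .data$start0, end = .data$end0)),
      span_start = min(.data$start0), span_end = max(.data$end0),
      .groups = "drop"
    ) |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$span_start, .data$span_end),
      tts = ifelse(.data$strand == "+", .data$span_end, .data$span_start),
      length = .data$span_end - .data$span_start,
      n_exons = vapply(.data$exons, nrow, integer(1))
    ) |>
    select("gene_id", "chrom", "strand", "tss", "tts", "length",
           "exons", "n_exons")
}

empty_gene_set <- function() {
  tibble(gene_id = character(), chrom = character(), strand = character(),
         tss = numeric(), tts = numeric(), length = numeric(),
         exons = list(), n_exons = integer())
}

#' Validate a gene-model table
#'
#' Checks the structural invariants of a gene-model table: unique ids,
#' positive lengths, strand-consistent TSS/TTS, and exons that are sorted,
#' non-overlapping and contained in the gene span.
#'
#' @param genes A gene-model table as returned by [read_annotation()].
#' @return `genes`, invisibly; errors describe the first violated invariant.
#' @export
validate_gene_set <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "tss", "tts", "length", "exons")
  miss <- setdiff(req, names(genes))
  if (length(miss)) abort(paste0("gene table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(genes$gene_id)) abort("gene_id values are not unique")
  if (any(genes$length <= 0)) abort("gene length must be > 0")
  bad_strand <- (genes$strand == "+" & genes$tss >= genes$tts) |
    (genes$strand == "-" & genes$tss <= genes$tts)
  if (any(bad_strand)) abort("TSS must be the 5' end with respect to strand")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    lo <- min(genes$tss[i], genes$tts[i]); hi <- max(genes$tss[i], genes$tts[i])
    if (any(ex[, 1] >= ex[, 2]) || is.unsorted(ex[, 1]) ||
        any(ex[-1, 1, drop = TRUE] < ex[-nrow(ex), 2, drop = TRUE]) ||
        any(ex[, 1] < lo) || any(ex[, 2] > hi)) {
      abort(paste0("invalid exon structure for gene ", genes$gene_id[i]))
    }
  }
  invisible(genes)
}

#' Keep the longest transcript per gene
#'
#' Collapses a transcript-level model table to one model per gene, keeping
#' the transcript that maximizes length. Ties are broken deterministically
#' by the lexicographically smallest transcript id.
#'
#' @param genes Transcript-level gene-model table (ids in `gene_id` are
#'   transcript ids).
#' @param gene_key A tibble mapping `transcript_id` to `gene_id`; every
#'   transcript in `genes` must appear exactly once.
#' @return A gene-model table with one row per gene; `gene_id` holds the
#'   gene id and `transcript_id` records the transcript retained.
#' @export
keep_longest_transcript <- function(genes, gene_key) {
  if (nrow(gene_key) == 0) abort("empty transcript-to-gene mapping")
  if (!all(c("transcript_id", "gene_id") %in% names(gene_key)))
    abort("gene_key needs columns transcript_id and gene_id")
  unmapped <- setdiff(genes$gene_id, gene_key$transcript_id)
  if (length(unmapped))
    abort(paste0("transcript(s) missing from gene_key: ",
                 paste(head(unmapped, 5), collapse = ", ")))
  genes |>
    rename(transcript_id = "gene_id") |>
    inner_join(gene_key, by = "transcript_id") |>
    arrange(.data$gene_id, desc(.data$length), .data$transcript_id) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    relocate("gene_id")
}

#' Strand-aware genomic windows around gene anchors
#'
#' Derives the half-open genomic interval `upstream` bp before and
#' `downstream` bp after an anchor (TSS or TTS), measured in the direction
#' of transcription: for minus-strand genes "upstream" extends towards
#' larger genomic coordinates. Intervals extending below position 0 are
#' clipped at 0 and flagged.
#'
#' @param genes Gene-model table.
#' @param anchor `"tss"` or `"tts"`.
#' @param upstream,downstream Non-negative distances in bp.
#' @return Tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `clipped`.
#' @examples
#' g <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
#'                     tss = 10000, tts = 30000, length = 20000,
#'                     exons = list(cbind(10000, 30000)), n_exons = 1L)
#' gene_window(g, "tss", 500, 500)   # promoter TSS +/- 500 bp
#' @export
gene_window <- function(genes, anchor = c("tss", "tts"),
                        upstream = 0, downstream = 0) {
  anchor <- match.arg(anchor)
  if (any(upstream < 0) || any(downstream < 0))
    abort("window distances must be >= 0")
  pos <- genes[[anchor]]
  plus <- genes$strand == "+"
  start <- ifelse(plus, pos - upstream, pos - downstream)
  end <- ifelse(plus, pos + downstream, pos + upstream)
  clipped <- start < 0
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = pmax(start, 0), end = pmax(end, 0), clipped = clipped)
}

#' Gene-body intervals
#'
#' The genomic span of each gene as a half-open interval, equal to
#' `gene_window(genes, "tss", 0, length)` regardless of strand.
#'
#' @param genes Gene-model table.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_body <- function(genes) {
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = pmin(genes$tss, genes$tts),
         end = pmax(genes$tss, genes$tts))
}

#' Write a curated gene table as TSV
#'
#' Writes `gene_id`, `chrom`, `strand`, `tss`, `tts`, `length`, `n_exons`
#' (exon coordinates are not serialized; use [write_bed12()] for a
#' round-trippable format).
#'
#' @param genes Gene-model table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  genes |>
    select("gene_id", "chrom", "strand", "tss", "tts", "length", "n_exons") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Write a gene table as BED12
#'
#' Serializes gene models, including exon block structure, as BED12. A
#' valid table round-trips bit-exactly through [read_annotation()].
#'
#' @param genes Gene-model table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  body <- gene_body(genes)
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    s <- body$start[i]; e <- body$end[i]
    sizes <- ex[, 2] - ex[, 1]
    starts <- ex[, 1] - s
    paste(body$chrom[i], format(s, scientific = FALSE),
          format(e, scientific = FALSE),
          genes$gene_id[i], 0L, genes$strand[i],
          format(s, scientific = FALSE), format(e, scientific = FALSE), "0",
          nrow(ex),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
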
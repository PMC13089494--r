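# Reference-annotation repair: 3' UTR extension for sparse annotations and
# profiling of intergenic read distances to the nearest upstream gene.
#
# Coordinates are GTF-style 1-based inclusive throughout. The same-strand gap
# between a gene and its downstream neighbour is `next_start - end - 1` on the
# plus strand (0 means directly adjacent).

#' Extend gene 3' ends into downstream intergenic space
#'
#' For every gene whose distance to the nearest same-strand downstream gene
#' exceeds `min_gap_bp` — or which has no same-strand downstream neighbour —
#' the 3' end is moved `extension_bp` downstream (end on the plus strand,
#' start on the minus strand), clipped to the chromosome. Genes with smaller
#' gaps, including same-strand overlaps (treated as gap 0), are unchanged.
#' Gene count, ids, strands and all other fields are conserved.
#'
#' @param genes Gene-model tibble with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive) and any extra columns.
#' @param extension_bp Extension in bp (typically 3000 or 5000).
#' @param min_gap_bp Minimum same-strand downstream gap required to extend.
#' @param chrom_lengths Named vector of chromosome lengths covering all
#'   chromosomes present.
#' @return The gene tibble with updated coordinates, in the input row order.
#' @export
extend_three_prime <- function(genes, extension_bp, min_gap_bp = 10000,
                               chrom_lengths) {
  if (extension_bp <= 0) rlang::abort("extension_bp must be positive")
  missing_chr <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(missing_chr) > 0) {
    rlang::abort(paste0("chrom_lengths missing: ", paste(missing_chr, collapse = ", ")))
  }
  if (any(genes$start > genes$end)) rlang::abort("gene with start > end")
  genes <- dplyr::mutate(genes, .row = dplyr::row_number())
  out <- genes |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::group_modify(function(g, key) {
      gap <- downstream_gap(g, key$strand)
      extend <- is.na(gap) | gap > min_gap_bp
      if (key$strand == "+") {
        g$end[extend] <- pmin(g$end[extend] + extension_bp,
                              chrom_lengths[[key$chrom]])
      } else {
        g$start[extend] <- pmax(g$start[extend] - extension_bp, 1L)
      }
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
  out
}

# Distance (bp) from each gene's 3' end to the nearest same-strand downstream
# gene start; NA when no downstream neighbour exists. Overlap maps to 0.
downstream_gap <- function(g, strand) {
  n <- nrow(g)
  gap <- rep(NA_real_, n)
  if (n < 2) return(gap)
  if (strand == "+") {
    for (i in seq_len(n)) {
      cand <- g$start[g$start > g$end[i]]
      if (length(cand) > 0) gap[i] <- min(cand) - g$end[i] - 1
      else if (any(g$start[-i] > g$start[i])) gap[i] <- 0  # overlapping neighbour
    }
  } else {
    for (i in seq_len(n)) {
      cand <- g$end[g$end < g$start[i]]
      if (length(cand) > 0) gap[i] <- g$start[i] - max(cand) - 1
      else if (any(g$end[-i] < g$end[i])) gap[i] <- 0
    }
  }
  pmax(gap, 0)
}

#' Histogram of intergenic read distances to upstream gene 3' ends
#'
#' Reads overlapping any gene (either strand) are excluded. Each remaining
#' read is assigned the distance from its proximal edge to the 3' end of the
#' nearest same-strand upstream gene (0 = first base past the gene), and
#' counted in fixed-width bins stratified by that gene's (biotype, has_utr3).
#' Reads beyond `max_distance` fall into an overflow bin (`bin_start = NA`);
#' reads with no same-strand upstream gene are dropped.
#'
#' @param reads Interval tibble: `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`.
#' @param genes Gene-model tibble with `biotype` and `has_utr3`.
#' @param max_distance Largest distance kept in regular bins.
#' @param bin_width Bin width in bp.
#' @return Tibble `biotype`, `has_utr3`, `bin_start`, `count`, covering all
#'   (stratum, bin) combinations present in `genes` (zero counts included).
#' @export
intergenic_distance_profile <- function(reads, genes, max_distance = 10000,
                                        bin_width = 1000) {
  if (bin_width <= 0) rlang::abort("bin_width must be positive")
  strata <- dplyr::distinct(genes, .data$biotype, .data$has_utr3)
  bins <- seq(0, max_distance - bin_width, by = bin_width)
  grid <- tidyr::crossing(strata, bin_start = c(bins, NA_real_))
  if (nrow(reads) == 0) {
    return(dplyr::mutate(grid, count = 0L))
  }
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start, genes$end),
                                     strand = genes$strand)
  gr_reads <- GenomicRanges::GRanges(reads$chrom,
                                     IRanges::IRanges(reads$start, reads$end),
                                     strand = reads$strand)
  ov <- GenomicRanges::findOverlaps(gr_reads, gr_genes, ignore.strand = TRUE)
  keep <- setdiff(seq_len(nrow(reads)), unique(S4Vectors::queryHits(ov)))
  hits <- purrr::map(keep, function(i) {
    r <- reads[i, ]
    same <- genes[genes$chrom == r$chrom & genes$strand == r$strand, ]
    if (nrow(same) == 0) return(NULL)
    if (r$strand == "+") {
      up <- same[same$end < r$start, ]
      if (nrow(up) == 0) return(NULL)
      g <- up[which.max(up$end), ]
      d <- r$start - g$end - 1
    } else {
      up <- same[same$start > r$end, ]
      if (nrow(up) == 0) return(NULL)
      g <- up[which.min(up$start), ]
      d <- g$start - r$end - 1
    }
    tibble::tibble(biotype = g$biotype, has_utr3 = g$has_utr3, distance = d)
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) return(dplyr::mutate(grid, count = 0L))
  hits$bin_start <- ifelse(hits$distance >= max_distance, NA_real_,
                           floor(hits$distance / bin_width) * bin_width)
  counts <- hits |>
    dplyr::count(.data$biotype, .data$has_utr3, .data$bin_start, name = "count")
  grid |>
    dplyr::left_join(counts, by = c("biotype", "has_utr3", "bin_start")) |>
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
}

#' 3' UTR length distribution per biotype
#'
#' Collects annotated 3' UTR lengths (genes with `has_utr3 = TRUE`) per
#' biotype, for diagnosing annotation artifacts such as spikes at stop-codon
#' length.
#'
#' @param genes Gene-model tibble with `biotype`, `has_utr3`, `utr3_length`.
#' @return Tibble `biotype`, `utr3_length` (one row per annotated UTR).
#' @export
utr3_lengths <- function(genes) {
  genes |>
    dplyr::filter(.data$has_utr3) |>
    dplyr::select("biotype", "utr3_length") |>
    tibble::as_tibble()
}

#' Read gene records from a GTF file
#'
#' Imports `gene`-type records via rtracklayer into the gene-model tibble.
#' Attribute columns are carried through untouched; `has_utr3`/`utr3_length`
#' are taken from attributes of the same name when present, otherwise filled
#' with `FALSE`/`0`.
#'
#' @param path GTF file path.
#' @return Gene-model tibble.
#' @export
read_gene_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  df <- as.data.frame(gr)
  out <- tibble::tibble(
    gene_id = df$gene_id, chrom = as.character(df$seqnames),
    strand = as.character(df$strand), start = df$start, end = df$end,
    biotype = if ("gene_biotype" %in% names(df)) df$gene_biotype else "protein_coding",
    has_utr3 = if ("has_utr3" %in% names(df)) as.logical(df$has_utr3) else FALSE,
    utr3_length = if ("utr3_length" %in% names(df)) as.numeric(df$utr3_length) else 0
  )
  out
}

#' Write gene records to a GTF file
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gtf <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  gr$type <- "gene"
  gr$source <- "crosscortex"
  gr$gene_id <- genes$gene_id
  gr$gene_biotype <- genes$biotype
  gr$has_utr3 <- genes$has_utr3
  gr$utr3_length <- genes$utr3_length
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read read-intervals from a BED6 file
#'
#' BED's 0-based half-open coordinates are converted to the package's 1-based
#' inclusive convention on import.
#'
#' @param path BED6 file path.
#' @return Interval tibble `chrom`, `start`, `end`, `strand`.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::start(gr) > GenomicRanges::end(gr))) {
    rlang::abort("BED interval with start > end")
  }
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}
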
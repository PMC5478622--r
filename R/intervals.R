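## Coordinate substrate: 0-based half-open intervals on named chromosomes.
## Genes, islands and probes are plain data.frames; GRanges are built
## transiently for overlap queries (GRanges is 1-based inclusive, hence
## the +1 on starts below).

#' Convert 1-based inclusive coordinates to the internal convention
#'
#' Published tables and GTF print 1-based inclusive coordinates;
#' internally everything is 0-based half-open.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return A list with elements `start` and `end` (0-based half-open).
#' @examples
#' from_one_based(72975469, 72975797)
#' @export
from_one_based <- function(start, end) {
  list(start = start - 1L, end = end)
}

#' @noRd
validate_intervals <- function(start, end, what = "interval") {
  bad <- which(!(start >= 0 & start < end))
  if (length(bad) > 0L) {
    stop(sprintf("%s %d has invalid coordinates [%s, %s): need 0 <= start < end",
                 what, bad[1L], start[bad[1L]], end[bad[1L]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a CpG island table
#'
#' @param island_id character vector of unique island identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @return data.frame with columns island_id, chrom, start, end, sorted by
#'   (chrom, start).  Overlapping islands on one chromosome are rejected.
#' @export
cpg_islands <- function(island_id, chrom, start, end) {
  validate_intervals(start, end, "island")
  if (anyDuplicated(island_id)) stop("duplicate island_id", call. = FALSE)
  df <- data.frame(island_id = as.character(island_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  check_islands_disjoint(df)
  df
}

#' @noRd
check_islands_disjoint <- function(islands) {
  for (ch in unique(islands$chrom)) {
    x <- islands[islands$chrom == ch, , drop = FALSE]
    if (nrow(x) < 2L) next
    ov <- which(x$start[-1L] < x$end[-nrow(x)])
    if (length(ov) > 0L) {
      i <- ov[1L]
      stop(sprintf("islands %s and %s overlap or are unsorted on %s",
                   x$island_id[i], x$island_id[i + 1L], ch), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Construct a gene model table
#'
#' A gene model carries the gene interval, strand, and optional
#' sub-feature intervals (5'-UTR, first exon, body, 3'-UTR), all 0-based
#' half-open.  The TSS is the strand-local start of the interval (the
#' first base for `+` genes, the last base for `-` genes) and the TES the
#' strand-local end; both are implied by interval and strand.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end gene interval, 0-based half-open.
#' @param strand "+" or "-".
#' @param utr5_start,utr5_end,first_exon_start,first_exon_end,body_start,body_end,utr3_start,utr3_end
#'   optional sub-feature intervals (NA when absent); when the first exon
#'   or body is missing the whole interval is used as body (logged via a
#'   message).
#' @return data.frame of gene models.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        utr5_start = NA, utr5_end = NA,
                        first_exon_start = NA, first_exon_end = NA,
                        body_start = NA, body_end = NA,
                        utr3_start = NA, utr3_end = NA) {
  validate_intervals(start, end, "gene")
  if (anyDuplicated(gene_id)) stop("duplicate gene_id", call. = FALSE)
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'", call. = FALSE)
  n <- length(gene_id)
  rep_n <- function(x) if (length(x) == 1L) rep(x, n) else x
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   utr5_start = as.integer(rep_n(utr5_start)),
                   utr5_end = as.integer(rep_n(utr5_end)),
                   first_exon_start = as.integer(rep_n(first_exon_start)),
                   first_exon_end = as.integer(rep_n(first_exon_end)),
                   body_start = as.integer(rep_n(body_start)),
                   body_end = as.integer(rep_n(body_end)),
                   utr3_start = as.integer(rep_n(utr3_start)),
                   utr3_end = as.integer(rep_n(utr3_end)),
                   stringsAsFactors = FALSE)
  no_body <- is.na(df$body_start) & is.na(df$first_exon_start)
  if (any(no_body)) {
    message(sum(no_body), " gene(s) without sub-features; whole interval used as body")
    df$body_start[no_body] <- df$start[no_body]
    df$body_end[no_body] <- df$end[no_body]
  }
  rownames(df) <- NULL
  df
}

#' TSS base position of each gene
#'
#' The position (0-based) of the transcription start base: `start` for
#' `+` strand genes, `end - 1` for `-` strand genes.
#'
#' @param genes gene model data.frame.
#' @return integer vector of positions, named by gene_id.
#' @export
tss_position <- function(genes) {
  setNames(ifelse(genes$strand == "+", genes$start, genes$end - 1L),
           genes$gene_id)
}

## Strand-local boundary coordinates used for distances: the TSS boundary
## is the half-open edge where transcription enters the gene, the TES
## boundary where it leaves.  Boundary (not base) coordinates make + and -
## strand distances exact mirror images.
#' @noRd
tss_boundary <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' @noRd
tes_boundary <- function(genes) {
  ifelse(genes$strand == "+", genes$end, genes$start)
}

#' Construct a CpG probe table
#'
#' @param probe_id unique probe identifiers.
#' @param chrom chromosome names.
#' @param pos 0-based base positions.
#' @return data.frame with columns probe_id, chrom, pos.
#' @export
cpg_sites <- function(probe_id, chrom, pos) {
  if (any(pos < 0)) stop("probe pos must be >= 0", call. = FALSE)
  if (anyDuplicated(probe_id)) stop("duplicate probe_id", call. = FALSE)
  data.frame(probe_id = as.character(probe_id), chrom = as.character(chrom),
             pos = as.integer(pos), stringsAsFactors = FALSE)
}

#' @noRd
sites_gr <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(start = sites$pos + 1L, width = 1L))
}

#' @noRd
intervals_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}
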
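## CGIR segmentation and probe annotation.
##
## A CpG island region (CGIR) is the island plus 2 kb shores and 2 kb
## shelves on each side.  N denotes the lower-coordinate (p-arm) flank and
## S the higher-coordinate (q-arm) flank, irrespective of any gene strand;
## gene strand only enters when a shore is re-labelled 5' or 3' relative
## to a gene.

CGIR_LABELS <- c("island", "n_shore", "s_shore", "n_shelf", "s_shelf")
GENE_CATEGORIES <- c("TSS200", "TSS1500", "UTR5", "FirstExon", "Body", "UTR3")

#' Segment CpG islands into island/shore/shelf regions
#'
#' Each island is flanked by a shore (default 2 kb) and a shelf (default
#' 2 kb beyond the shore) on each side.  Flanks are clipped at chromosome
#' bounds.  Where two islands face each other across a gap smaller than
#' twice the full flank width, their facing flanks are truncated at the
#' midpoint of the gap (an odd gap gives the extra base to the
#' lower-coordinate island), so that emitted segments never overlap.
#'
#' @param islands island data.frame for one chromosome (see
#'   [cpg_islands()]), sorted and non-overlapping.
#' @param chrom_length chromosome length in bp; must be >= the last
#'   island end.
#' @param shore_width,shelf_width flank widths in bp (default 2000 each).
#' @return data.frame with columns island_id, label (one of island,
#'   n_shore, s_shore, n_shelf, s_shelf), chrom, start, end.  Zero-length
#'   segments are omitted.
#' @examples
#' isl <- cpg_islands("cgi1", "chrT", 10000, 10500)
#' segment_cgir(isl, 100000)
#' @export
segment_cgir <- function(islands, chrom_length, shore_width = 2000L,
                         shelf_width = 2000L) {
  stopifnot(shore_width > 0, shelf_width > 0)
  if (nrow(islands) == 0L) {
    return(data.frame(island_id = character(), label = character(),
                      chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  if (length(unique(islands$chrom)) != 1L) {
    stop("segment_cgir operates on one chromosome at a time", call. = FALSE)
  }
  if (is.unsorted(islands$start)) stop("islands must be sorted by start", call. = FALSE)
  check_islands_disjoint(islands)
  if (chrom_length < max(islands$end)) {
    stop("chrom_length smaller than last island end", call. = FALSE)
  }

  n <- nrow(islands)
  flank <- shore_width + shelf_width
  ## midpoint boundaries between consecutive islands; odd gaps give the
  ## extra base to the lower-coordinate island
  gap_lo <- islands$end[-n]
  gap_hi <- islands$start[-1L]
  mid <- gap_lo + ceiling((gap_hi - gap_lo) / 2)
  left_limit <- c(0L, as.integer(mid))
  right_limit <- c(as.integer(mid), as.integer(chrom_length))

  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- islands$start[i]; e <- islands$end[i]
    lo <- max(left_limit[i], s - flank)
    hi <- min(right_limit[i], e + flank)
    seg <- data.frame(
      island_id = islands$island_id[i],
      label = c("n_shelf", "n_shore", "island", "s_shore", "s_shelf"),
      chrom = islands$chrom[i],
      start = c(lo, max(lo, s - shore_width), s, e, min(hi, e + shore_width)),
      end = c(max(lo, s - shore_width), s, e, min(hi, e + shore_width), hi),
      stringsAsFactors = FALSE)
    out[[i]] <- seg[seg$end > seg$start, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Segment islands on every chromosome
#'
#' @param islands island data.frame (multiple chromosomes allowed).
#' @param chrom_sizes data.frame with columns chrom, length.
#' @inheritParams segment_cgir
#' @return combined segment data.frame (see [segment_cgir()]).
#' @export
segment_cgir_all <- function(islands, chrom_sizes, shore_width = 2000L,
                             shelf_width = 2000L) {
  pieces <- lapply(unique(islands$chrom), function(ch) {
    len <- chrom_sizes$length[chrom_sizes$chrom == ch]
    if (length(len) != 1L) stop("no chromosome length for ", ch, call. = FALSE)
    segment_cgir(islands[islands$chrom == ch, , drop = FALSE], len,
                 shore_width, shelf_width)
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Assign probes to CGIR segments
#'
#' @param sites probe data.frame (see [cpg_sites()]).
#' @param segments segment data.frame from [segment_cgir_all()].
#' @return data.frame with columns probe_id, cgir_label, island_id;
#'   probes outside every segment get ("no_cgir", NA).
#' @export
classify_cpg_cgir <- function(sites, segments) {
  res <- data.frame(probe_id = sites$probe_id,
                    cgir_label = rep("no_cgir", nrow(sites)),
                    island_id = rep(NA_character_, nrow(sites)),
                    stringsAsFactors = FALSE)
  if (nrow(segments) > 0L && nrow(sites) > 0L) {
    hits <- GenomicRanges::findOverlaps(sites_gr(sites), intervals_gr(segments))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    res$cgir_label[q] <- segments$label[s]
    res$island_id[q] <- segments$island_id[s]
  }
  res
}

#' @noRd
gene_category_regions <- function(genes, tss1500 = 1500L, tss200 = 200L) {
  plus <- genes$strand == "+"
  tssb <- tss_boundary(genes)
  reg <- function(gene_id, category, chrom, start, end) {
    keep <- !is.na(start) & !is.na(end) & end > pmax(start, 0L)
    data.frame(gene_id = gene_id[keep], category = rep(category, sum(keep)),
               chrom = chrom[keep],
               start = pmax(as.integer(start[keep]), 0L),
               end = as.integer(end[keep]), stringsAsFactors = FALSE)
  }
  pieces <- list(
    reg(genes$gene_id, "TSS200", genes$chrom,
        ifelse(plus, tssb - tss200, tssb),
        ifelse(plus, tssb, tssb + tss200)),
    reg(genes$gene_id, "TSS1500", genes$chrom,
        ifelse(plus, tssb - tss1500, tssb + tss200),
        ifelse(plus, tssb - tss200, tssb + tss1500)),
    reg(genes$gene_id, "UTR5", genes$chrom, genes$utr5_start, genes$utr5_end),
    reg(genes$gene_id, "FirstExon", genes$chrom,
        genes$first_exon_start, genes$first_exon_end),
    reg(genes$gene_id, "Body", genes$chrom, genes$body_start, genes$body_end),
    reg(genes$gene_id, "UTR3", genes$chrom, genes$utr3_start, genes$utr3_end))
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Gene-context category of probes
#'
#' Classifies each probe against each gene it touches, in strand-local
#' coordinates: TSS1500 is 1500 to 200 bp upstream of the TSS, TSS200 the
#' final 200 bp before the TSS; inside the gene the annotated sub-feature
#' applies.  When a position falls in several regions of one gene the
#' precedence is TSS200 > TSS1500 > 5'-UTR > first exon > body > 3'-UTR.
#' A probe may be annotated against several overlapping genes (one row
#' per gene); probes touching no gene are absent from the result.
#'
#' @param sites probe data.frame.
#' @param genes gene model data.frame.
#' @return data.frame with columns probe_id, gene_id, category.
#' @export
gene_context <- function(sites, genes) {
  empty <- data.frame(probe_id = character(), gene_id = character(),
                      category = character(), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L || nrow(genes) == 0L) return(empty)
  regions <- gene_category_regions(genes)
  if (nrow(regions) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(sites_gr(sites), intervals_gr(regions))
  if (length(hits) == 0L) return(empty)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  df <- data.frame(probe_id = sites$probe_id[q],
                   gene_id = regions$gene_id[s],
                   category = regions$category[s], stringsAsFactors = FALSE)
  ## per (probe, gene) keep the highest-precedence category
  prec <- match(df$category, GENE_CATEGORIES)
  df <- df[order(df$probe_id, df$gene_id, prec), , drop = FALSE]
  df <- df[!duplicated(df[, c("probe_id", "gene_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Is a probe within a window of any TSS?
#'
#' Boundary-inclusive: a probe exactly `window` bp from a TSS base
#' counts as proximal.
#'
#' @param sites probe data.frame.
#' @param genes gene model data.frame (TSS base positions are derived
#'   per gene).
#' @param window half-width in bp (default 300).
#' @return logical vector along sites.
#' @export
tss_proximal <- function(sites, genes, window = 300L) {
  stopifnot(window > 0)
  out <- logical(nrow(sites))
  if (nrow(genes) == 0L) return(out)
  tpos <- tss_position(genes)
  for (ch in unique(sites$chrom)) {
    tt <- sort(unname(tpos[genes$chrom == ch]))
    if (length(tt) == 0L) next
    idx <- which(sites$chrom == ch)
    p <- sites$pos[idx]
    k <- findInterval(p, tt)
    d_lo <- ifelse(k >= 1L, p - tt[pmax(k, 1L)], Inf)
    d_hi <- ifelse(k < length(tt), tt[pmin(k + 1L, length(tt))] - p, Inf)
    out[idx] <- pmin(d_lo, d_hi) <= window
  }
  out
}

#' Orient a shore relative to a gene's strand
#'
#' N and S shores are named by chromosome coordinate order (p-arm to
#' q-arm).  For a Watson-strand (+) gene the N-shore is its 5'-shore;
#' for a Crick-strand (-) gene the S-shore is its 5'-shore.
#'
#' @param shore_label "n_shore" or "s_shore" (vectorized).
#' @param strand "+" or "-" (vectorized).
#' @return character vector, "five_prime" or "three_prime".
#' @export
orient_shore <- function(shore_label, strand) {
  if (!all(shore_label %in% c("n_shore", "s_shore"))) {
    stop("orient_shore applies only to shore labels", call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  ifelse((shore_label == "n_shore") == (strand == "+"), "five_prime", "three_prime")
}

#' Promoter/coding class of a gene-context category
#'
#' Promoter regions are TSS1500, TSS200, 5'-UTR and first exon; coding
#' regions are the gene body and 3'-UTR.
#'
#' @param category character vector of gene-context categories.
#' @return character vector, "promoter" or "coding".
#' @export
region_class <- function(category) {
  if (!all(category %in% GENE_CATEGORIES)) {
    stop("unknown gene-context category", call. = FALSE)
  }
  ifelse(category %in% c("TSS1500", "TSS200", "UTR5", "FirstExon"),
         "promoter", "coding")
}

#' Full probe annotation
#'
#' Joins CGIR classification, gene context, TSS proximity and shore
#' orientation into one long table (one row per probe x overlapping
#' gene; intergenic probes keep a single row with NA gene columns).
#'
#' @param sites probe data.frame.
#' @param islands island data.frame.
#' @param genes gene model data.frame.
#' @param chrom_sizes data.frame with columns chrom, length.
#' @param tss_window TSS proximity half-width in bp (default 300).
#' @param shore_width,shelf_width CGIR flank widths in bp.
#' @return data.frame with columns probe_id, chrom, pos, cgir_label,
#'   island_id, tss_proximal, gene_id, category, region_class,
#'   shore_orientation.
#' @export
annotate_probes <- function(sites, islands, genes, chrom_sizes,
                            tss_window = 300L, shore_width = 2000L,
                            shelf_width = 2000L) {
  segments <- segment_cgir_all(islands, chrom_sizes, shore_width, shelf_width)
  cgir <- classify_cpg_cgir(sites, segments)
  ctx <- gene_context(sites, genes)
  base <- data.frame(sites, cgir_label = cgir$cgir_label,
                     island_id = cgir$island_id,
                     tss_proximal = tss_proximal(sites, genes, tss_window),
                     stringsAsFactors = FALSE)
  ann <- merge(base, ctx, by = "probe_id", all.x = TRUE, sort = FALSE)
  ann$region_class <- ifelse(is.na(ann$category), NA_character_,
                             region_class(ifelse(is.na(ann$category), "Body",
                                                 ann$category)))
  is_shore <- ann$cgir_label %in% c("n_shore", "s_shore") & !is.na(ann$gene_id)
  ann$shore_orientation <- NA_character_
  if (any(is_shore)) {
    str <- genes$strand[match(ann$gene_id[is_shore], genes$gene_id)]
    ann$shore_orientation[is_shore] <-
      orient_shore(ann$cgir_label[is_shore], str)
  }
  ann <- ann[order(ann$chrom, ann$pos, ann$probe_id,
                   ifelse(is.na(ann$gene_id), "", ann$gene_id)), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}
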
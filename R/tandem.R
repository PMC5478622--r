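## Tandem-oriented gene pairs: two same-strand genes where the TES of the
## upstream gene lies close upstream of the TSS of the downstream gene.
## Distances use half-open boundary coordinates, which makes the + and -
## strand definitions exact mirror images under coordinate reflection.

#' TES-to-TSS distance of a candidate tandem pair
#'
#' Strand-local intergenic distance from the transcription end of the
#' upstream gene to the transcription start of the downstream gene:
#' `TSS(down) - TES(up)` for `+` strand pairs and its mirror for `-`.
#' Negative for overlapping (read-through) pairs; callers filter.
#'
#' @param upstream,downstream single-row gene model data.frames (or
#'   aligned multi-row frames) on the same chromosome and strand.
#' @return numeric distance(s) in bp.
#' @export
tes_tss_distance <- function(upstream, downstream) {
  if (any(upstream$strand != downstream$strand)) {
    stop("tandem pair members must share a strand", call. = FALSE)
  }
  if (any(upstream$chrom != downstream$chrom)) {
    stop("tandem pair members must share a chromosome", call. = FALSE)
  }
  ifelse(upstream$strand == "+",
         downstream$start - upstream$end,
         upstream$start - downstream$end)
}

#' Detect tandem-oriented gene pairs
#'
#' For each gene the nearest same-strand downstream neighbor (in
#' strand-local orientation, ordered by TSS) forms a candidate pair.
#' Pairs with any intervening gene (either strand) overlapping the
#' TES-to-TSS gap are dropped, as are overlapping pairs (negative
#' distance), so the retained distance is a clean intergenic gap.
#'
#' @param genes gene model data.frame.
#' @return data.frame with columns upstream_gene_id, downstream_gene_id,
#'   chrom, strand, distance_bp; possibly zero rows.
#' @export
find_tandem_pairs <- function(genes) {
  empty <- data.frame(upstream_gene_id = character(),
                      downstream_gene_id = character(),
                      chrom = character(), strand = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(genes) < 2L) return(empty)
  out <- list()
  for (ch in unique(genes$chrom)) {
    gch <- genes[genes$chrom == ch, , drop = FALSE]
    for (str in c("+", "-")) {
      g <- gch[gch$strand == str, , drop = FALSE]
      if (nrow(g) < 2L) next
      tssb <- tss_boundary(g)
      ## strand-local order: ascending TSS boundary for +, descending for -
      ord <- order(if (str == "+") tssb else -tssb, g$gene_id)
      g <- g[ord, , drop = FALSE]
      up <- g[-nrow(g), , drop = FALSE]
      down <- g[-1L, , drop = FALSE]
      d <- tes_tss_distance(up, down)
      keep <- d >= 0
      if (!any(keep)) next
      up <- up[keep, , drop = FALSE]; down <- down[keep, , drop = FALSE]
      d <- d[keep]
      ## drop pairs with an intervening gene (either strand) in the gap
      gap_start <- if (str == "+") up$end else down$end
      gap_end <- if (str == "+") down$start else up$start
      blocked <- vapply(seq_along(d), function(i) {
        if (gap_end[i] <= gap_start[i]) return(FALSE)
        others <- gch[!(gch$gene_id %in% c(up$gene_id[i], down$gene_id[i])), ,
                      drop = FALSE]
        any(others$start < gap_end[i] & others$end > gap_start[i])
      }, logical(1L))
      if (all(blocked)) next
      out[[length(out) + 1L]] <- data.frame(
        upstream_gene_id = up$gene_id[!blocked],
        downstream_gene_id = down$gene_id[!blocked],
        chrom = ch, strand = str,
        distance_bp = as.integer(d[!blocked]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$upstream_gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Attach the downstream promoter CpG island to tandem pairs
#'
#' The downstream CGI of a pair is the island overlapping the window
#' TSS +/- `tss_window` around the downstream gene's TSS base.  When
#' several islands overlap the window the one whose nearest edge is
#' closest to the TSS wins; exact ties go to the lower-coordinate
#' island.  Pairs without such an island get NA (they are excluded from
#' methylation analysis).
#'
#' @param pairs pair data.frame from [find_tandem_pairs()].
#' @param genes gene model data.frame.
#' @param islands island data.frame.
#' @param tss_window half-width of the TSS window in bp (default 300).
#' @return `pairs` with an added downstream_cgi_id column.
#' @export
attach_downstream_cgi <- function(pairs, genes, islands, tss_window = 300L) {
  tpos <- tss_position(genes)
  pairs$downstream_cgi_id <- vapply(seq_len(nrow(pairs)), function(i) {
    gid <- pairs$downstream_gene_id[i]
    t <- tpos[[gid]]
    isl <- islands[islands$chrom == pairs$chrom[i], , drop = FALSE]
    ## island [s, e) overlaps inclusive window [t - w, t + w]
    hit <- isl[isl$start <= t + tss_window & isl$end > t - tss_window, ,
               drop = FALSE]
    if (nrow(hit) == 0L) return(NA_character_)
    dist <- ifelse(hit$start <= t & t < hit$end, 0L,
                   ifelse(t < hit$start, hit$start - t, t - hit$end + 1L))
    hit$island_id[order(dist, hit$start)][1L]
  }, character(1L))
  pairs
}

#' Bin tandem pairs by TES-to-TSS distance
#'
#' A pair at distance d falls in bin i when edges[i] <= d < edges[i+1];
#' with the default 1 kb edges the "k kb" bin is the half-open interval
#' [k-1, k) kb.  Pairs at or beyond the last edge go to an overflow
#' group.
#'
#' @param pairs pair data.frame with a distance_bp column.
#' @param edges strictly increasing bin edges in bp.
#' @return `pairs` with an added `bin` factor column whose levels are
#'   "1 kb", "2 kb", ... and an overflow level ">6 kb" (labels follow
#'   the upper edges).
#' @export
bin_pairs_by_distance <- function(pairs,
                                  edges = seq(0L, 6000L, by = 1000L)) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing", call. = FALSE)
  labels <- paste0(edges[-1L] / 1000, " kb")
  overflow <- paste0(">", edges[length(edges)] / 1000, " kb")
  idx <- findInterval(pairs$distance_bp, edges)
  lab <- rep(NA_character_, nrow(pairs))
  lab[idx >= 1L & idx < length(edges)] <- labels[idx[idx >= 1L & idx < length(edges)]]
  lab[pairs$distance_bp >= edges[length(edges)]] <- overflow
  pairs$bin <- factor(lab, levels = c(labels, overflow))
  pairs
}
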
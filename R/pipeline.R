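## End-to-end orchestration: annotation -> tandem pairs -> aggregation ->
## stratified summaries, shore asymmetry, distance-bin analysis and the
## ranked hypermethylation tables.  All thresholds are arguments with
## the field's usual defaults (2 kb shores/shelves, TSS +/- 300 bp,
## 1 kb distance bins to 6 kb).

#' Pipeline configuration
#'
#' @param shore_width,shelf_width CGIR flank widths (bp).
#' @param tss_window TSS proximity half-width (bp).
#' @param bin_edges distance bin edges (bp).
#' @param agg_stat group aggregation statistic ("median" or "mean").
#' @param test group-comparison test for contrasts.
#' @param top_n rows of the ranked tables.
#' @param seed integer seed recorded in outputs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(shore_width = 2000L, shelf_width = 2000L,
                            tss_window = 300L,
                            bin_edges = seq(0L, 6000L, by = 1000L),
                            agg_stat = "median", test = "wilcoxon_ranksum",
                            top_n = 20L, seed = 1L) {
  stopifnot(shore_width > 0, shelf_width > 0, tss_window > 0,
            all(diff(bin_edges) > 0))
  structure(list(shore_width = shore_width, shelf_width = shelf_width,
                 tss_window = tss_window, bin_edges = bin_edges,
                 agg_stat = agg_stat, test = test, top_n = top_n,
                 seed = seed), class = "pipeline_config")
}

#' @noRd
island_membership <- function(annotations) {
  idx <- annotations$cgir_label == "island" & !is.na(annotations$island_id)
  ann <- annotations[idx, c("probe_id", "island_id"), drop = FALSE]
  ann <- ann[!duplicated(ann), , drop = FALSE]
  split(ann$probe_id, ann$island_id)
}

#' @noRd
tss_island_ids <- function(annotations) {
  idx <- annotations$cgir_label == "island" & annotations$tss_proximal &
    !is.na(annotations$island_id)
  unique(annotations$island_id[idx])
}

#' Run the full methylome-context pipeline
#'
#' @param sites probe data.frame.
#' @param islands island data.frame.
#' @param genes gene model data.frame.
#' @param chrom_sizes data.frame (chrom, length).
#' @param beta beta matrix (fractions).
#' @param sheet sample sheet with groups "tumor" and "normal" (other
#'   labels are carried through summaries but not used in scoring).
#' @param config a [pipeline_config()].
#' @return list with annotation, pairs, region_means, strata_cgir,
#'   strata_context, shore_asymmetry (promoter and coding), distance_bins,
#'   ranked (hypermethylation ranking over all TSS-associated CGIs),
#'   ranked_tandem (ranking restricted to downstream tandem CGIs, with
#'   the downstream gene attached) and config.
#' @export
run_pipeline <- function(sites, islands, genes, chrom_sizes, beta, sheet,
                         config = pipeline_config()) {
  ann <- annotate_probes(sites, islands, genes, chrom_sizes,
                         tss_window = config$tss_window,
                         shore_width = config$shore_width,
                         shelf_width = config$shelf_width)
  pairs <- find_tandem_pairs(genes)
  pairs <- attach_downstream_cgi(pairs, genes, islands,
                                 tss_window = config$tss_window)
  pairs <- bin_pairs_by_distance(pairs, edges = config$bin_edges)

  membership <- island_membership(ann)
  rm <- region_means_matrix(beta, membership)
  means_pct <- rm$means * 100

  tumor_ids <- sheet$sample_id[sheet$group == "tumor"]
  normal_ids <- sheet$sample_id[sheet$group == "normal"]

  strata_cgir <- stratified_distribution(beta, ann, sheet, by = "cgir_tss")
  strata_ctx <- stratified_distribution(beta, ann, sheet,
                                        by = "category_orientation")
  shore_prom <- shore_asymmetry_analysis(beta, ann, "promoter", sheet)
  shore_cod <- shore_asymmetry_analysis(beta, ann, "coding", sheet)
  dist_bins <- distance_bin_analysis(pairs, beta, membership, sheet,
                                     tss_islands = tss_island_ids(ann))

  ranked <- ranked_tandem <- NULL
  if (length(tumor_ids) >= 1L && length(normal_ids) >= 1L) {
    tss_isl <- intersect(tss_island_ids(ann), rownames(means_pct))
    if (length(tss_isl) > 0L) {
      scores <- hypermeth_score(means_pct[tss_isl, , drop = FALSE],
                                tumor_ids, normal_ids)
      ranked <- rank_hypermethylated(scores, n = config$top_n)
    }
    down_isl <- intersect(unique(pairs$downstream_cgi_id[
      !is.na(pairs$downstream_cgi_id)]), rownames(means_pct))
    if (length(down_isl) > 0L) {
      gene_map <- setNames(pairs$downstream_gene_id[
        match(down_isl, pairs$downstream_cgi_id)], down_isl)
      scores2 <- hypermeth_score(means_pct[down_isl, , drop = FALSE],
                                 tumor_ids, normal_ids,
                                 gene_symbols = gene_map)
      ranked_tandem <- rank_hypermethylated(scores2, n = config$top_n)
    }
  }

  list(annotation = ann, pairs = pairs,
       region_means = rm, strata_cgir = strata_cgir,
       strata_context = strata_ctx,
       shore_asymmetry = list(promoter = shore_prom, coding = shore_cod),
       distance_bins = dist_bins, ranked = ranked,
       ranked_tandem = ranked_tandem, config = config)
}

#' Write pipeline outputs as TSV files
#'
#' Writes annotation, pairs, stratified summaries, shore-asymmetry
#' summaries/tests, distance-bin summary, ranked tables and a manifest
#' of produced files with md5 checksums.
#'
#' @param result output of [run_pipeline()].
#' @param outdir output directory.
#' @return named character vector of written files (invisible).
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- list(seed = result$config$seed,
                 shore_width = result$config$shore_width,
                 shelf_width = result$config$shelf_width,
                 tss_window = result$config$tss_window,
                 bin_edges = result$config$bin_edges)
  p <- function(f) file.path(outdir, f)
  out <- c()
  wr <- function(df, f) {
    write_tsv_commented(df, p(f), params)
    out[[f]] <<- p(f)
  }
  wr(result$annotation, "annotation.tsv")
  pr <- result$pairs
  pr$bin <- as.character(pr$bin)
  wr(pr, "pairs.tsv")
  wr(result$strata_cgir$summary, "strata_cgir.tsv")
  wr(result$strata_context$summary, "strata_context.tsv")
  for (rc in c("promoter", "coding")) {
    sa <- result$shore_asymmetry[[rc]]
    if (!sa$empty) {
      wr(sa$summary, paste0("shore_", rc, "_summary.tsv"))
      wr(sa$tests, paste0("shore_", rc, "_tests.tsv"))
    }
  }
  wr(result$distance_bins$per_bin, "distance_bins.tsv")
  if (!is.null(result$ranked)) {
    wr(hypermeth_report(result$ranked), "ranked_cgi.tsv")
  }
  if (!is.null(result$ranked_tandem)) {
    wr(hypermeth_report(result$ranked_tandem), "ranked_tandem.tsv")
  }
  files <- unlist(out)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, p("MANIFEST.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(files, manifest = p("MANIFEST.tsv")))
}
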
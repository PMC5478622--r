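## File dialects at the boundary: BED is read verbatim (already 0-based
## half-open), GTF is converted from 1-based inclusive.  rtracklayer does
## the parsing; this module only reshapes into the package's data.frames.

#' Read CpG islands from BED3+
#'
#' @param path BED file; column 4 (name), when present, becomes the
#'   island id, otherwise ids are chrom:start-end.
#' @return island data.frame (see [cpg_islands()]).
#' @export
read_cgi_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  nm <- S4Vectors::mcols(gr)$name
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (is.null(nm) || all(is.na(nm))) {
    nm <- sprintf("%s:%d-%d", chrom, start0, end0)
  }
  cpg_islands(nm, chrom, start0, end0)
}

#' Read gene models from GTF
#'
#' Gene intervals come from `gene` features (or the span of each gene's
#' exons when absent); the first exon is the strand-local first `exon`;
#' UTRs from `five_prime_utr`/`three_prime_utr` (or `UTR`) features; the
#' body is the gene span minus nothing (whole span) and sub-feature
#' precedence handles overlap.  One TSS per gene.
#'
#' @param path GTF file with gene_id attributes.
#' @return gene model data.frame.
#' @export
read_gene_models_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "GTF"),
                 error = function(e) stop("malformed GTF file '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stop("GTF lacks gene_id attributes", call. = FALSE)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,   # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(md$type),
                   gene_id = as.character(md$gene_id),
                   stringsAsFactors = FALSE)
  build_one <- function(sub) {
    gene_row <- sub[sub$type == "gene", , drop = FALSE]
    if (nrow(gene_row) == 0L) {
      gene_row <- data.frame(chrom = sub$chrom[1L], start = min(sub$start),
                             end = max(sub$end), strand = sub$strand[1L],
                             stringsAsFactors = FALSE)
    }
    strand <- gene_row$strand[1L]
    exons <- sub[sub$type == "exon", , drop = FALSE]
    fe <- if (nrow(exons) > 0L) {
      if (strand == "+") exons[which.min(exons$start), ] else
        exons[which.max(exons$end), ]
    } else NULL
    pick <- function(tp) {
      r <- sub[sub$type %in% tp, , drop = FALSE]
      if (nrow(r) == 0L) c(NA_integer_, NA_integer_) else
        c(min(r$start), max(r$end))
    }
    u5 <- pick(c("five_prime_utr", "5UTR"))
    u3 <- pick(c("three_prime_utr", "3UTR"))
    ## the body is the gene span minus the first exon (TSS side) and the
    ## 3'-UTR (TES side), strand-aware
    if (strand == "+") {
      body_s <- if (is.null(fe)) gene_row$start[1L] else fe$end
      body_e <- if (is.na(u3[1L])) gene_row$end[1L] else u3[1L]
    } else {
      body_s <- if (is.na(u3[1L])) gene_row$start[1L] else u3[2L]
      body_e <- if (is.null(fe)) gene_row$end[1L] else fe$start
    }
    data.frame(gene_id = sub$gene_id[1L], chrom = gene_row$chrom[1L],
               start = gene_row$start[1L], end = gene_row$end[1L],
               strand = strand,
               utr5_start = u5[1L], utr5_end = u5[2L],
               first_exon_start = if (is.null(fe)) NA_integer_ else fe$start,
               first_exon_end = if (is.null(fe)) NA_integer_ else fe$end,
               body_start = body_s, body_end = max(body_s, body_e),
               utr3_start = u3[1L], utr3_end = u3[2L],
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(split(df, df$gene_id), build_one))
  rownames(res) <- NULL
  do.call(gene_models, res)
}

#' Read a CpG probe manifest
#'
#' @param path TSV with columns probe_id, chrom, pos (0-based), or a BED
#'   file of single-base probe intervals (name column = probe id).
#' @return probe data.frame (see [cpg_sites()]).
#' @export
read_manifest <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(cpg_sites(S4Vectors::mcols(gr)$name,
                     as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L))
  }
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("probe_id", "chrom", "pos") %in% names(df))) {
    stop("manifest needs columns probe_id, chrom, pos", call. = FALSE)
  }
  cpg_sites(df$probe_id, df$chrom, df$pos)
}

#' Read chromosome sizes
#'
#' @param path two-column TSV (chrom, length), no header required.
#' @return data.frame with columns chrom, length.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2L) stop("chrom sizes file needs two columns", call. = FALSE)
  names(df)[1:2] <- c("chrom", "length")
  df[, c("chrom", "length")]
}

#' Write a TSV with a parameter-recording header comment
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list recorded as `# key=value` comment lines.
#' @export
write_tsv_commented <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params)) {
    writeLines(sprintf("# %s=%s", k, paste(params[[k]], collapse = ",")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated data in the dialects the pipeline consumes
#'
#' Emits islands.bed, genes.gtf, manifest.tsv, beta.tsv (fraction
#' scale), samples.csv, chrom_sizes.tsv, truth_probes.tsv and
#' truth_pairs.tsv.
#'
#' @param genome output of [simulate_genome()].
#' @param sim output of [simulate_beta()].
#' @param config the [sim_config()] used.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_simulation <- function(genome, sim, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  isl <- genome$islands
  bed <- data.frame(isl$chrom, isl$start, isl$end, isl$island_id)
  write.table(bed, p("islands.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(format_gtf(genome$genes), p("genes.gtf"))
  write_tsv_commented(genome$sites, p("manifest.tsv"),
                      list(seed = config$seed))
  beta_df <- data.frame(probe_id = rownames(sim$beta),
                        round(sim$beta, 6), check.names = FALSE)
  write_tsv_commented(beta_df, p("beta.tsv"),
                      list(seed = config$seed, scale = "fraction"))
  utils::write.csv(sim$sheet, p("samples.csv"), row.names = FALSE,
                   quote = FALSE)
  write.table(genome$chrom_sizes, p("chrom_sizes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv_commented(genome$truth$probes, p("truth_probes.tsv"),
                      list(seed = config$seed))
  write_tsv_commented(genome$truth$pairs, p("truth_pairs.tsv"),
                      list(seed = config$seed))
  c(islands = p("islands.bed"), genes = p("genes.gtf"),
    manifest = p("manifest.tsv"), beta = p("beta.tsv"),
    samples = p("samples.csv"), chrom_sizes = p("chrom_sizes.tsv"),
    truth_probes = p("truth_probes.tsv"), truth_pairs = p("truth_pairs.tsv"))
}

#' @noRd
format_gtf <- function(genes) {
  rows <- character()
  attr_str <- function(gid) sprintf('gene_id "%s"; transcript_id "%s.t1";',
                                    gid, gid)
  line <- function(chrom, type, start0, end0, strand, gid) {
    sprintf("%s\ttandemCGI\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start0 + 1L, end0, strand, attr_str(gid))
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rows <- c(rows, line(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id))
    if (!is.na(g$first_exon_start)) {
      rows <- c(rows, line(g$chrom, "exon", g$first_exon_start,
                           g$first_exon_end, g$strand, g$gene_id))
    }
    if (!is.na(g$utr5_start)) {
      rows <- c(rows, line(g$chrom, "five_prime_utr", g$utr5_start,
                           g$utr5_end, g$strand, g$gene_id))
    }
    if (!is.na(g$utr3_start)) {
      rows <- c(rows, line(g$chrom, "three_prime_utr", g$utr3_start,
                           g$utr3_end, g$strand, g$gene_id))
    }
  }
  rows
}
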
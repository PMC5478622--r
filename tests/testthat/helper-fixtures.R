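# Small builders used across tests; all fixtures are constructed in code.

toy_gene <- function(id, chrom, start, end, strand,
                     with_subfeatures = TRUE) {
  if (!with_subfeatures) {
    return(suppressMessages(gene_models(id, chrom, start, end, strand)))
  }
  if (strand == "+") {
    gene_models(id, chrom, start, end, strand,
                utr5_start = start, utr5_end = start + 150L,
                first_exon_start = start, first_exon_end = start + 500L,
                body_start = start + 500L, body_end = end - 250L,
                utr3_start = end - 250L, utr3_end = end)
  } else {
    gene_models(id, chrom, start, end, strand,
                utr5_start = end - 150L, utr5_end = end,
                first_exon_start = end - 500L, first_exon_end = end,
                body_start = start + 250L, body_end = end - 500L,
                utr3_start = start, utr3_end = start + 250L)
  }
}

rbind_genes <- function(...) {
  g <- do.call(rbind, list(...))
  rownames(g) <- NULL
  g
}

# Per-bp brute-force CGIR labelling used as the segmentation oracle:
# each base belongs to the nearest island (midpoint rule, ties to the
# lower-coordinate island), labelled by its distance from that island.
brute_force_cgir <- function(islands, chrom_length, shore_width = 2000L,
                             shelf_width = 2000L) {
  labels <- rep("no_cgir", chrom_length)
  ids <- rep(NA_character_, chrom_length)
  pos <- seq_len(chrom_length) - 1L
  n <- nrow(islands)
  # distance of each bp to each island and the owning island
  dist <- matrix(Inf, nrow = chrom_length, ncol = n)
  for (j in seq_len(n)) {
    s <- islands$start[j]; e <- islands$end[j]
    dist[, j] <- ifelse(pos < s, s - pos, ifelse(pos >= e, pos - e + 1L, 0L))
  }
  owner <- apply(dist, 1L, which.min)     # ties -> lowest index = lowest coord
  dmin <- dist[cbind(seq_len(chrom_length), owner)]
  inside <- dmin == 0
  in_shore <- dmin > 0 & dmin <= shore_width
  in_shelf <- dmin > shore_width & dmin <= shore_width + shelf_width
  side_n <- pos < islands$start[owner]    # lower-coordinate flank
  labels[inside] <- "island"
  labels[in_shore & side_n] <- "n_shore"
  labels[in_shore & !side_n] <- "s_shore"
  labels[in_shelf & side_n] <- "n_shelf"
  labels[in_shelf & !side_n] <- "s_shelf"
  ids[inside | in_shore | in_shelf] <-
    islands$island_id[owner][inside | in_shore | in_shelf]
  data.frame(pos = pos, label = labels, island_id = ids,
             stringsAsFactors = FALSE)
}

# Per-bp brute-force gene-context classifier (single gene), mirroring the
# strand-local definitions independently of the vectorized implementation.
brute_force_gene_context <- function(pos, gene) {
  stopifnot(nrow(gene) == 1L)
  rel <- if (gene$strand == "+") pos - gene$start else (gene$end - 1L) - pos
  inr <- function(s, e) !is.na(s) && !is.na(e) && pos >= s && pos < e
  if (rel >= -200 && rel < 0) return("TSS200")
  if (rel >= -1500 && rel < -200) return("TSS1500")
  if (inr(gene$utr5_start, gene$utr5_end)) return("UTR5")
  if (inr(gene$first_exon_start, gene$first_exon_end)) return("FirstExon")
  if (inr(gene$body_start, gene$body_end)) return("Body")
  if (inr(gene$utr3_start, gene$utr3_end)) return("UTR3")
  NA_character_
}

# Exhaustive pairwise tandem-pair oracle with the same filters.
brute_force_tandem <- function(genes) {
  out <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(genes))) {
    if (i == j) next
    a <- genes[i, ]; b <- genes[j, ]
    if (a$chrom != b$chrom || a$strand != b$strand) next
    # b strand-locally downstream of a, immediately next by TSS
    tb_a <- if (a$strand == "+") a$start else -a$end
    tb_b <- if (b$strand == "+") b$start else -b$end
    if (tb_b < tb_a || (tb_b == tb_a && b$gene_id <= a$gene_id)) next
    same <- genes[genes$chrom == a$chrom & genes$strand == a$strand, ]
    tb_all <- if (a$strand == "+") same$start else -same$end
    between <- tb_all > tb_a & tb_all < tb_b
    at_b <- tb_all == tb_b & same$gene_id < b$gene_id & same$gene_id != a$gene_id
    at_a <- tb_all == tb_a & same$gene_id > a$gene_id & same$gene_id != b$gene_id
    if (any(between | at_b | at_a)) next      # not the nearest neighbor
    d <- tes_tss_distance(a, b)
    if (d < 0) next
    gap_s <- if (a$strand == "+") a$end else b$end
    gap_e <- if (a$strand == "+") b$start else a$start
    others <- genes[genes$chrom == a$chrom &
                      !(genes$gene_id %in% c(a$gene_id, b$gene_id)), ]
    if (gap_e > gap_s &&
        any(others$start < gap_e & others$end > gap_s)) next
    out[[length(out) + 1L]] <- data.frame(
      upstream_gene_id = a$gene_id, downstream_gene_id = b$gene_id,
      chrom = a$chrom, strand = a$strand, distance_bp = as.integer(d),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(upstream_gene_id = character(),
                      downstream_gene_id = character(), chrom = character(),
                      strand = character(), distance_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$upstream_gene_id), ]
}

# Random toy genome of non-overlapping genes for property tests.
random_toy_genes <- function(n, chrom = "chrT", chrom_length = 200000L) {
  starts <- sort(sample.int(chrom_length - 5000L, n))
  genes <- list()
  cursor <- 0L
  for (i in seq_len(n)) {
    s <- max(starts[i], cursor + sample(50:2000, 1L))
    len <- sample(800:3000, 1L)
    if (s + len > chrom_length) break
    genes[[length(genes) + 1L]] <-
      toy_gene(sprintf("tg%03d", i), chrom, s, s + len,
               sample(c("+", "-"), 1L))
    cursor <- s + len
  }
  do.call(rbind_genes, genes)
}

small_beta <- function(values, probe_ids, sample_ids) {
  m <- matrix(values, nrow = length(probe_ids), ncol = length(sample_ids))
  dimnames(m) <- list(probe_ids, sample_ids)
  m
}
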
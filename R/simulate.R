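## Synthetic toy genomes and 450K-style beta matrices.
##
## The generator embodies the generative structure the analysis assumes:
## every gene gets a promoter CGI spanning its TSS, a configurable
## fraction of genes are arranged in tandem pairs with TES-TSS distances
## drawn from a grid, tumor samples receive a distance-decaying
## hypermethylation effect on downstream tandem promoter CGIs, and
## 5'-shores carry a constant offset.  Class means echo the medians seen
## on real 450K data: unmethylated TSS CGIs (~8%), moderately methylated
## gene-body CGIs in normal (~17%) that rise strongly in tumor (~72%),
## high open-sea methylation (~82%), shores near 35% and shelves near
## 75%.  Probe-level noise is a mean-calibrated logit-normal
## perturbation, so the expectation of every probe equals its configured
## class mean exactly.

#' Simulation configuration
#'
#' @param seed integer seed (mandatory).  [simulate_genome()] seeds the
#'   RNG with `seed` and [simulate_beta()] with `seed + 1`.
#' @param n_chromosomes,chrom_length toy genome shape.
#' @param n_genes total genes across chromosomes.
#' @param fraction_tandem fraction of genes arranged in tandem pairs
#'   (pairs use two genes each).
#' @param tandem_distance_grid TES-TSS distances (bp) cycled over the
#'   planted pairs.
#' @param probes_per_island,probes_per_shore,probes_per_shelf,probes_per_gap
#'   probe counts per region.
#' @param mu_tss_cgi,mu_body_cgi_normal,mu_body_cgi_tumor,mu_no_cgir,mu_shore_base,mu_shelf
#'   class mean betas (fractions).
#' @param delta0,lambda tumor tandem effect: downstream promoter CGI
#'   probes gain `delta0 * exp(-d / lambda)` in tumor samples, d the
#'   pair's TES-TSS distance in bp.
#' @param delta_shore offset added to 5'-shore probe means (both groups).
#' @param kappa logit-scale noise s.d. (0 = noise-free).
#' @param n_tumor,n_normal sample counts.
#' @param body_cgi_fraction fraction of genes that also carry a gene-body
#'   CGI.
#' @param alternate_strands force strict strand alternation of
#'   consecutive non-tandem genes (guarantees zero tandem pairs when
#'   `fraction_tandem = 0`).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 2L, chrom_length = 1700000L,
                       n_genes = 150L, fraction_tandem = 0.48,
                       tandem_distance_grid = c(170L, 500L, 1500L, 2500L,
                                                4500L, 7000L),
                       probes_per_island = 6L, probes_per_shore = 4L,
                       probes_per_shelf = 2L, probes_per_gap = 2L,
                       mu_tss_cgi = 0.08, mu_body_cgi_normal = 0.17,
                       mu_body_cgi_tumor = 0.72, mu_no_cgir = 0.82,
                       mu_shore_base = 0.35, mu_shelf = 0.75,
                       delta0 = 0.6, lambda = 1500,
                       delta_shore = 0.15, kappa = 0.45,
                       n_tumor = 3L, n_normal = 2L,
                       body_cgi_fraction = 0.3,
                       alternate_strands = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  mus <- c(cfg$mu_tss_cgi, cfg$mu_body_cgi_normal, cfg$mu_body_cgi_tumor,
           cfg$mu_no_cgir, cfg$mu_shore_base, cfg$mu_shelf)
  if (any(mus < 0 | mus > 1)) stop("class means must be in [0, 1]", call. = FALSE)
  if (cfg$fraction_tandem < 0 || cfg$fraction_tandem > 1) {
    stop("fraction_tandem must be in [0, 1]", call. = FALSE)
  }
  if (cfg$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @noRd
even_positions <- function(start, end, k) {
  ## k roughly evenly spaced integer positions inside [start, end)
  if (end - start < k) k <- max(0L, end - start)
  if (k == 0L) return(integer())
  unique(as.integer(round(seq(start + (end - start) / (2 * k),
                              end - (end - start) / (2 * k),
                              length.out = k))))
}

#' @noRd
uniform_positions <- function(start, end, k) {
  if (end - start < 1L || k < 1L) return(integer())
  sort(unique(as.integer(floor(runif(k, start, end)))))
}

#' Simulate a toy genome
#'
#' Places gene units (tandem pairs and single genes) sequentially along
#' the chromosomes with 10-16 kb spacing, builds promoter and gene-body
#' CpG islands, places probes in islands, shores, shelves and intergenic
#' gaps, and records the ground truth of every planted feature.
#'
#' @param config a [sim_config()].
#' @return list with elements genes, islands, sites, chrom_sizes and
#'   truth (list with `probes` and `pairs` data.frames carrying the
#'   planted class labels, effects and expected betas).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pairs <- as.integer(floor(config$n_genes * config$fraction_tandem / 2))
  n_single <- config$n_genes - 2L * n_pairs
  pair_d <- rep(config$tandem_distance_grid, length.out = n_pairs)
  units <- c(lapply(pair_d, function(d) list(type = "pair", d = d)),
             replicate(n_single, list(type = "single"), simplify = FALSE))
  if (length(units) > 1L) units <- units[sample.int(length(units))]
  strands <- if (config$alternate_strands) {
    rep(c("+", "-"), length.out = length(units))
  } else sample(c("+", "-"), length(units), replace = TRUE)

  genes <- list(); islands <- list(); pairs <- list()
  gi <- 0L
  margin <- 6000L
  chrom_names <- paste0("chrS", seq_len(config$n_chromosomes))
  ch <- 1L
  cursor <- margin

  new_gene <- function(chrom, start, len, strand) {
    gi <<- gi + 1L
    id <- sprintf("g%03d", gi)
    s <- start; e <- start + len
    if (strand == "+") {
      g <- data.frame(gene_id = id, chrom = chrom, start = s, end = e,
                      strand = strand,
                      utr5_start = s, utr5_end = s + 150L,
                      first_exon_start = s, first_exon_end = s + 500L,
                      body_start = s + 500L, body_end = e - 250L,
                      utr3_start = e - 250L, utr3_end = e,
                      stringsAsFactors = FALSE)
      isl <- data.frame(island_id = paste0("cgi_", id), chrom = chrom,
                        start = s - 250L, end = s + 250L,
                        gene_id = id, kind = "promoter",
                        stringsAsFactors = FALSE)
    } else {
      g <- data.frame(gene_id = id, chrom = chrom, start = s, end = e,
                      strand = strand,
                      utr5_start = e - 150L, utr5_end = e,
                      first_exon_start = e - 500L, first_exon_end = e,
                      body_start = s + 250L, body_end = e - 500L,
                      utr3_start = s, utr3_end = s + 250L,
                      stringsAsFactors = FALSE)
      isl <- data.frame(island_id = paste0("cgi_", id), chrom = chrom,
                        start = e - 250L, end = e + 250L,
                        gene_id = id, kind = "promoter",
                        stringsAsFactors = FALSE)
    }
    list(gene = g, island = isl)
  }

  for (i in seq_along(units)) {
    u <- units[[i]]
    strand <- strands[i]
    spacing <- as.integer(round(runif(1, 10000, 16000)))
    l1 <- as.integer(round(runif(1, 2000, 4000)))
    l2 <- as.integer(round(runif(1, 2000, 4000)))
    span <- if (u$type == "pair") spacing + l1 + u$d + l2 else spacing + l1
    while (cursor + span + margin > config$chrom_length) {
      ch <- ch + 1L
      if (ch > config$n_chromosomes) {
        stop("genes do not fit on the configured chromosomes; ",
             "increase chrom_length or n_chromosomes", call. = FALSE)
      }
      cursor <- margin
    }
    cursor <- cursor + spacing
    chrom <- chrom_names[ch]
    if (u$type == "pair") {
      a <- new_gene(chrom, cursor, l1, strand)
      b <- new_gene(chrom, cursor + l1 + u$d, l2, strand)
      genes <- c(genes, list(a$gene, b$gene))
      islands <- c(islands, list(a$island, b$island))
      if (strand == "+") { up <- a; down <- b } else { up <- b; down <- a }
      pairs[[length(pairs) + 1L]] <- data.frame(
        upstream_gene_id = up$gene$gene_id,
        downstream_gene_id = down$gene$gene_id,
        chrom = chrom, strand = strand, distance_bp = u$d,
        downstream_cgi_id = down$island$island_id, stringsAsFactors = FALSE)
      cursor <- cursor + l1 + u$d + l2
    } else {
      a <- new_gene(chrom, cursor, l1, strand)
      genes <- c(genes, list(a$gene))
      islands <- c(islands, list(a$island))
      cursor <- cursor + l1
    }
  }

  genes <- do.call(rbind, genes)
  islands_df <- do.call(rbind, islands)
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(upstream_gene_id = character(), downstream_gene_id = character(),
               chrom = character(), strand = character(),
               distance_bp = integer(), downstream_cgi_id = character(),
               stringsAsFactors = FALSE)

  ## gene-body CGIs for a deterministic-size random subset
  n_body <- as.integer(round(nrow(genes) * config$body_cgi_fraction))
  body_genes <- if (n_body > 0L) {
    genes$gene_id[sample.int(nrow(genes), n_body)]
  } else character()
  for (gid in body_genes) {
    g <- genes[genes$gene_id == gid, ]
    mid <- as.integer(floor((g$body_start + g$body_end) / 2))
    islands_df <- rbind(islands_df, data.frame(
      island_id = paste0("cgi_body_", gid), chrom = g$chrom,
      start = mid - 200L, end = mid + 200L, gene_id = gid, kind = "body",
      stringsAsFactors = FALSE))
  }
  islands_df <- islands_df[order(islands_df$chrom, islands_df$start), ,
                           drop = FALSE]
  rownames(islands_df) <- NULL

  chrom_sizes <- data.frame(chrom = chrom_names,
                            length = rep(config$chrom_length,
                                         config$n_chromosomes),
                            stringsAsFactors = FALSE)

  ## ---- probes with truth labels -------------------------------------
  segments <- segment_cgir_all(islands_df[, c("island_id", "chrom",
                                              "start", "end")], chrom_sizes)
  planted_cgi <- pairs$downstream_cgi_id
  effect <- setNames(config$delta0 * exp(-pairs$distance_bp / config$lambda),
                     planted_cgi)
  probe_rows <- list()
  add_probes <- function(chrom, pos, class, gene_id, island_id, orientation,
                         planted, distance_bp, mu_n, mu_t) {
    if (length(pos) == 0L) return(invisible(NULL))
    probe_rows[[length(probe_rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, class = class, gene_id = gene_id,
      island_id = island_id, orientation = orientation, planted = planted,
      distance_bp = distance_bp, mu_normal = mu_n, mu_tumor = mu_t,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }

  for (i in seq_len(nrow(islands_df))) {
    isl <- islands_df[i, ]
    g <- genes[genes$gene_id == isl$gene_id, ]
    segs <- segments[segments$island_id == isl$island_id, , drop = FALSE]
    is_planted <- isl$island_id %in% planted_cgi
    d_bp <- if (is_planted) {
      pairs$distance_bp[match(isl$island_id, pairs$downstream_cgi_id)]
    } else NA_integer_
    if (isl$kind == "promoter") {
      mu_n <- config$mu_tss_cgi
      mu_t <- config$mu_tss_cgi +
        if (is_planted) unname(effect[isl$island_id]) else 0
      add_probes(isl$chrom, even_positions(isl$start, isl$end,
                                           config$probes_per_island),
                 "tss_cgi", isl$gene_id, isl$island_id, NA_character_,
                 is_planted, d_bp, mu_n, mu_t)
    } else {
      add_probes(isl$chrom, even_positions(isl$start, isl$end,
                                           config$probes_per_island),
                 "body_cgi", isl$gene_id, isl$island_id, NA_character_,
                 FALSE, NA_integer_, config$mu_body_cgi_normal,
                 config$mu_body_cgi_tumor)
    }
    for (lab in c("n_shore", "s_shore")) {
      sh <- segs[segs$label == lab, , drop = FALSE]
      if (nrow(sh) == 0L || sh$end - sh$start < 50L) next
      ori <- orient_shore(lab, g$strand)
      mu <- config$mu_shore_base +
        if (ori == "five_prime") config$delta_shore else 0
      add_probes(sh$chrom, uniform_positions(sh$start, sh$end,
                                             config$probes_per_shore),
                 "shore", isl$gene_id, isl$island_id, ori, FALSE,
                 NA_integer_, mu, mu)
    }
    for (lab in c("n_shelf", "s_shelf")) {
      sh <- segs[segs$label == lab, , drop = FALSE]
      if (nrow(sh) == 0L || sh$end - sh$start < 50L) next
      add_probes(sh$chrom, uniform_positions(sh$start, sh$end,
                                             config$probes_per_shelf),
                 "shelf", isl$gene_id, isl$island_id, NA_character_, FALSE,
                 NA_integer_, config$mu_shelf, config$mu_shelf)
    }
  }

  ## intergenic (no-CGIR) probes: gap midpoints, kept >= 4.5 kb from any
  ## island so they fall outside every CGIR segment
  for (chn in chrom_names) {
    gch <- genes[genes$chrom == chn, , drop = FALSE]
    if (nrow(gch) == 0L) next
    edges <- sort(c(0L, gch$start, gch$end, config$chrom_length))
    starts <- edges[seq(1L, length(edges), by = 2L)]
    ends <- edges[seq(2L, length(edges), by = 2L)]
    for (k in seq_along(starts)) {
      centre <- as.integer(floor((starts[k] + ends[k]) / 2))
      half <- floor((ends[k] - starts[k]) / 2) - 4600L
      if (half < 50L) next
      pos <- uniform_positions(centre - half, centre + half,
                               config$probes_per_gap)
      isl_ch <- islands_df[islands_df$chrom == chn, , drop = FALSE]
      near <- vapply(pos, function(p) {
        any(p >= isl_ch$start - 4500L & p < isl_ch$end + 4500L)
      }, logical(1L))
      add_probes(chn, pos[!near], "no_cgir", NA_character_, NA_character_,
                 NA_character_, FALSE, NA_integer_, config$mu_no_cgir,
                 config$mu_no_cgir)
    }
  }

  truth_probes <- do.call(rbind, probe_rows)
  truth_probes <- truth_probes[order(truth_probes$chrom, truth_probes$pos), ,
                               drop = FALSE]
  truth_probes <- truth_probes[!duplicated(truth_probes[, c("chrom", "pos")]), ,
                               drop = FALSE]
  truth_probes <- data.frame(probe_id = sprintf("cg%06d",
                                                seq_len(nrow(truth_probes))),
                             truth_probes, stringsAsFactors = FALSE)
  rownames(truth_probes) <- NULL

  ## clip expectations that drifted outside [0, 1]
  eps <- 1e-3
  n_clip <- sum(truth_probes$mu_normal < eps | truth_probes$mu_normal > 1 - eps |
                  truth_probes$mu_tumor < eps | truth_probes$mu_tumor > 1 - eps)
  if (n_clip > 0L) {
    warning(n_clip, " probe expectation(s) clipped into [0.001, 0.999]")
  }
  truth_probes$mu_normal <- pmin(pmax(truth_probes$mu_normal, eps), 1 - eps)
  truth_probes$mu_tumor <- pmin(pmax(truth_probes$mu_tumor, eps), 1 - eps)

  sites <- cpg_sites(truth_probes$probe_id, truth_probes$chrom,
                     truth_probes$pos)
  list(genes = genes,
       islands = islands_df[, c("island_id", "chrom", "start", "end")],
       island_kinds = islands_df[, c("island_id", "gene_id", "kind")],
       sites = sites, chrom_sizes = chrom_sizes,
       truth = list(probes = truth_probes, pairs = pairs))
}

#' Mean-calibrating location of a logit-normal draw
#'
#' Solves for m such that `E[plogis(m + kappa * Z)] = mu` (Z standard
#' normal), by quadrature and root finding, so that simulated probes hit
#' their configured class mean in expectation.
#'
#' @param mu target means in (0, 1) (vectorized).
#' @param kappa logit-scale s.d.
#' @return locations m, same length as mu.
#' @export
logitnorm_location <- function(mu, kappa) {
  if (kappa == 0) return(qlogis(mu))
  z <- seq(-8, 8, length.out = 161)
  w <- dnorm(z); w <- w / sum(w)
  solve_one <- function(m0) {
    uniroot(function(m) sum(w * plogis(m + kappa * z)) - plogis(m0),
            interval = qlogis(plogis(m0)) + c(-6, 6) * max(kappa, 1),
            tol = 1e-10)$root
  }
  um <- unique(mu)
  loc <- vapply(qlogis(um), solve_one, numeric(1L))
  loc[match(mu, um)]
}

#' Simulate a beta matrix over a toy genome
#'
#' Each probe's expected beta is its truth-table class mean (tumor or
#' normal, already including the 5'-shore offset and the tandem
#' distance effect).  Realized values are mean-calibrated logit-normal
#' draws with logit-scale s.d. `kappa`; `kappa = 0` returns the
#' expectations exactly.
#'
#' @param genome output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return list with `beta` (probes x samples fraction matrix) and
#'   `sheet` (sample_id, group).
#' @export
simulate_beta <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tp <- genome$truth$probes
  sample_ids <- c(sprintf("T%d", seq_len(config$n_tumor)),
                  sprintf("N%d", seq_len(config$n_normal)))
  groups <- c(rep("tumor", config$n_tumor), rep("normal", config$n_normal))
  mu <- cbind(matrix(rep(tp$mu_tumor, config$n_tumor), ncol = config$n_tumor),
              matrix(rep(tp$mu_normal, config$n_normal),
                     ncol = config$n_normal))
  if (config$kappa == 0) {
    beta <- mu
  } else {
    loc <- matrix(logitnorm_location(as.vector(mu), config$kappa),
                  nrow = nrow(mu))
    beta <- plogis(loc + config$kappa * matrix(rnorm(length(mu)),
                                               nrow = nrow(mu)))
  }
  dimnames(beta) <- list(tp$probe_id, sample_ids)
  list(beta = beta,
       sheet = data.frame(sample_id = sample_ids, group = groups,
                          stringsAsFactors = FALSE))
}
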
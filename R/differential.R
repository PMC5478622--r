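## Tumor-vs-normal hypermethylation scoring and the statistical contracts.
##
## Scores are computed on unrounded per-sample region means (percent
## scale) and only rounded half-up at report time; published tables are
## consistent with round-half-up (e.g. a 84.5 difference printed as 85),
## not banker's rounding.

#' Round half away from zero toward +Inf ("round half up")
#'
#' `round_half_up(0.5) == 1`, `round_half_up(84.5) == 85`; unlike base
#' [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal digits to keep (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Score regions for tumor-specific hypermethylation
#'
#' For each region (row of `means_pct`) the tumor mean is the mean of
#' the tumor samples' region means, likewise the normal mean, and the
#' difference is tumor minus normal, all on unrounded percent values.
#'
#' @param means_pct regions x samples numeric matrix of per-sample region
#'   mean methylation in percent (rownames = region ids).
#' @param tumor_ids,normal_ids sample id vectors (>= 1 each).
#' @param gene_symbols optional named character vector mapping region id
#'   to associated gene symbol(s).
#' @return data.frame with columns region_id, gene, per-sample percent
#'   columns for the tumor samples, tumor_mean, normal_mean, difference
#'   (all unrounded), and `complete` (FALSE when any required sample's
#'   value is missing).
#' @export
hypermeth_score <- function(means_pct, tumor_ids, normal_ids,
                            gene_symbols = NULL) {
  if (length(tumor_ids) < 1L || length(normal_ids) < 1L) {
    stop("need >= 1 tumor and >= 1 normal sample", call. = FALSE)
  }
  missing <- setdiff(c(tumor_ids, normal_ids), colnames(means_pct))
  if (length(missing) > 0L) {
    stop("samples absent from means matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tum <- means_pct[, tumor_ids, drop = FALSE]
  nor <- means_pct[, normal_ids, drop = FALSE]
  rec <- data.frame(region_id = rownames(means_pct),
                    stringsAsFactors = FALSE)
  rec$gene <- if (is.null(gene_symbols)) NA_character_ else
    unname(gene_symbols[rec$region_id])
  for (s in tumor_ids) rec[[s]] <- tum[, s]
  rec$tumor_mean <- rowMeans(tum)
  rec$normal_mean <- rowMeans(nor)
  rec$difference <- rec$tumor_mean - rec$normal_mean
  rec$complete <- stats::complete.cases(tum) & stats::complete.cases(nor)
  rownames(rec) <- NULL
  rec
}

#' Rank hypermethylated regions
#'
#' Descending by difference, ties broken by descending tumor mean, then
#' lexicographically by region id; the top `n` complete records are
#' returned (all of them, with a message, when fewer than `n` exist).
#'
#' @param records data.frame from [hypermeth_score()].
#' @param n number of top records to keep (default 20).
#' @return ordered data.frame of at most `n` rows.
#' @export
rank_hypermethylated <- function(records, n = 20L) {
  records <- records[records$complete, , drop = FALSE]
  ord <- order(-records$difference, -records$tumor_mean, records$region_id)
  records <- records[ord, , drop = FALSE]
  if (n > nrow(records)) {
    message("requested top ", n, " but only ", nrow(records), " records")
    n <- nrow(records)
  }
  res <- head(records, n)
  rownames(res) <- NULL
  res
}

#' Format a ranked table with printed-style integer percentages
#'
#' @param records (ranked) data.frame from [hypermeth_score()].
#' @return the same frame with per-sample, tumor_mean, normal_mean and
#'   difference columns rounded half-up to integers.
#' @export
hypermeth_report <- function(records) {
  num <- setdiff(names(records)[vapply(records, is.numeric, logical(1L))],
                 character())
  for (cn in num) records[[cn]] <- round_half_up(records[[cn]])
  records
}

#' Significance stars
#'
#' @param p p-value vector.
#' @return "***" for p < 0.001, "**" for p < 0.01, "*" for p < 0.05,
#'   "" otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @noRd
ranksum_exact <- function(a, b) {
  ## Exact two-sided rank-sum p by full enumeration of group assignments,
  ## with midranks so ties are handled exactly.  Statistic = rank sum of
  ## group a; p = Pr(|W - E W| >= |W_obs - E W|) over all C(n, na)
  ## equally likely assignments.
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  w_all <- colSums(matrix(r[combs], nrow = na))
  mu <- mean(w_all)
  tol <- 1e-9
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - tol)
  list(statistic = w_obs, p = p)
}

#' Two-group comparison tests
#'
#' The tests used for group contrasts: Wilcoxon rank-sum (exact by full
#' enumeration with midrank tie handling when the pooled sample is small,
#' normal approximation with continuity correction otherwise), Student's
#' unpaired t-test (equal variances), and the chi-square test without
#' continuity correction (for a counts table passed as `a`).
#'
#' @param a,b numeric value vectors; for `chi_square`, `a` is the counts
#'   matrix and `b` is ignored.
#' @param test one of "wilcoxon_ranksum", "t_unpaired", "chi_square".
#' @param exact_max largest pooled sample size for which the rank-sum p
#'   is computed by exhaustive enumeration (default 10).
#' @return list with statistic, p, stars, method.  Degenerate input
#'   (e.g. zero variance in the t-test) yields p = 1 when the group
#'   means are equal and p = 0 otherwise, never an error.
#' @export
compare_groups <- function(a, b = NULL,
                           test = c("wilcoxon_ranksum", "t_unpaired", "chi_square"),
                           exact_max = 10L) {
  test <- match.arg(test)
  if (test == "chi_square") {
    tab <- as.matrix(a)
    ct <- stats::chisq.test(tab, correct = FALSE)
    return(list(statistic = unname(ct$statistic), p = unname(ct$p.value),
                stars = significance_stars(unname(ct$p.value)),
                method = "chi_square"))
  }
  if (length(a) < 2L || length(b) < 2L) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  if (test == "wilcoxon_ranksum") {
    if (length(a) + length(b) <= exact_max) {
      res <- ranksum_exact(a, b)
      return(list(statistic = res$statistic, p = res$p,
                  stars = significance_stars(res$p),
                  method = "wilcoxon_ranksum_exact"))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    return(list(statistic = unname(wt$statistic), p = unname(wt$p.value),
                stars = significance_stars(unname(wt$p.value)),
                method = "wilcoxon_ranksum_normal"))
  }
  ## Student's unpaired t-test, equal variances; degenerate input handled
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(statistic = 0, p = p, stars = significance_stars(p),
                method = "t_unpaired_degenerate"))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p = unname(tt$p.value),
       stars = significance_stars(unname(tt$p.value)), method = "t_unpaired")
}

#' 5'- vs 3'-shore methylation asymmetry
#'
#' Pools shore-probe betas by orientation (five_prime vs three_prime)
#' within the chosen region class (promoter or coding), per group, and
#' tests the orientation contrast with the rank-sum test.  By default
#' the comparison is unpaired over pooled probes; `paired = TRUE`
#' instead compares per-gene mean 5'- and 3'-shore betas with the
#' signed-rank test (genes with both sides present).
#'
#' @param beta beta matrix.
#' @param annotations annotation data.frame from [annotate_probes()].
#' @param region_class "promoter" or "coding".
#' @param sheet sample sheet.
#' @param paired use the per-gene paired signed-rank variant.
#' @return list with `summary` (group, orientation, n_probes, n_values,
#'   median, mean), `tests` (per group: delta_median, statistic, p,
#'   stars) and `empty` flag (TRUE when no shore probe matched).
#' @export
shore_asymmetry_analysis <- function(beta, annotations,
                                     region_class = c("promoter", "coding"),
                                     sheet, paired = FALSE) {
  rc <- match.arg(region_class)
  check_sheet_matches(beta, sheet)
  ann <- annotations[!is.na(annotations$shore_orientation) &
                       !is.na(annotations$region_class) &
                       annotations$region_class == rc &
                       annotations$probe_id %in% rownames(beta), , drop = FALSE]
  if (nrow(ann) == 0L) {
    message("no shore probes in region class ", rc)
    return(list(summary = data.frame(), tests = data.frame(), empty = TRUE))
  }
  groups <- sheet$group[match(colnames(beta), sheet$sample_id)]
  rows <- list(); tests <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    pool <- list()
    for (ori in c("five_prime", "three_prime")) {
      probes <- unique(ann$probe_id[ann$shore_orientation == ori])
      v <- if (length(probes)) as.vector(beta[probes, cols, drop = FALSE]) else numeric()
      v <- v[!is.na(v)]
      pool[[ori]] <- v
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, orientation = ori, n_probes = length(probes),
        n_values = length(v),
        median = if (length(v)) median(v) else NA_real_,
        mean = if (length(v)) mean(v) else NA_real_, stringsAsFactors = FALSE)
    }
    delta <- if (length(pool$five_prime) && length(pool$three_prime)) {
      median(pool$five_prime) - median(pool$three_prime)
    } else NA_real_
    test_row <- data.frame(group = g, delta_median = delta,
                           statistic = NA_real_, p = NA_real_, stars = "",
                           stringsAsFactors = FALSE)
    if (!paired) {
      if (length(pool$five_prime) >= 2L && length(pool$three_prime) >= 2L) {
        ct <- compare_groups(pool$five_prime, pool$three_prime,
                             "wilcoxon_ranksum")
        test_row$statistic <- ct$statistic; test_row$p <- ct$p
        test_row$stars <- ct$stars
      }
    } else {
      per_gene <- lapply(c("five_prime", "three_prime"), function(ori) {
        sub <- ann[ann$shore_orientation == ori, , drop = FALSE]
        vapply(split(sub$probe_id, sub$gene_id), function(p) {
          mean(beta[unique(p), cols], na.rm = TRUE)
        }, numeric(1L))
      })
      shared <- intersect(names(per_gene[[1L]]), names(per_gene[[2L]]))
      if (length(shared) >= 2L) {
        wt <- suppressWarnings(stats::wilcox.test(per_gene[[1L]][shared],
                                                  per_gene[[2L]][shared],
                                                  paired = TRUE))
        test_row$statistic <- unname(wt$statistic)
        test_row$p <- unname(wt$p.value)
        test_row$stars <- significance_stars(test_row$p)
      }
    }
    tests[[length(tests) + 1L]] <- test_row
  }
  list(summary = do.call(rbind, rows), tests = do.call(rbind, tests),
       empty = FALSE)
}

#' Methylation of downstream tandem promoters by TES-TSS distance bin
#'
#' For each tandem pair with a downstream CGI, the CGI's per-sample mean
#' beta is averaged within each sample group; per bin these per-pair
#' group means form the pooled distributions.  The near-vs-far contrast
#' compares, within `contrast_group`, pairs at distance <= `near_max`
#' against pairs at distance > `far_min` by rank-sum.  Reference
#' distributions are also returned: pooled betas of all CGI-located
#' probes ("all CpGs") and per-island means of all TSS-associated
#' islands ("all TSS").
#'
#' @param pairs_binned pair data.frame with downstream_cgi_id and bin
#'   columns (see [attach_downstream_cgi()], [bin_pairs_by_distance()]).
#' @param beta beta matrix.
#' @param membership named list island_id -> member (island) probe ids.
#' @param sheet sample sheet.
#' @param tss_islands character vector of TSS-associated island ids for
#'   the "all TSS" reference.
#' @param contrast_group group label whose values enter the contrast
#'   (default "tumor").
#' @param near_max,far_min contrast cut points in bp (defaults 2000 and
#'   4000: <= 2 kb vs > 4 kb).
#' @return list with `per_bin` summary data.frame (bin, group, n_pairs,
#'   median, mean), `bin_values` (bin -> group -> per-pair means),
#'   `contrast` (statistic, p, stars, n_near, n_far, untestable flag)
#'   and `references`.
#' @export
distance_bin_analysis <- function(pairs_binned, beta, membership, sheet,
                                  tss_islands = character(),
                                  contrast_group = "tumor",
                                  near_max = 2000L, far_min = 4000L) {
  check_sheet_matches(beta, sheet)
  pairs <- pairs_binned[!is.na(pairs_binned$downstream_cgi_id), , drop = FALSE]
  groups <- sheet$group[match(colnames(beta), sheet$sample_id)]
  rm <- region_means_matrix(beta, membership)
  pair_means <- list()   # per group: numeric vector along pairs
  for (g in unique(groups)) {
    cols <- which(groups == g)
    m <- rm$means[, cols, drop = FALSE]
    pair_means[[g]] <- rowMeans(m, na.rm = TRUE)[pairs$downstream_cgi_id]
  }
  bins <- levels(pairs$bin)
  rows <- list(); bin_values <- list()
  for (b in bins) {
    sel <- which(as.character(pairs$bin) == b)
    bin_values[[b]] <- lapply(pair_means, function(v) {
      x <- unname(v[sel]); x[!is.na(x)]
    })
    for (g in names(pair_means)) {
      v <- bin_values[[b]][[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, group = g, n_pairs = length(v),
        median = if (length(v)) median(v) else NA_real_,
        mean = if (length(v)) mean(v) else NA_real_, stringsAsFactors = FALSE)
    }
  }
  v <- pair_means[[contrast_group]]
  near <- v[pairs$distance_bp <= near_max]; near <- near[!is.na(near)]
  far <- v[pairs$distance_bp > far_min]; far <- far[!is.na(far)]
  contrast <- list(n_near = length(near), n_far = length(far),
                   statistic = NA_real_, p = NA_real_, stars = "",
                   untestable = length(near) < 2L || length(far) < 2L)
  if (!contrast$untestable) {
    ct <- compare_groups(near, far, "wilcoxon_ranksum")
    contrast$statistic <- ct$statistic; contrast$p <- ct$p
    contrast$stars <- ct$stars
  }
  all_cgi_probes <- unique(unlist(membership))
  all_cgi_probes <- intersect(all_cgi_probes, rownames(beta))
  references <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    ac <- as.vector(beta[all_cgi_probes, cols, drop = FALSE])
    tssm <- rm$means[intersect(tss_islands, rownames(rm$means)), cols,
                     drop = FALSE]
    references[[g]] <- list(all_cpgs = ac[!is.na(ac)],
                            all_tss = rowMeans(tssm, na.rm = TRUE))
  }
  per_bin <- if (length(rows)) do.call(rbind, rows) else data.frame()
  list(per_bin = per_bin, bin_values = bin_values, contrast = contrast,
       references = references)
}
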
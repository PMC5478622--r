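## Beta-value handling and region/group aggregation.  A beta matrix is a
## plain numeric matrix (probes x samples) of fractions in [0, 1] with NA
## for missing; the sample sheet maps samples to groups (tumor/normal or
## any free labels).  Aggregation is an unweighted mean over member
## probes, then a missing-aware group statistic over samples.

#' Read a beta-value matrix from TSV
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Lines starting with `#` are ignored.
#'
#' @param path TSV file path.
#' @param scale "fraction" for values already in [0, 1], "percent" for
#'   0-100 input (divided by 100 on read).
#' @return numeric matrix (probes x samples), rownames = probe ids.
#' @export
read_beta_matrix <- function(path, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("beta matrix needs a probe column and >= 1 sample", call. = FALSE)
  probes <- as.character(df[[1L]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe ids in beta matrix: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "), call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(non_num)) {
    stop("non-numeric beta values in sample(s): ",
         paste(names(vals)[non_num], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- probes
  if (scale == "percent") m <- m / 100
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("beta values outside [0, 1] after scaling", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids", call. = FALSE)
  m
}

#' Read a sample sheet
#'
#' @param path CSV file with columns sample_id, group.
#' @return data.frame with columns sample_id, group.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("sample sheet needs columns sample_id, group", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sheet", call. = FALSE)
  df[, c("sample_id", "group")]
}

#' @noRd
check_sheet_matches <- function(beta, sheet) {
  missing <- setdiff(colnames(beta), sheet$sample_id)
  if (length(missing) > 0L) {
    stop("samples absent from sheet: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean beta of a region's member probes, per sample
#'
#' Arithmetic mean over the non-missing member values; NA when every
#' member is missing in that sample.
#'
#' @param beta beta matrix (probes x samples).
#' @param member_probes non-empty character vector of probe ids.
#' @return named numeric vector, one value per sample.
#' @export
region_mean <- function(beta, member_probes) {
  if (length(member_probes) == 0L) stop("empty member probe set", call. = FALSE)
  missing <- setdiff(member_probes, rownames(beta))
  if (length(missing) > 0L) {
    stop("member probes absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- colMeans(beta[member_probes, , drop = FALSE], na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  v
}

#' Per-region per-sample mean betas
#'
#' @param beta beta matrix.
#' @param membership named list mapping region_id to member probe ids;
#'   probes absent from the matrix are ignored (regions with no present
#'   probe are dropped).
#' @return list with `means` (regions x samples matrix) and `n_probes`
#'   (probes used per region).
#' @export
region_means_matrix <- function(beta, membership) {
  membership <- lapply(membership, function(p) intersect(p, rownames(beta)))
  membership <- membership[lengths(membership) > 0L]
  means <- t(vapply(membership,
                    function(p) colMeans(beta[p, , drop = FALSE], na.rm = TRUE),
                    numeric(ncol(beta))))
  if (ncol(beta) == 1L) {                       # vapply drops to vector shape
    means <- matrix(means, ncol = 1L, dimnames = list(names(membership),
                                                      colnames(beta)))
  } else colnames(means) <- colnames(beta)
  means[is.nan(means)] <- NA_real_
  list(means = means, n_probes = lengths(membership))
}

#' Group-wise summary of per-sample values
#'
#' @param values named numeric vector (names = sample ids).
#' @param sheet sample sheet data.frame.
#' @param stat "median" or "mean".
#' @return named numeric vector, one statistic per group.
#' @export
group_summary <- function(values, sheet, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  unknown <- setdiff(names(values), sheet$sample_id)
  if (length(unknown) > 0L) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  f <- if (stat == "median") function(x) median(x, na.rm = TRUE)
       else function(x) mean(x, na.rm = TRUE)
  groups <- sheet$group[match(names(values), sheet$sample_id)]
  vapply(split(values, groups), f, numeric(1L))
}

#' Stratified pooled beta distributions
#'
#' Pools probe-level betas per stratum and group.  With
#' `by = "cgir_tss"` each probe contributes to exactly one stratum,
#' cgir_label x TSS proximity (the probe-level annotation rows are
#' deduplicated).  With `by = "category_orientation"` strata are
#' gene-context category x shore orientation over the probe-by-gene
#' annotation rows.  Probes in the matrix but absent from the annotation
#' are counted, reported and excluded.
#'
#' @param beta beta matrix.
#' @param annotations annotation data.frame from [annotate_probes()].
#' @param sheet sample sheet.
#' @param by stratification scheme.
#' @return list with `summary` (data.frame stratum, group, n_probes,
#'   n_values, median, mean), `values` (named list stratum -> group ->
#'   pooled numeric vector) and `n_unannotated`.
#' @export
stratified_distribution <- function(beta, annotations, sheet,
                                    by = c("cgir_tss", "category_orientation")) {
  by <- match.arg(by)
  check_sheet_matches(beta, sheet)
  unannot <- setdiff(rownames(beta), annotations$probe_id)
  if (length(unannot) > 0L) {
    message(length(unannot), " probe(s) in matrix but not annotated; excluded")
  }
  if (by == "cgir_tss") {
    ann <- annotations[!duplicated(annotations$probe_id),
                       c("probe_id", "cgir_label", "tss_proximal"),
                       drop = FALSE]
    ann$stratum <- paste0(ann$cgir_label, ifelse(ann$tss_proximal,
                                                 ":tss", ":no_tss"))
  } else {
    ann <- annotations[!is.na(annotations$category), , drop = FALSE]
    ann$stratum <- paste0(ann$category,
                          ifelse(is.na(ann$shore_orientation), "",
                                 paste0(":", ann$shore_orientation)))
    ann <- ann[!duplicated(ann[, c("probe_id", "stratum")]), , drop = FALSE]
  }
  ann <- ann[ann$probe_id %in% rownames(beta), , drop = FALSE]
  groups <- sheet$group[match(colnames(beta), sheet$sample_id)]
  strata <- sort(unique(ann$stratum))
  values <- list(); rows <- list()
  for (s in strata) {
    probes <- unique(ann$probe_id[ann$stratum == s])
    sub <- beta[probes, , drop = FALSE]
    values[[s]] <- lapply(split(seq_along(groups), groups), function(j) {
      v <- as.vector(sub[, j, drop = FALSE]); v[!is.na(v)]
    })
    for (g in names(values[[s]])) {
      v <- values[[s]][[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, group = g, n_probes = length(probes),
        n_values = length(v),
        median = if (length(v)) median(v) else NA_real_,
        mean = if (length(v)) mean(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(), group = character(),
               n_probes = integer(), n_values = integer(),
               median = numeric(), mean = numeric(), stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, values = values, n_unannotated = length(unannot))
}
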
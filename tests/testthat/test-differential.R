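# Hypermethylation scoring/ranking and the statistical test contracts.

test_that("published per-line promoter methylation values reproduce printed means and differences", {
  # per-cell-line CGI promoter methylation (%) with the normal reference,
  # as printed for four well-known hypermethylated genes
  m <- matrix(c(99, 97, 99, 2, NA,      # P2RY6 (three lines vs one normal)
                91, 93, 91, 13, NA),    # RASSF1A, same design
              nrow = 2, byrow = TRUE,
              dimnames = list(c("P2RY6", "RASSF1A"),
                              c("L1", "L2", "L3", "N1", "N2")))
  rec <- hypermeth_score(m[, 1:4], c("L1", "L2", "L3"), "N1")
  rep_ <- hypermeth_report(rec)
  expect_equal(rep_$tumor_mean, c(98, 92))
  expect_equal(rep_$difference, c(96, 79))

  # two-normal design (downstream tandem genes table): mean normal and
  # difference columns, including the half-up case 84.5 -> 85
  m2 <- matrix(c(82, 94, 94, 6, 5,     # AOX1
                 93, 91, 91, 7, 8,     # RASSF1A
                 51, 38, 51, 17, 15),  # CDKN1C
               nrow = 3, byrow = TRUE,
               dimnames = list(c("AOX1", "RASSF1A", "CDKN1C"),
                               c("L1", "L2", "L3", "N1", "N2")))
  rec2 <- hypermeth_score(m2, c("L1", "L2", "L3"), c("N1", "N2"))
  rep2 <- hypermeth_report(rec2)
  expect_equal(rep2$tumor_mean, c(90, 92, 47))
  expect_equal(rep2$normal_mean, c(6, 8, 16))
  expect_equal(rep2$difference, c(85, 84, 31))
})

test_that("identical tumor and normal values give difference zero; labels swap flips sign", {
  m <- matrix(c(50, 50, 50, 50), nrow = 1,
              dimnames = list("r1", c("t1", "t2", "n1", "n2")))
  rec <- hypermeth_score(m, c("t1", "t2"), c("n1", "n2"))
  expect_equal(rec$difference, 0)
  m2 <- matrix(c(70, 72, 10, 12), nrow = 1,
               dimnames = list("r1", c("t1", "t2", "n1", "n2")))
  a <- hypermeth_score(m2, c("t1", "t2"), c("n1", "n2"))
  b <- hypermeth_score(m2, c("n1", "n2"), c("t1", "t2"))
  expect_equal(a$difference, -b$difference)
  # sample-order invariance
  c_ <- hypermeth_score(m2, c("t2", "t1"), c("n2", "n1"))
  expect_equal(a$tumor_mean, c_$tumor_mean)
})

test_that("round_half_up rounds halves upward where banker's rounding would not", {
  expect_equal(round_half_up(84.5), 85)
  expect_equal(round_half_up(5.5), 6)
  expect_equal(round_half_up(c(2.4, 2.5, 3.5)), c(2, 3, 4))
  expect_equal(round_half_up(c(0.125, 0.135), digits = 2), c(0.13, 0.14))
})

test_that("ranking orders by difference, then tumor mean, then region id", {
  rec <- data.frame(region_id = c("rA", "rB", "rC"),
                    tumor_mean = c(98, 97, 96),
                    normal_mean = c(2, 4, 3),
                    difference = c(96, 93, 93),
                    complete = TRUE, stringsAsFactors = FALSE)
  got <- rank_hypermethylated(rec, n = 3)
  expect_equal(got$region_id, c("rA", "rB", "rC"))
  expect_equal(rank_hypermethylated(rec[1, ], n = 1)$region_id, "rA")
  expect_message(all3 <- rank_hypermethylated(rec, n = 10), "only 3")
  expect_equal(nrow(all3), 3L)
})

test_that("ranking agrees with a brute-force sort oracle and is stable under duplication", {
  set.seed(17)
  rec <- data.frame(region_id = sprintf("r%03d", 1:100),
                    tumor_mean = round(runif(100, 50, 99)),
                    normal_mean = round(runif(100, 1, 40)),
                    complete = TRUE, stringsAsFactors = FALSE)
  rec$difference <- rec$tumor_mean - rec$normal_mean
  got <- rank_hypermethylated(rec, n = 100)
  # oracle: repeatedly extract the maximum under the documented total order
  pool <- rec; want <- character()
  better <- function(i, j) {
    if (pool$difference[i] != pool$difference[j])
      return(pool$difference[i] > pool$difference[j])
    if (pool$tumor_mean[i] != pool$tumor_mean[j])
      return(pool$tumor_mean[i] > pool$tumor_mean[j])
    pool$region_id[i] < pool$region_id[j]
  }
  while (nrow(pool) > 0L) {
    best <- 1L
    for (i in seq_len(nrow(pool))) if (better(i, best)) best <- i
    want <- c(want, pool$region_id[best])
    pool <- pool[-best, , drop = FALSE]
  }
  expect_equal(got$region_id, want)
  # duplicated records keep a deterministic total order
  dup <- rbind(rec, rec)
  expect_equal(nrow(rank_hypermethylated(dup, n = 200)), 200L)
})

test_that("rank-sum p equals exhaustive permutation p on all small inputs", {
  enumerate_p <- function(a, b) {
    pooled <- c(a, b); n <- length(pooled); na <- length(a)
    r <- rank(pooled)
    stats <- c()
    idx <- utils::combn(n, na)
    for (k in seq_len(ncol(idx))) stats <- c(stats, sum(r[idx[, k]]))
    mu <- mean(stats)
    obs <- sum(r[seq_len(na)])
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(77)
  for (rep in 1:30) {
    na <- sample(2:4, 1L); nb <- sample(2:4, 1L)
    a <- sample(1:5, na, replace = TRUE)     # replacement forces ties
    b <- sample(1:5, nb, replace = TRUE)
    got <- compare_groups(a, b, "wilcoxon_ranksum")
    expect_equal(got$p, enumerate_p(a, b))
  }
  # identical samples: all assignments equivalent -> p = 1
  expect_equal(compare_groups(c(3, 3, 3), c(3, 3, 3), "wilcoxon_ranksum")$p, 1)
  # {1,2} vs {3,4}: 2 of 6 assignments are as extreme -> 1/3
  expect_equal(compare_groups(c(1, 2), c(3, 4), "wilcoxon_ranksum")$p, 1 / 3)
})

test_that("rank-sum without ties matches the classical exact distribution", {
  set.seed(5)
  for (rep in 1:10) {
    a <- runif(4); b <- runif(3)   # continuous, so ties are impossible
    got <- compare_groups(a, b, "wilcoxon_ranksum")
    want <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(got$p, want)
  }
})

test_that("chi-square on a perfectly separated 2x2 table gives the hand-computed 20", {
  tab <- matrix(c(10, 0, 0, 10), nrow = 2)
  got <- compare_groups(tab, test = "chi_square")
  # oracle: sum over cells of (O - E)^2 / E with E from the margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E))
  expect_equal(got$statistic, 20)
  expect_equal(got$stars, "***")
})

test_that("t-test handles zero-variance input without crashing", {
  expect_equal(compare_groups(c(5, 5), c(5, 5), "t_unpaired")$p, 1)
  expect_equal(compare_groups(c(5, 5), c(7, 7), "t_unpaired")$p, 0)
  reg <- compare_groups(c(1, 2, 3), c(4, 5, 7), "t_unpaired")
  want <- stats::t.test(c(1, 2, 3), c(4, 5, 7), var.equal = TRUE)
  expect_equal(reg$p, want$p.value)
})

test_that("significance stars follow the 0.05/0.01/0.001 thresholds", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.004, 0.0004)),
               c("", "*", "**", "***"))
})

test_that("one shore probe per side reduces the asymmetry output to those values", {
  isl <- cpg_islands("i1", "chrT", 10000, 10500)
  genes <- toy_gene("g1", "chrT", 10200, 14000, "+")
  # one probe in the n-shore (five_prime, TSS1500 of g1) and one in the
  # s-shore (three_prime via first exon/body context)
  sites <- cpg_sites(c("p5", "p3"), "chrT", c(9500, 10600))
  sizes <- data.frame(chrom = "chrT", length = 50000)
  ann <- annotate_probes(sites, isl, genes, sizes)
  beta <- small_beta(c(0.6, 0.3), c("p5", "p3"), "s1")
  sheet <- data.frame(sample_id = "s1", group = "tumor")
  sa <- shore_asymmetry_analysis(beta, ann, "promoter", sheet)
  expect_false(sa$empty)
  s <- sa$summary
  expect_equal(s$median[s$orientation == "five_prime"], 0.6)
  expect_equal(s$median[s$orientation == "three_prime"], 0.3)
  expect_equal(sa$tests$delta_median, 0.3)
  # no shore probes at all -> empty result, not an error
  far <- cpg_sites("pX", "chrT", 40000)
  annX <- annotate_probes(far, isl, genes, sizes)
  betaX <- small_beta(0.5, "pX", "s1")
  expect_message(saX <- shore_asymmetry_analysis(betaX, annX, "promoter",
                                                 sheet), "no shore probes")
  expect_true(saX$empty)
})

test_that("distance-bin contrast flags untestable input instead of failing", {
  pairs <- data.frame(upstream_gene_id = "u", downstream_gene_id = "d",
                      chrom = "chrT", strand = "+", distance_bp = 170L,
                      downstream_cgi_id = NA_character_,
                      stringsAsFactors = FALSE)
  pairs <- bin_pairs_by_distance(pairs)
  beta <- small_beta(c(0.1, 0.2), c("a", "b"), "s1")
  sheet <- data.frame(sample_id = "s1", group = "tumor")
  res <- distance_bin_analysis(pairs, beta, list(i1 = c("a", "b")), sheet)
  expect_true(res$contrast$untestable)
})
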
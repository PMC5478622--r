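# CGIR segmentation, probe classification, gene context, TSS proximity,
# shore orientation and promoter/coding classes.

test_that("segmentation emits 2 kb shores and shelves around an isolated island", {
  isl <- cpg_islands("cgi1", "chrT", 10000, 10500)
  seg <- segment_cgir(isl, 100000)
  expect_equal(seg$label,
               c("n_shelf", "n_shore", "island", "s_shore", "s_shelf"))
  expect_equal(seg$start, c(6000, 8000, 10000, 10500, 12500))
  expect_equal(seg$end, c(8000, 10000, 10500, 12500, 14500))
})

test_that("segmentation clips at chromosome bounds and drops empty segments", {
  isl <- cpg_islands("e", "chrT", 500, 1000)
  seg <- segment_cgir(isl, 100000)
  expect_false("n_shelf" %in% seg$label)       # zero length after clipping
  n_shore <- seg[seg$label == "n_shore", ]
  expect_equal(c(n_shore$start, n_shore$end), c(0, 500))
  # island at the very end of the chromosome
  isl2 <- cpg_islands("f", "chrT", 99000, 99500)
  seg2 <- segment_cgir(isl2, 100000)
  s_shore <- seg2[seg2$label == "s_shore", ]
  expect_equal(c(s_shore$start, s_shore$end), c(99500, 100000))
  expect_false("s_shelf" %in% seg2$label)
})

test_that("facing flanks of nearby islands are truncated at the gap midpoint", {
  isl <- cpg_islands(c("a", "b"), "chrT", c(10000, 13500), c(10500, 14000))
  seg <- segment_cgir(isl, 100000)
  a_s_shore <- seg[seg$island_id == "a" & seg$label == "s_shore", ]
  b_n_shore <- seg[seg$island_id == "b" & seg$label == "n_shore", ]
  expect_equal(c(a_s_shore$start, a_s_shore$end), c(10500, 12000))
  expect_equal(c(b_n_shore$start, b_n_shore$end), c(12000, 13500))
  expect_false("s_shelf" %in% seg$label[seg$island_id == "a"])
})

test_that("segmentation agrees with the per-bp nearest-island oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(2:5, 1L)
    starts <- sort(sample.int(28000, n))
    ends <- starts + sample(200:800, n, replace = TRUE)
    ok <- c(TRUE, starts[-1L] > ends[-n])
    starts <- starts[ok]; ends <- ends[ok]
    isl <- cpg_islands(paste0("i", seq_along(starts)), "chrT", starts, ends)
    seg <- segment_cgir(isl, 30000)
    oracle <- brute_force_cgir(isl, 30000)
    sites <- cpg_sites(paste0("p", 1:30000), "chrT", 0:29999)
    got <- classify_cpg_cgir(sites, seg)
    expect_identical(got$cgir_label, oracle$label)
    expect_identical(got$island_id, oracle$island_id)
  }
})

test_that("segments of one island are disjoint and contiguous with it", {
  set.seed(7)
  starts <- sort(sample.int(90000, 8))
  ends <- starts + sample(300:900, 8, replace = TRUE)
  ok <- c(TRUE, starts[-1L] > ends[-8])
  isl <- cpg_islands(paste0("i", which(ok)), "chrT", starts[ok], ends[ok])
  seg <- segment_cgir(isl, 100000)
  # pairwise disjoint across the whole chromosome
  seg <- seg[order(seg$start), ]
  expect_true(all(seg$start[-1L] >= seg$end[-nrow(seg)]))
  # per island, the union of segments is one contiguous block
  for (id in isl$island_id) {
    s <- seg[seg$island_id == id, ]
    s <- s[order(s$start), ]
    expect_true(all(s$start[-1L] == s$end[-nrow(s)]))
  }
})

test_that("overlapping or unsorted islands are rejected with the pair named", {
  expect_error(cpg_islands(c("a", "b"), "chrT", c(100, 150), c(200, 400)),
               "a and b overlap")
  isl <- data.frame(island_id = c("b", "a"), chrom = "chrT",
                    start = c(500, 100), end = c(600, 200),
                    stringsAsFactors = FALSE)
  expect_error(segment_cgir(isl, 10000), "sorted")
})

test_that("probe CGIR classification returns the unique containing segment", {
  isl <- cpg_islands("cgi1", "chrT", 10000, 10500)
  seg <- segment_cgir(isl, 100000)
  sites <- cpg_sites(c("p1", "p2", "p3"), "chrT", c(10200, 9000, 50000))
  got <- classify_cpg_cgir(sites, seg)
  expect_equal(got$cgir_label, c("island", "n_shore", "no_cgir"))
  expect_equal(got$island_id, c("cgi1", "cgi1", NA))
})

test_that("gene context follows strand-local TSS windows", {
  gplus <- toy_gene("gp", "chrT", 50000, 54000, "+")
  sites <- cpg_sites(c("a", "b", "c"), "chrT", c(49900, 48600, 47000))
  ctx <- gene_context(sites, gplus)
  expect_equal(ctx$category[match(c("a", "b"), ctx$probe_id)],
               c("TSS200", "TSS1500"))
  expect_false("c" %in% ctx$probe_id)          # beyond 1500 bp upstream
  # minus-strand mirror: gene ending at 50000 has its TSS at the high end
  gminus <- toy_gene("gm", "chrT", 46000, 50000, "-")
  ctx2 <- gene_context(cpg_sites("d", "chrT", 50100), gminus)
  expect_equal(ctx2$category, "TSS200")
})

test_that("gene context agrees with the per-bp brute-force classifier", {
  set.seed(42)
  n_checked <- 0L
  for (rep in 1:25) {
    strand <- sample(c("+", "-"), 1L)
    s <- sample(3000:20000, 1L)
    g <- toy_gene(paste0("g", rep), "chrT", s, s + sample(900:4000, 1L),
                  strand)
    pos <- sample(max(0L, s - 2500L):(g$end + 2500L), 60L)
    sites <- cpg_sites(paste0("p", seq_along(pos)), "chrT", pos)
    got <- gene_context(sites, g)
    want <- vapply(pos, brute_force_gene_context, character(1L), gene = g)
    got_vec <- setNames(rep(NA_character_, length(pos)), sites$probe_id)
    got_vec[got$probe_id] <- got$category
    expect_identical(unname(got_vec), want)
    n_checked <- n_checked + length(pos)
  }
  expect_gte(n_checked, 1000L)
})

test_that("genes without sub-features fall back to body for genic positions", {
  g <- toy_gene("nofeat", "chrT", 1000, 3000, "+", with_subfeatures = FALSE)
  ctx <- gene_context(cpg_sites("p", "chrT", 1500), g)
  expect_equal(ctx$category, "Body")
})

test_that("TSS proximity is boundary-inclusive at the window edge", {
  g <- toy_gene("g1", "chrT", 50000, 52000, "+")
  sites <- cpg_sites(paste0("p", 1:4), "chrT",
                     c(50000, 50300, 50301, 49700))
  expect_equal(tss_proximal(sites, g, window = 300),
               c(TRUE, TRUE, FALSE, TRUE))
  expect_false(any(tss_proximal(sites, g[0, ], window = 300)))
})

test_that("shore orientation follows the Watson/Crick rule and its involution", {
  expect_equal(orient_shore("n_shore", "+"), "five_prime")
  expect_equal(orient_shore("s_shore", "-"), "five_prime")
  expect_equal(orient_shore("s_shore", "+"), "three_prime")
  expect_equal(orient_shore("n_shore", "-"), "three_prime")
  # involution: flipping the strand flips the orientation
  for (lab in c("n_shore", "s_shore")) for (str in c("+", "-")) {
    flipped <- if (str == "+") "-" else "+"
    expect_false(orient_shore(lab, str) == orient_shore(lab, flipped))
  }
  expect_error(orient_shore("island", "+"), "shore")
})

test_that("region classes split promoter from coding categories", {
  expect_equal(region_class(c("TSS200", "UTR3", "FirstExon")),
               c("promoter", "coding", "promoter"))
  expect_equal(region_class(c("TSS1500", "UTR5", "Body")),
               c("promoter", "promoter", "coding"))
  expect_error(region_class("Exon2"), "unknown")
})

test_that("mirror symmetry: reflecting the genome swaps N/S shores and keeps orientations", {
  set.seed(5)
  L <- 60000L
  isl <- cpg_islands(c("i1", "i2"), "chrT", c(12000, 30000), c(12600, 30400))
  genes <- rbind_genes(toy_gene("g1", "chrT", 11500, 14500, "+"),
                       toy_gene("g2", "chrT", 28000, 30500, "-"))
  pos <- sample(0:(L - 1L), 400L)
  sites <- cpg_sites(paste0("p", seq_along(pos)), "chrT", pos)
  sizes <- data.frame(chrom = "chrT", length = L)
  ann <- annotate_probes(sites, isl, genes, sizes)

  # reflected genome: x -> L - 1 - x, intervals [s,e) -> [L-e, L-s), strands flip
  refl <- function(s, e) list(start = L - e, end = L - s)
  isl_r <- cpg_islands(c("i1", "i2"), "chrT",
                       c(L - 12600, L - 30400), c(L - 12000, L - 30000))
  gene_r <- function(g) {
    toy_gene(g$gene_id, "chrT", L - g$end, L - g$start,
             if (g$strand == "+") "-" else "+")
  }
  genes_r <- rbind_genes(gene_r(genes[1, ]), gene_r(genes[2, ]))
  sites_r <- cpg_sites(sites$probe_id, "chrT", L - 1L - pos)
  ann_r <- annotate_probes(sites_r, isl_r, genes_r, sizes)

  key <- function(a) a[order(a$probe_id, ifelse(is.na(a$gene_id), "", a$gene_id)), ]
  a <- key(ann); b <- key(ann_r)
  swap <- c(island = "island", n_shore = "s_shore", s_shore = "n_shore",
            n_shelf = "s_shelf", s_shelf = "n_shelf", no_cgir = "no_cgir")
  expect_identical(unname(swap[a$cgir_label]), b$cgir_label)
  expect_identical(a$tss_proximal, b$tss_proximal)
  expect_identical(a$shore_orientation, b$shore_orientation)
  expect_identical(a$category, b$category)
})
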
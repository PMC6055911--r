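unif4 <- matrix(0.25, nrow = 8, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))

test_that("Shannon diversity closed forms", {
  mono <- matrix(rep(c(1, 0, 0, 0), each = 8), nrow = 8)
  expect_equal(shannon_diversity(mono), 0)
  expect_equal(shannon_diversity(unif4), 2)
  coin <- matrix(rep(c(0.5, 0.5, 0, 0), each = 8), nrow = 8)
  expect_equal(shannon_diversity(coin), 1)
  ## allele relabeling invariance
  expect_equal(shannon_diversity(coin[, c(3, 1, 4, 2)]),
               shannon_diversity(coin))
  expect_error(shannon_diversity(unif4 * 2), "sum to 1")
  expect_error(shannon_diversity(unif4[, 1:3]), "4 allele")
})

test_that("moving any position toward uniform increases D", {
  set.seed(41)
  for (rep in 1:20) {
    p <- matrix(rgamma(32, 1), nrow = 8)
    p <- p / rowSums(p)
    lam <- runif(1, 0.1, 0.9)
    q <- p
    q[3, ] <- (1 - lam) * p[3, ] + lam * 0.25   # mix row 3 toward uniform
    expect_gte(shannon_diversity(q), shannon_diversity(p) - 1e-12)
  }
})

test_that("footprint filtering enforces length and promoter overlap", {
  prom <- data.frame(chrom = "chr1", start = c(100, 1000),
                     end = c(600, 1500))
  fp <- data.frame(chrom = "chr1",
                   start = c(150, 200, 700, 1400, 50),
                   end = c(157, 230, 720, 1460, 110),
                   name = c("short7", "ok", "outside", "ok2", "edge"))
  kept <- filter_footprints(fp, prom)
  expect_setequal(names(kept), c("ok", "ok2", "edge"))
  expect_error(filter_footprints(
    data.frame(chrom = "c", start = 10, end = 5), prom), "negative-length")
  ## synthetic generator: planted retained counts are exact
  om <- omega4()
  spec <- synthetic_spec(n_tfs = 2, k = 4, seed = 6,
                         n_footprints_per_tf = 5, decoy_frac = 0.4)
  gen <- generate_escore_table(spec, om)
  nets <- dominant_networks(gen$table, om)
  iv <- generate_invivo(spec, nets, intranetwork_report(gen$table, om))
  kept2 <- filter_footprints(iv$footprints, iv$promoters)
  expect_length(kept2, 10)          # all planted kept, all decoys dropped
  expect_setequal(names(kept2),
                  iv$truth$footprints$footprint[!is.na(iv$truth$footprints$tf_id)])
})

test_that("promoters_from_tss builds 500 bp upstream windows by strand", {
  tss <- data.frame(chrom = "chr1", pos = c(1000, 2000),
                    strand = c("+", "-"))
  pr <- promoters_from_tss(tss)
  expect_equal(GenomicRanges::start(pr), c(501, 2001))
  expect_equal(GenomicRanges::end(pr), c(1000, 2500))
})

test_that("assign_sites picks qualifying windows deterministically", {
  om <- omega4()
  sites <- enumerate_space(4)
  sc <- matrix(-0.5, 136, 2, dimnames = list(sites, c("T1", "T2")))
  sc[match(canonical("ACGG"), sites), 1] <- 0.45   # T1 binds ACGG only
  sc[match(canonical("ACGG"), sites), 2] <- 0.40
  sc[match(canonical("CGGT"), sites), 2] <- 0.40   # T2 binds two windows
  tab <- escore_table(sc, 4)
  fp <- data.frame(chrom = "chr1", start = 10, end = 18, name = "f1")
  seqs <- c(f1 = "AACGGTAA")   # windows: AACG ACGG CGGT GGTA GTAA
  a <- assign_sites(fp, seqs, tab, tau = 0.35, seed = 1)
  expect_equal(a$site[a$tf_id == "T1"], canonical("ACGG"))
  expect_equal(a$start[a$tf_id == "T1"], 11)       # 0-based genomic
  ## footprint with no qualifying window yields no assignment
  expect_equal(nrow(assign_sites(fp, c(f1 = "TTTTTTTT"), tab, seed = 1)), 0)
  ## multi-hit choice is seeded; only multi-hit rows may change with seed
  a1 <- assign_sites(fp, seqs, tab, seed = 1)
  a2 <- assign_sites(fp, seqs, tab, seed = 1)
  expect_identical(a1, a2)
  picks <- vapply(1:30, function(s)
    assign_sites(fp, seqs, tab, seed = s)$site[2], "")
  expect_setequal(unique(picks), canonical(c("ACGG", "CGGT")))
  t1picks <- vapply(1:10, function(s)
    assign_sites(fp, seqs, tab, seed = s)$site[1], "")
  expect_equal(unique(t1picks), canonical("ACGG"))
})

test_that("site_diversity joins allele frequencies onto assignments", {
  freqs <- data.frame(chrom = "chr1", pos = c(12, 13),
                      A = c(0.5, 1), C = c(0.5, 0), G = 0, `T` = 0,
                      check.names = FALSE)
  asg <- data.frame(tf_id = "T1", footprint = "f1", chrom = "chr1",
                    start = 11, window = "ACGG", site = "ACGG")
  d <- site_diversity(asg, freqs, k = 4)
  expect_equal(d$D, 1 / 4)          # one fair-coin position over 4
  expect_true(d$polymorphic)
  ## no records at the site -> monomorphic, D = 0
  asg2 <- asg; asg2$start <- 100
  d2 <- site_diversity(asg2, freqs, k = 4)
  expect_equal(d2$D, 0)
  expect_false(d2$polymorphic)
})

test_that("allele frequency VCF round trip (biallelic AF records)", {
  skip_if_not_installed("VariantAnnotation")
  freqs <- data.frame(chrom = "chr1", pos = c(5, 9, 20),
                      A = c(0.7, 0, 1), C = c(0.3, 0.2, 0),
                      G = c(0, 0.8, 0), `T` = c(0, 0, 0),
                      check.names = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_vcf_af(freqs, f)
  back <- allele_freqs_from_vcf(f)
  expect_equal(nrow(back), 2)       # the monomorphic position is absent
  expect_equal(back$pos, c(5, 9))
  expect_equal(back$A[1], 0.7, tolerance = 1e-5)
  expect_equal(back$C[1], 0.3, tolerance = 1e-5)
  expect_equal(back$G[2], 0.8, tolerance = 1e-5)
})

test_that("partial Spearman behaves like plain Spearman with constant control", {
  set.seed(42)
  x <- rnorm(30); y <- 0.8 * x + rnorm(30, sd = 0.5)
  ## constant control variable: ranks of z are all ties -> guard with a
  ## near-constant z instead
  z <- rnorm(30, sd = 1e-9)
  ps <- partial_spearman(x, y, z)
  plain <- cor(x, y, method = "spearman")
  expect_equal(ps$rho, plain, tolerance = 0.05)
  ## perfectly monotone relation gives rho 1
  ps2 <- partial_spearman(1:20, (1:20)^2, rnorm(20))
  expect_gt(ps2$rho, 0.95)
  expect_lt(ps2$p, 1e-6)
  expect_error(partial_spearman(1:3, 1:3, 1:3), "insufficient")
})

test_that("structure-diversity correlations recover planted relations", {
  ## direct construction: diversity driven by size and by L given size
  set.seed(43)
  n <- 60
  size <- sort(sample(50:1000, n))
  L <- 1 + 0.004 * size + rnorm(n, sd = 0.3)
  D <- 0.002 * size + 0.8 * L + rnorm(n, sd = 0.2)
  intra <- data.frame(tf_id = paste0("T", 1:n), dominant_size = size,
                      L = L, q = runif(n, 1, 1.2), r = runif(n, -0.2, 0.5),
                      degenerate = FALSE)
  div <- data.frame(tf_id = rep(intra$tf_id, 2), D = rep(D, 2),
                    polymorphic = TRUE)
  res <- structure_diversity_correlations(intra, div)
  cr <- res$correlations
  expect_equal(cr$metric, c("dominant_size", "L", "q", "r"))
  expect_gt(cr$rho[cr$metric == "dominant_size"], 0.5)
  expect_gt(cr$rho[cr$metric == "L"], 0.3)
  expect_lt(cr$p[cr$metric == "L"], 0.05)
  ## q and r carry no planted effect
  expect_gt(cr$p[cr$metric == "q"], 0.001)
  ## diversity independent of everything: rho near 0
  div0 <- data.frame(tf_id = rep(intra$tf_id, 2),
                     D = rnorm(2 * n), polymorphic = TRUE)
  res0 <- structure_diversity_correlations(intra, div0)
  expect_lt(abs(res0$correlations$rho[1]), 0.35)
  expect_error(structure_diversity_correlations(intra[1:3, ], div),
               "insufficient")
})
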
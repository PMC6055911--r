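## Most checks run on the k = 4 space against the string-based oracles.

test_that("overlap matrix arithmetic and symmetry identities", {
  om <- omega4()
  a <- sort(c("AAAA", neighbors("AAAA")[1:3]))
  b <- sort(c(a[1:2], "CCGG", neighbors("CCGG")[1:5]))
  nets <- list(A = a, B = b)
  O <- overlap_matrix(nets, om)
  expect_equal(O["A", "A"], 1)
  expect_equal(O["A", "B"], length(intersect(a, b)) / length(b))
  expect_equal(O["B", "A"], length(intersect(a, b)) / length(a))
  ## intersection count identity
  expect_equal(O["A", "B"] * length(b), O["B", "A"] * length(a))
  ## identical and disjoint networks
  O2 <- overlap_matrix(list(X = a, Y = a), om)
  expect_true(all(O2 == 1))
  far <- c("GGGG", neighbors("GGGG")[1])
  O3 <- overlap_matrix(list(X = a, Y = setdiff(far, a)), om)
  expect_equal(O3["X", "Y"], 0)
})

test_that("local spectra match hand enumeration of neighbors", {
  tw <- toy_networks4()
  om <- tw$omega
  sets <- tw$networks
  set.seed(31)
  for (s in sample(om$sites, 12)) {
    ls <- local_spectrum(s, sets, om)
    nb <- oracle_neighbors(s)
    expect_equal(ls$k, length(nb))
    for (q in names(sets)) {
      expect_equal(unname(ls$counts[q]), sum(nb %in% sets[[q]]))
    }
    expect_true(all(ls$phi >= 0 & ls$phi <= 1))
    expect_true(all(ls$counts <= ls$k))
  }
  ## all neighbors in one network -> phi 1; none -> 0
  full <- local_spectrum("AAAA", list(Z = om$sites), om)
  expect_equal(unname(full$phi["Z"]), 1)
  none <- local_spectrum("AAAA", list(Z = "GGCC"), om)
  expect_equal(unname(none$phi["Z"]), 0)
})

test_that("phi matrix equals brute-force neighbor counting", {
  tw <- toy_networks4()
  om <- tw$omega
  deg_of <- function(s) length(oracle_neighbors(s))
  phi <- phi_matrix(tw$networks, om)
  expect_equal(phi, oracle_phi_matrix(tw$networks, deg_of))
  expect_true(all(phi >= 0 & phi <= 1))
})

test_that("global connectivity sums phi over other phenotypes", {
  phi <- matrix(c(0.5, 0.2, 0.1, 0.6), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(global_connectivity(phi), c(a = 0.1, b = 0.2))
  ## Spearman(Phi_q, network size) > 0 under a planted size gradient
  om <- omega4()
  centers <- c("AAAA", "ACCA", "CGAC", "AGGG", "ATTG")
  d <- igraph::distances(om$graph, v = site_index(centers, om))
  radii <- c(0, 1, 1, 2, 2)  # increasing sizes
  sets <- lapply(seq_along(centers), function(i)
    om$sites[d[i, ] <= radii[i]])
  names(sets) <- paste0("P", seq_along(sets))
  sets <- lapply(sets, function(s) genotype_networks(s, om)$dominant)
  Phi <- global_connectivity(phi_matrix(sets, om))
  expect_gt(cor(Phi, lengths(sets), method = "spearman"), 0)
})

test_that("accessibility matrix matches the boundary oracle", {
  tw <- toy_networks4()
  A <- accessibility_matrix(tw$networks, tw$omega)
  expect_equal(A, oracle_accessibility(tw$networks))
  ## whole space has an empty boundary
  Afull <- accessibility_matrix(list(all = tw$omega$sites,
                                     p = tw$networks[[1]]), tw$omega)
  expect_true(all(is.na(Afull[, "all"])))
})

test_that("accessibility and phi are strongly rank-correlated", {
  ## needs networks that are small relative to the space, as for real
  ## PBM data: ball phenotypes with planted paralog overlap at k = 8
  om <- omega8()
  set.seed(10)
  centers <- om$sites[sample.int(om$n, 4)]
  centers <- c(centers, neighbors(centers[1])[1], neighbors(centers[2])[3])
  d <- igraph::distances(om$graph, v = site_index(centers, om))
  sets <- lapply(seq_along(centers), function(i) om$sites[d[i, ] <= 2])
  names(sets) <- paste0("P", seq_along(sets))
  sets <- lapply(sets, function(s) genotype_networks(s, om)$dominant)
  A <- accessibility_matrix(sets, om)
  phi <- phi_matrix(sets, om)
  off <- !diag(TRUE, length(sets))
  expect_gt(cor(A[off], phi[off], method = "spearman"), 0.5)
})

test_that("Bhattacharyya coefficient closed forms and oracle equality", {
  tw <- toy_networks4()
  om <- tw$omega
  ## closed form: spectra (0.5, 0.5) vs (1, 0) -> sqrt(0.5)
  expect_equal(sum(sqrt(c(0.5, 0.5) * c(1, 0))), sqrt(0.5))
  dom <- tw$networks[[1]]
  g <- induced_graph(dom, om)
  el <- igraph::as_edgelist(g)
  for (e in seq_len(min(10, nrow(el)))) {
    expect_equal(
      bhattacharyya(el[e, 1], el[e, 2], tw$networks, om),
      oracle_bc(el[e, 1], el[e, 2], tw$networks))
  }
  ## identical spectra without exclusion give exactly 1: under a single
  ## all-covering phenotype every site has spectrum (1)
  expect_equal(bhattacharyya("AAAA", "CCGG", list(all = om$sites), om,
                             exclude_shared = FALSE), 1,
               tolerance = 1e-12)
  ## disjoint-support spectra give 0
  balls <- list(A = c("AAAA", neighbors("AAAA")),
                B = c("GGCC", neighbors("GGCC")))
  expect_equal(bhattacharyya("AAAA", "GGCC", balls, om,
                             exclude_shared = FALSE), 0)
  i <- dom[1]
  ## sqrt form bounded in [0, 1]; product form is <= sqrt form
  v1 <- bhattacharyya(el[1, 1], el[1, 2], tw$networks, om)
  v2 <- bhattacharyya(el[1, 1], el[1, 2], tw$networks, om,
                      sqrt_form = FALSE)
  expect_true(v1 >= 0 && v1 <= 1)
  expect_lte(v2, v1 + 1e-12)
  expect_error(bhattacharyya(i, i, tw$networks, om), "distinct")
})

test_that("similarity ratio is deterministic under seed and 1 for uniform spectra", {
  tw <- toy_networks4()
  om <- tw$omega
  dom <- tw$networks[[1]]
  r1 <- similarity_ratio(dom, tw$networks, om, seed = 9)
  r2 <- similarity_ratio(dom, tw$networks, om, seed = 9)
  expect_identical(r1$ratios, r2$ratios)
  expect_true(all(r1$ratios > 0))
  ## in a network where every local spectrum is identical (the full
  ## space, single phenotype) all ratios are exactly 1
  rfull <- similarity_ratio(om$sites, list(all = om$sites), om, seed = 1)
  expect_true(all(abs(rfull$ratios - 1) < 1e-12))
  expect_error(similarity_ratio(dom[1:2], tw$networks, om), ">= 3")
})

test_that("unbound interface ratio matches hand counting", {
  tw <- toy_networks4()
  om <- tw$omega
  unb <- unbound_sites(tw$table, tau = 0.35)
  ui <- unbound_interface(tw$networks, unb$sites, om)
  expect_equal(ui$f_unbound[1], length(unb$sites) / om$n)
  for (i in seq_len(nrow(ui))) {
    S <- tw$networks[[ui$phenotype[i]]]
    phi_u <- mean(vapply(S, function(s) {
      nb <- oracle_neighbors(s)
      sum(nb %in% unb$sites) / length(nb)
    }, 0))
    expect_equal(ui$phi_unbound[i], phi_u)
  }
  ## no unbound sites -> NA ratio
  ui0 <- unbound_interface(tw$networks, character(0), om)
  expect_true(all(is.na(ui0$ratio)))
})

test_that("clustered binding depresses the unbound interface below unity", {
  ## motif-like (ball) phenotypes sit away from unbound space relative
  ## to the random expectation
  om <- omega4()
  d <- igraph::distances(om$graph, v = site_index(c("AAAA", "CGCG"), om))
  sets <- list(P1 = om$sites[d[1, ] <= 2], P2 = om$sites[d[2, ] <= 2])
  sets <- lapply(sets, function(s) genotype_networks(s, om)$dominant)
  unb <- setdiff(om$sites, unique(unlist(sets)))
  ui <- unbound_interface(sets, unb, om)
  expect_true(all(ui$ratio < 1))
})

test_that("covering curves match the BFS oracle and are monotone", {
  tw <- toy_networks4()
  om <- tw$omega
  p <- names(tw$networks)[1]
  for (variant in c("neutral", "non-neutral")) {
    cv <- phenotype_space_covering(p, tw$networks, om, variant = variant)
    expect_true(all(diff(cv$mean) >= -1e-12))
    expect_true(all(cv$mean >= 0 & cv$mean <= 1))
    ## oracle: average over sources of the per-source coverage
    or <- rowMeans(vapply(tw$networks[[p]], function(s)
      oracle_covering(s, p, tw$networks, variant, 0:4),
      numeric(5)))
    expect_equal(cv$mean, or)
  }
  ## neutral curve is constant beyond the network diameter
  g <- induced_graph(tw$networks[[p]], om)
  dm <- path_metrics(g)$diameter
  cvn <- phenotype_space_covering(p, tw$networks, om, "neutral")
  expect_true(all(abs(diff(cvn$mean[(dm + 1):5])) < 1e-12))
  ## the two variants coincide at n = 1 when networks do not overlap the
  ## sources' own neighborhoods identically is not guaranteed; but both
  ## start from the same n = 0 coverage
  cvx <- phenotype_space_covering(p, tw$networks, om, "non-neutral")
  expect_equal(cvn$mean[1], cvx$mean[1])
  expect_error(phenotype_space_covering("nope", tw$networks, om),
               "unknown phenotype")
})

test_that("covering with disjoint networks saturates at the self fraction", {
  om <- omega4()
  d <- igraph::distances(om$graph, v = site_index(c("AAAA", "GGCC"), om))
  sets <- list(P1 = genotype_networks(om$sites[d[1, ] <= 1], om)$dominant,
               P2 = genotype_networks(om$sites[d[2, ] <= 1], om)$dominant)
  stopifnot(length(intersect(sets$P1, sets$P2)) == 0)
  cv <- phenotype_space_covering("P1", sets, om, "neutral")
  expect_true(all(cv$mean == 0.5))  # only P1 itself ever covered
})

test_that("phenotype network edges encode overlap and adjacency", {
  om <- omega4()
  a <- genotype_networks(c("AAAA", neighbors("AAAA")), om)$dominant
  ## overlapping partner: shares a site
  b <- genotype_networks(c(a[2], neighbors(a[2])), om)$dominant
  pn <- phenotype_network(list(A = a, B = b), om)
  expect_equal(nrow(pn), 1)
  expect_true(pn$overlap)
  ## disjoint but adjacent at distance 1
  s <- "GGCC"
  c1 <- genotype_networks(c(s, neighbors(s)[1]), om)$dominant
  adj_site <- setdiff(neighbors(neighbors(s)[1]), c1)[1]
  c2 <- genotype_networks(adj_site, om)$dominant
  pn2 <- phenotype_network(list(A = c1, B = c2), om)
  expect_equal(nrow(pn2), 1)
  expect_false(pn2$overlap)
  expect_true(pn2$adjacent)
  ## far apart: no edge
  d <- igraph::distances(om$graph, v = site_index("AAAA", om))[1, ]
  far <- om$sites[which(d >= 3)[1]]
  pn3 <- phenotype_network(list(A = "AAAA", B = far), om)
  expect_equal(nrow(pn3), 0)
})

test_that("domain coarse-graining unions member TF genotype sets", {
  tw <- toy_networks4(n_tfs = 4)
  meta <- tw$meta
  meta$domain <- c("D1", "D1", "D2", "")
  expect_warning(sets <- domain_coarse_grain(tw$table, meta),
                 "without domain")
  expect_setequal(names(sets), c("D1", "D2"))
  b1 <- bound_sites(tw$table, meta$tf_id[1])
  b2 <- bound_sites(tw$table, meta$tf_id[2])
  expect_setequal(sets$D1, union(b1, b2))
  expect_setequal(sets$D2, bound_sites(tw$table, meta$tf_id[3]))
  ## single-TF domain is identical to that TF's set; disjoint sets add
  expect_equal(length(sets$D1) <= length(b1) + length(b2), TRUE)
})

test_that("matrix export blanks the diagonal", {
  tw <- toy_networks4()
  O <- overlap_matrix(tw$networks, tw$omega)
  f <- tempfile(fileext = ".tsv")
  write_matrix(O, f)
  df <- read.table(f, sep = "\t", header = TRUE, check.names = FALSE)
  expect_true(all(is.na(diag(as.matrix(df[, -1])))))
})
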
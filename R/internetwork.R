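## Internetwork statistics: overlap, mutational connectivity, phenotype
## accessibility, local-neighborhood similarity, phenotype space covering
## and the phenotype network.
##
## All measures are computed on dominant genotype networks. Functions
## take `networks` as a *named* list of canonical site vectors (one per
## phenotype); entries may also be `genotype_networks` objects, in which
## case their dominant component is used.

.dominant_sets <- function(networks) {
  if (inherits(networks, "genotype_networks")) networks <- list(networks)
  out <- lapply(networks, function(x) {
    if (inherits(x, "genotype_networks")) x$dominant else as.character(x)
  })
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("networks must be a named list", call. = FALSE)
  out
}

## n_sites x Q phenotype membership matrix (0/1)
.membership <- function(sets, omega) {
  m <- matrix(0L, nrow = omega$n, ncol = length(sets),
              dimnames = list(NULL, names(sets)))
  for (q in seq_along(sets)) m[site_index(sets[[q]], omega), q] <- 1L
  m
}

#' Dominant genotype networks for all TFs of an E-score table
#'
#' @param table an `escore_table`.
#' @param omega a `genotype_space`.
#' @param tau affinity threshold.
#' @param tfs subset of TFs (default all). TFs with empty genotype sets
#'   are dropped with a warning.
#' @return named list of canonical site vectors (dominant networks).
#' @export
dominant_networks <- function(table, omega, tau = 0.35, tfs = table$tfs) {
  sets <- lapply(tfs, function(tf) bound_sites(table, tf, tau))
  names(sets) <- tfs
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping TFs with empty genotype sets: ",
            paste(tfs[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  lapply(sets, function(s) genotype_networks(s, omega)$dominant)
}

#' Pairwise overlap of genotype networks
#'
#' `O[q, p]` is the fraction of phenotype p's sites that also belong to
#' phenotype q's network: `|S(Gq) n S(Gp)| / |S(Gp)|`. Asymmetric; the
#' diagonal equals 1.
#'
#' @param networks named list of site vectors (see module docs).
#' @param omega a `genotype_space`.
#' @return Q x Q matrix with target phenotypes in rows and source
#'   phenotypes in columns.
#' @export
overlap_matrix <- function(networks, omega) {
  sets <- .dominant_sets(networks)
  m <- .membership(sets, omega)
  counts <- crossprod(m)
  sweep(counts, 2, lengths(sets), "/")
}

#' Local phenotype spectrum of a site
#'
#' For site i, the fraction of its genotype-space neighbors that belong
#' to each phenotype's dominant network: `phi_q_local(i) = n_iq / k_i`.
#'
#' @param site a canonical site (canonicalized internally).
#' @inheritParams overlap_matrix
#' @return list with `site`, `k` (degree in the genotype space),
#'   `counts` (named n_iq) and `phi` (named fractions).
#' @export
local_spectrum <- function(site, networks, omega) {
  sets <- .dominant_sets(networks)
  m <- .membership(sets, omega)
  i <- site_index(site, omega)
  nb <- omega$adj[[i]]
  counts <- colSums(m[nb, , drop = FALSE])
  list(site = omega$sites[i], k = omega$deg[i], counts = counts,
       phi = counts / omega$deg[i])
}

## counts matrix n_iq for the sites indexed by idx: |idx| x Q
.neighbor_counts <- function(idx, m, omega) {
  nb <- unlist(omega$adj[idx], use.names = FALSE)
  grp <- rep(seq_along(idx), omega$deg[idx])
  cnt <- rowsum(m[nb, , drop = FALSE], grp)
  rownames(cnt) <- NULL
  cnt
}

#' Mutation probability matrix phi
#'
#' `phi[q, p]` is the mean, over the sites i of phenotype p's network, of
#' the fraction of i's genotype-space neighbors lying in phenotype q's
#' network — the probability that a random single mutation of a p-site
#' yields a q-site. The diagonal is the neutral-mutation fraction.
#'
#' @inheritParams overlap_matrix
#' @return Q x Q matrix, target phenotypes in rows, sources in columns.
#' @export
phi_matrix <- function(networks, omega) {
  sets <- .dominant_sets(networks)
  m <- .membership(sets, omega)
  Q <- length(sets)
  phi <- matrix(NA_real_, Q, Q, dimnames = list(names(sets), names(sets)))
  for (p in seq_len(Q)) {
    idx <- site_index(sets[[p]], omega)
    cnt <- .neighbor_counts(idx, m, omega)
    phi[, p] <- colMeans(cnt / omega$deg[idx])
  }
  phi
}

#' Global mutational connectivity
#'
#' `Phi_q`, the sum of `phi[q, p]` over all source phenotypes p != q: how
#' reachable phenotype q's network is by single mutations from all other
#' networks.
#'
#' @param phi a phi matrix from [phi_matrix()].
#' @return named numeric vector.
#' @export
global_connectivity <- function(phi) {
  rowSums(phi) - diag(phi)
}

#' Phenotype accessibility matrix
#'
#' `A[q, p]` is the fraction of the external mutational boundary of
#' phenotype p's network (all genotype-space neighbors of its sites that
#' are not themselves in the network) that belongs to phenotype q's
#' network.
#'
#' @inheritParams overlap_matrix
#' @return Q x Q matrix; a column is `NA` if the boundary is empty.
#' @export
accessibility_matrix <- function(networks, omega) {
  sets <- .dominant_sets(networks)
  m <- .membership(sets, omega)
  Q <- length(sets)
  A <- matrix(NA_real_, Q, Q, dimnames = list(names(sets), names(sets)))
  for (p in seq_len(Q)) {
    idx <- site_index(sets[[p]], omega)
    bnd <- setdiff(unique(unlist(omega$adj[idx], use.names = FALSE)), idx)
    if (length(bnd)) A[, p] <- colMeans(m[bnd, , drop = FALSE])
  }
  A
}

## normalized local spectrum of site index i with a neighbor exclusion
.norm_spectrum <- function(i, m, omega, exclude = integer(0)) {
  nb <- setdiff(omega$adj[[i]], exclude)
  if (!length(nb)) return(NULL)
  cnt <- colSums(m[nb, , drop = FALSE])
  tot <- sum(cnt)
  if (tot == 0) return(NULL)
  cnt / tot
}

#' Bhattacharyya coefficient of two local phenotype spectra
#'
#' Overlap of the normalized local phenotype spectra of two sites:
#' `BC = sum_q sqrt(p_q(i) p_q(j))`, 1 for identical spectra, 0 for
#' disjoint support. With `exclude_shared = TRUE` (default) neighbors
#' common to i and j are removed before computing the spectra, giving a
#' more conservative measure. `sqrt_form = FALSE` gives the literal
#' product-sum variant.
#'
#' @param i,j two distinct canonical sites.
#' @inheritParams overlap_matrix
#' @param exclude_shared drop neighbors shared by i and j.
#' @param sqrt_form use the square-root (Bhattacharyya) form.
#' @return coefficient in `[0, 1]`, or `NA` if either spectrum has zero
#'   mass after exclusion.
#' @export
bhattacharyya <- function(i, j, networks, omega, exclude_shared = TRUE,
                          sqrt_form = TRUE) {
  sets <- .dominant_sets(networks)
  m <- .membership(sets, omega)
  ii <- site_index(i, omega)
  jj <- site_index(j, omega)
  if (ii == jj) stop("i and j must be distinct sites", call. = FALSE)
  .bc_pair(ii, jj, m, omega, exclude_shared, sqrt_form)
}

.bc_pair <- function(ii, jj, m, omega, exclude_shared, sqrt_form) {
  excl <- if (exclude_shared) intersect(omega$adj[[ii]], omega$adj[[jj]])
          else integer(0)
  pi_ <- .norm_spectrum(ii, m, omega, excl)
  pj_ <- .norm_spectrum(jj, m, omega, excl)
  if (is.null(pi_) || is.null(pj_)) return(NA_real_)
  if (sqrt_form) sum(sqrt(pi_ * pj_)) else sum(pi_ * pj_)
}

#' Similarity ratio of neighborhood spectra
#'
#' For every pair of neutral neighbors (i, j) in a genotype network,
#' the ratio `BC(i, j) / BC(i, k)` where k is a randomly sampled member
#' of the same network that is not a neighbor of i. Shared neighbors are
#' excluded from each coefficient. A mean ratio above 1 means neutral
#' neighbors have more similar mutational neighborhoods than
#' non-neighbors from the same network.
#'
#' @param network site vector (or `genotype_networks`) of the focal
#'   dominant network; must have at least 3 sites.
#' @inheritParams overlap_matrix
#' @param seed integer seed for the non-neighbor sampling.
#' @param sqrt_form passed to [bhattacharyya()].
#' @return list with `ratios`, `mean`, `sem` and `n_skipped` (pairs
#'   dropped for lack of a valid non-neighbor or zero-mass spectra).
#' @export
similarity_ratio <- function(network, networks, omega, seed = NULL,
                             sqrt_form = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sites <- if (inherits(network, "genotype_networks")) network$dominant
           else as.character(network)
  if (length(sites) < 3) stop("network needs >= 3 sites", call. = FALSE)
  sets <- .dominant_sets(networks)
  m <- .membership(sets, omega)
  idx <- site_index(sites, omega)
  g <- induced_graph(sites, omega)
  el <- igraph::as_edgelist(g, names = FALSE)
  nbrs_in_g <- lapply(seq_along(idx), function(v)
    as.integer(igraph::neighbors(g, v)))
  ratios <- rep(NA_real_, nrow(el))
  skipped <- 0L
  for (e in seq_len(nrow(el))) {
    vi <- el[e, 1]; vj <- el[e, 2]
    pool <- setdiff(seq_along(idx), c(vi, nbrs_in_g[[vi]]))
    if (!length(pool)) { skipped <- skipped + 1L; next }
    vk <- if (length(pool) == 1) pool else sample(pool, 1)
    bij <- .bc_pair(idx[vi], idx[vj], m, omega, TRUE, sqrt_form)
    bik <- .bc_pair(idx[vi], idx[vk], m, omega, TRUE, sqrt_form)
    if (is.na(bij) || is.na(bik) || bik == 0) { skipped <- skipped + 1L; next }
    ratios[e] <- bij / bik
  }
  ratios <- ratios[!is.na(ratios)]
  list(ratios = ratios, mean = mean(ratios),
       sem = stats::sd(ratios) / sqrt(length(ratios)), n_skipped = skipped)
}

#' Interface of genotype networks with unbound genotype space
#'
#' For each phenotype p, the mean fraction of mutations from its sites
#' landing on unbound sites, divided by the overall unbound fraction
#' `f_unbound`. A ratio of 1 is the null expectation; below 1 means the
#' network is insulated from unbound space.
#'
#' @inheritParams overlap_matrix
#' @param unbound character vector of unbound sites (same threshold).
#' @return data.frame with `phenotype`, `phi_unbound`, `f_unbound`,
#'   `ratio`.
#' @export
unbound_interface <- function(networks, unbound, omega) {
  sets <- .dominant_sets(networks)
  f_unb <- length(unbound) / omega$n
  mu <- .membership(list(unbound = unbound), omega)
  phi_u <- vapply(sets, function(s) {
    idx <- site_index(s, omega)
    cnt <- .neighbor_counts(idx, mu, omega)
    mean(cnt[, 1] / omega$deg[idx])
  }, 0)
  data.frame(phenotype = names(sets), phi_unbound = unname(phi_u),
             f_unbound = f_unb,
             ratio = if (f_unb > 0) unname(phi_u) / f_unb else NA_real_,
             stringsAsFactors = FALSE)
}

#' Phenotype space covering curve
#'
#' Average fraction of phenotypes found within a mutational radius n of a
#' binding site of phenotype `p`. In the `"neutral"` variant only
#' mutational paths inside p's genotype network are followed (covering
#' then reflects network overlap); in the `"non-neutral"` variant every
#' step must leave p's network (paths run through the rest of the
#' genotype space).
#'
#' @param p name of the focal phenotype (an entry of `networks`).
#' @inheritParams overlap_matrix
#' @param variant `"neutral"` or `"non-neutral"`.
#' @param radii radii to report (default `0:k`).
#' @param sources optional subset of source sites (default all sites of
#'   p's network); useful for sampling on large networks.
#' @param count_self count phenotypes covered at the source itself
#'   (radius 0), including p (default `TRUE`).
#' @return data.frame with columns `phenotype`, `variant`, `n`, `mean`,
#'   `sd` (mean/sd over source sites of the fraction of phenotypes
#'   covered).
#' @export
phenotype_space_covering <- function(p, networks, omega,
                                     variant = c("neutral", "non-neutral"),
                                     radii = 0:omega$k, sources = NULL,
                                     count_self = TRUE) {
  variant <- match.arg(variant)
  sets <- .dominant_sets(networks)
  if (!p %in% names(sets)) stop("unknown phenotype: ", p, call. = FALSE)
  m <- .membership(sets, omega)
  Q <- ncol(m)
  idx_p <- site_index(sets[[p]], omega)
  src <- if (is.null(sources)) idx_p else site_index(sources, omega)
  if (!all(src %in% idx_p))
    stop("sources must belong to the network of ", p, call. = FALSE)

  if (variant == "neutral") {
    g <- induced_graph(sets[[p]], omega)
    vsrc <- match(src, idx_p)
    D <- igraph::distances(g, v = vsrc)   # |src| x |S_p|
    msub <- m[idx_p, , drop = FALSE]
    frac <- vapply(radii, function(n) {
      reach <- (D <= n)
      cov <- (reach %*% msub) > 0
      if (!count_self) cov[, p] <- FALSE
      rowSums(cov) / Q
    }, numeric(length(src)))
  } else {
    outside <- setdiff(seq_len(omega$n), idx_p)
    H <- igraph::induced_subgraph(omega$graph, outside)
    pos <- integer(omega$n)
    pos[outside] <- seq_along(outside)
    mout <- m[outside, , drop = FALSE]
    frac <- vapply(seq_along(src), function(s) {
      i <- src[s]
      oni <- setdiff(omega$adj[[i]], idx_p)
      if (length(oni)) {
        dH <- igraph::distances(H, v = pos[oni])
        dmin <- apply(dH, 2, min) + 1
      } else dmin <- rep(Inf, length(outside))
      self_cov <- if (count_self) m[i, ] > 0 else rep(FALSE, Q)
      vapply(radii, function(n) {
        cov <- colSums(mout[dmin <= n, , drop = FALSE]) > 0 | self_cov
        sum(cov) / Q
      }, 0)
    }, numeric(length(radii)))
    frac <- t(frac)                        # |src| x |radii|
  }
  frac <- matrix(frac, nrow = length(src))
  data.frame(phenotype = p, variant = variant, n = radii,
             mean = colMeans(frac), sd = apply(frac, 2, stats::sd),
             stringsAsFactors = FALSE)
}

#' Phenotype network edge list
#'
#' Nodes are phenotypes; two phenotypes are linked when their dominant
#' genotype networks share at least one genotype (`overlap`) or can be
#' reached from one another by at least one single mutation
#' (`adjacent`).
#'
#' @inheritParams overlap_matrix
#' @return data.frame with columns `p`, `q`, `overlap`, `adjacent`, one
#'   row per linked unordered pair.
#' @export
phenotype_network <- function(networks, omega) {
  sets <- .dominant_sets(networks)
  m <- .membership(sets, omega)
  Q <- length(sets)
  idx <- lapply(sets, site_index, omega = omega)
  bnd <- lapply(idx, function(i)
    setdiff(unique(unlist(omega$adj[i], use.names = FALSE)), i))
  rows <- list()
  for (a in seq_len(Q - 1)) for (b in (a + 1):Q) {
    ov <- any(m[idx[[a]], b] > 0)
    adj <- any(m[bnd[[a]], b] > 0) || any(m[bnd[[b]], a] > 0)
    if (ov || adj)
      rows[[length(rows) + 1L]] <- data.frame(
        p = names(sets)[a], q = names(sets)[b], overlap = ov,
        adjacent = adj, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(p = character(), q = character(),
                      overlap = logical(), adjacent = logical()))
  do.call(rbind, rows)
}

#' Domain-level genotype sets
#'
#' Coarse-grains phenotypes to DNA-binding domains: a site has domain
#' phenotype d when it binds at least one TF of domain d. The returned
#' sets feed the same network constructors and internetwork measures as
#' TF-level sets.
#'
#' @param table an `escore_table`.
#' @param meta TF metadata (`tf_id`, `species`, `domain`).
#' @param tau affinity threshold.
#' @return named list of canonical site vectors, one per domain. TFs
#'   without a domain label are excluded with a warning.
#' @export
domain_coarse_grain <- function(table, meta, tau = 0.35) {
  meta <- meta[meta$tf_id %in% table$tfs, ]
  bad <- is.na(meta$domain) | !nzchar(meta$domain)
  if (any(bad)) {
    warning("excluding TFs without domain label: ",
            paste(meta$tf_id[bad], collapse = ", "))
    meta <- meta[!bad, ]
  }
  doms <- sort(unique(meta$domain))
  out <- lapply(doms, function(d) {
    tfs <- meta$tf_id[meta$domain == d]
    sort(unique(unlist(lapply(tfs, bound_sites, table = table, tau = tau))))
  })
  names(out) <- doms
  out[lengths(out) > 0]
}

#' Write an internetwork matrix with NA diagonal
#'
#' @param mat a Q x Q matrix from [overlap_matrix()], [phi_matrix()] or
#'   [accessibility_matrix()].
#' @param path output TSV path.
#' @param na_diagonal blank out the diagonal (default `TRUE`), matching
#'   the usual heatmap convention.
#' @export
write_matrix <- function(mat, path, na_diagonal = TRUE) {
  if (na_diagonal) diag(mat) <- NA
  df <- data.frame(phenotype = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
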
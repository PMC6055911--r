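## Independent brute-force oracles. Everything here is implemented with
## naive string operations and triple loops, deliberately sharing no
## code with the package internals.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
        collapse = "")
}

oracle_canonical <- function(s) {
  r <- oracle_revcomp(s)
  if (s <= r) s else r
}

## all canonical neighbors by explicit string surgery
oracle_neighbors <- function(s, k = nchar(s)) {
  out <- character(0)
  for (p in seq_len(k)) for (b in c("A", "C", "G", "T")) {
    if (substr(s, p, p) != b) {
      t <- s
      substr(t, p, p) <- b
      out <- c(out, oracle_canonical(t))
    }
  }
  for (b in c("A", "C", "G", "T")) {
    out <- c(out, oracle_canonical(paste0(substr(s, 2, k), b)),
             oracle_canonical(paste0(b, substr(s, 1, k - 1))))
  }
  sort(setdiff(unique(out), oracle_canonical(s)))
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

oracle_mutdist <- function(a, b) {
  min(oracle_hamming(a, b), oracle_hamming(a, oracle_revcomp(b)))
}

## adjacency matrix of a site set from the oracle neighbor rule
oracle_adjacency <- function(sites) {
  n <- length(sites)
  A <- matrix(0L, n, n, dimnames = list(sites, sites))
  for (i in seq_len(n)) {
    nb <- intersect(oracle_neighbors(sites[i]), sites)
    A[i, match(nb, sites)] <- 1L
  }
  A
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  cs <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(A[i, ])
    if (ki < 2) next
    tri <- 0
    nb <- which(A[i, ] == 1)
    for (j in nb) for (l in nb) tri <- tri + A[j, l]
    cs[i] <- tri / (ki * (ki - 1))
  }
  mean(cs)
}

oracle_assortativity <- function(A) {
  deg <- rowSums(A)
  js <- c(); ks <- c()
  n <- nrow(A)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (A[i, j] == 1) {
    js <- c(js, deg[i]); ks <- c(ks, deg[j])
  }
  ## Pearson correlation over symmetrized edge-endpoint degrees
  suppressWarnings(cor(c(js, ks), c(ks, js)))
}

## Floyd-Warshall all-pairs distances
oracle_apsp <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
  D
}

oracle_path_stats <- function(A) {
  D <- oracle_apsp(A)
  up <- D[upper.tri(D)]
  list(diameter = max(up), L = mean(up))
}

oracle_route_factor <- function(sites, target, Dnet, Domega, all_sites) {
  others <- setdiff(sites, target)
  mean(vapply(others, function(s)
    Dnet[match(s, sites), match(target, sites)] /
      Domega[match(s, all_sites), match(target, all_sites)], 0))
}

## internetwork oracles operate on named lists of site vectors plus the
## oracle neighbor rule
oracle_phi_local <- function(site, sets, k_site) {
  nb <- oracle_neighbors(site)
  vapply(sets, function(S) sum(nb %in% S) / k_site, 0)
}

oracle_phi_matrix <- function(sets, degree_of) {
  Q <- length(sets)
  phi <- matrix(0, Q, Q, dimnames = list(names(sets), names(sets)))
  for (p in seq_len(Q)) {
    acc <- matrix(0, nrow = length(sets[[p]]), ncol = Q)
    for (ii in seq_along(sets[[p]])) {
      s <- sets[[p]][ii]
      acc[ii, ] <- oracle_phi_local(s, sets, degree_of(s))
    }
    phi[, p] <- colMeans(acc)
  }
  phi
}

oracle_overlap_matrix <- function(sets) {
  Q <- length(sets)
  O <- matrix(0, Q, Q, dimnames = list(names(sets), names(sets)))
  for (q in seq_len(Q)) for (p in seq_len(Q))
    O[q, p] <- length(intersect(sets[[q]], sets[[p]])) / length(sets[[p]])
  O
}

oracle_accessibility <- function(sets) {
  Q <- length(sets)
  A <- matrix(NA_real_, Q, Q, dimnames = list(names(sets), names(sets)))
  for (p in seq_len(Q)) {
    bnd <- setdiff(unique(unlist(lapply(sets[[p]], oracle_neighbors))),
                   sets[[p]])
    if (length(bnd))
      for (q in seq_len(Q)) A[q, p] <- mean(bnd %in% sets[[q]])
  }
  A
}

oracle_bc <- function(i, j, sets, exclude_shared = TRUE) {
  ni <- oracle_neighbors(i)
  nj <- oracle_neighbors(j)
  if (exclude_shared) {
    sh <- intersect(ni, nj)
    ni <- setdiff(ni, sh)
    nj <- setdiff(nj, sh)
  }
  ci <- vapply(sets, function(S) sum(ni %in% S), 0)
  cj <- vapply(sets, function(S) sum(nj %in% S), 0)
  if (sum(ci) == 0 || sum(cj) == 0) return(NA_real_)
  sum(sqrt((ci / sum(ci)) * (cj / sum(cj))))
}

## covering oracle: BFS by explicit frontier expansion
oracle_covering <- function(source, p, sets, variant, radii) {
  Sp <- sets[[p]]
  maxn <- max(radii)
  visited <- source
  frontier <- source
  frac_at <- function(vis)
    mean(vapply(sets, function(S) any(vis %in% S), TRUE))
  frac <- numeric(maxn + 1)
  frac[1] <- frac_at(visited)
  for (d in seq_len(maxn)) {
    nxt <- setdiff(unique(unlist(lapply(frontier, oracle_neighbors))),
                   visited)
    nxt <- if (variant == "neutral") intersect(nxt, Sp)
           else setdiff(nxt, Sp)
    visited <- c(visited, nxt)
    frontier <- nxt
    frac[d + 1] <- frac_at(visited)
  }
  frac[radii + 1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
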
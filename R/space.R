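## Genotype space of canonical double-stranded k-mers.
##
## Sites are identified with their reverse complements; the canonical
## representative of the pair {s, revcomp(s)} is the lexicographically
## smaller sequence. Internally sites are base-4 integer codes with the
## first base most significant, so integer order equals lexicographic
## order over A < C < G < T.

.BASES <- c("A", "C", "G", "T")

.check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k > 10 || k != round(k))
    stop("site length k must be a single integer in [2, 10]", call. = FALSE)
  as.integer(k)
}

## character sites -> integer codes (vectorized)
sites_to_codes <- function(x, k = NULL) {
  x <- toupper(x)
  if (is.null(k)) k <- nchar(x[1])
  k <- .check_k(k)
  if (any(nchar(x) != k))
    stop("all sites must have length ", k, call. = FALSE)
  ch <- strsplit(x, "", fixed = TRUE)
  d <- match(unlist(ch), .BASES) - 1L
  if (anyNA(d))
    stop("invalid alphabet: sites must contain only A, C, G, T", call. = FALSE)
  m <- matrix(d, nrow = k)
  as.vector(4^((k - 1):0) %*% m)
}

codes_to_sites <- function(codes, k) {
  k <- .check_k(k)
  cols <- vector("list", k)
  for (i in seq_len(k)) {
    cols[[i]] <- .BASES[((codes %/% 4^(k - i)) %% 4) + 1L]
  }
  do.call(paste0, cols)
}

## reverse complement in code space
.revcomp_code <- function(x, k) {
  rc <- numeric(length(x))
  for (i in seq_len(k)) {
    d <- (x %/% 4^(k - i)) %% 4
    rc <- rc + (3 - d) * 4^(i - 1)
  }
  rc
}

#' Reverse complement of DNA sites
#'
#' @param s character vector of equal-length DNA sequences over `{A,C,G,T}`
#'   (lowercase accepted).
#' @return character vector of reverse complements, uppercase.
#' @examples
#' revcomp("AAAACGTT")
#' @export
revcomp <- function(s) {
  k <- .check_k(nchar(toupper(s[1])))
  codes_to_sites(.revcomp_code(sites_to_codes(s, k), k), k)
}

#' Canonical representative of a double-stranded site
#'
#' Each site is identified with its reverse complement; the canonical
#' representative is the lexicographically smaller of the pair, so every
#' double-stranded site has exactly one name.
#'
#' @inheritParams revcomp
#' @return character vector of canonical sites.
#' @examples
#' canonical("TTTTTTTT")  # "AAAAAAAA"
#' @export
canonical <- function(s) {
  k <- .check_k(nchar(toupper(s[1])))
  x <- sites_to_codes(s, k)
  codes_to_sites(pmin(x, .revcomp_code(x, k)), k)
}

#' Enumerate all canonical double-stranded k-mers
#'
#' There are (4^k - 4^(k/2))/2 + 4^(k/2) canonical sites for even k
#' (32,896 for k = 8): one per reverse-complement pair, with the 4^(k/2)
#' palindromic (self-reverse-complementary) sites unmerged.
#'
#' @param k site length (default 8).
#' @return sorted character vector of canonical sites.
#' @export
enumerate_space <- function(k = 8) {
  k <- .check_k(k)
  all_codes <- 0:(4^k - 1)
  codes <- sort(unique(pmin(all_codes, .revcomp_code(all_codes, k))))
  codes_to_sites(codes, k)
}

## raw (uncanonicalized) mutant codes: 3k point mutants then 8 shifts
.mutant_codes <- function(codes, k) {
  n <- length(codes)
  out <- matrix(0, nrow = n, ncol = 3L * k + 8L)
  col <- 0L
  for (p in 0:(k - 1)) {
    d <- (codes %/% 4^p) %% 4
    for (m in 1:3) {
      col <- col + 1L
      out[, col] <- codes + (((d + m) %% 4) - d) * 4^p
    }
  }
  for (b in 0:3) {           # 3'-ward shift: drop first base, append b
    col <- col + 1L
    out[, col] <- (codes %% 4^(k - 1)) * 4 + b
  }
  for (b in 0:3) {           # 5'-ward shift: prepend b, drop last base
    col <- col + 1L
    out[, col] <- b * 4^(k - 1) + codes %/% 4
  }
  out
}

.canonical_mutant_set <- function(s, cols) {
  k <- .check_k(nchar(toupper(s)))
  x <- sites_to_codes(s, k)
  raw <- .mutant_codes(x, k)[1, cols]
  can <- pmin(raw, .revcomp_code(raw, k))
  can <- setdiff(unique(can), pmin(x, .revcomp_code(x, k)))
  codes_to_sites(sort(can), k)
}

#' Single point mutants of a canonical site
#'
#' All 3k single-base substitutions, canonicalized; the site itself and
#' duplicates arising from reverse-complement merging are removed, so the
#' result can have fewer than 3k members.
#'
#' @param s a single site (canonicalized internally).
#' @return character vector of canonical point-mutant sites.
#' @export
point_mutants <- function(s) {
  k <- nchar(toupper(s))
  .canonical_mutant_set(s, seq_len(3L * k))
}

#' Single-base shift mutants of a canonical site
#'
#' The 4x2 = 8 one-base shift indels: an insertion/deletion at either end
#' that slides the whole k-mer window by one base, the incoming base being
#' any of A, C, G, T. Canonicalized and deduplicated as in
#' [point_mutants()].
#'
#' @inheritParams point_mutants
#' @return character vector of canonical shift-mutant sites.
#' @export
shift_mutants <- function(s) {
  k <- nchar(toupper(s))
  .canonical_mutant_set(s, 3L * k + 1:8)
}

#' All single-mutation neighbors of a canonical site
#'
#' Union of [point_mutants()] and [shift_mutants()]; at most 3k + 8
#' neighbors (32 for k = 8).
#'
#' @inheritParams point_mutants
#' @return character vector of canonical neighbor sites.
#' @export
neighbors <- function(s) {
  k <- nchar(toupper(s))
  .canonical_mutant_set(s, seq_len(3L * k + 8L))
}

#' Gapless mutational distance between two sites
#'
#' Number of mismatches in the zero-offset gapless alignment of `s1`
#' against `s2`, minimized over `s2` and its reverse complement. This is
#' the single-step (point mutation) distance; multi-step distances along
#' the full mutation model are graph distances in the genotype space.
#'
#' @param s1,s2 equal-length site vectors (recycled to common length).
#' @return integer vector of distances in `[0, k]`.
#' @export
mutational_distance <- function(s1, s2) {
  k <- .check_k(nchar(toupper(s1[1])))
  x1 <- sites_to_codes(s1, k)
  x2 <- sites_to_codes(s2, k)
  n <- max(length(x1), length(x2))
  x1 <- rep_len(x1, n)
  x2 <- rep_len(x2, n)
  x2r <- .revcomp_code(x2, k)
  mm <- function(a, b) {
    d <- integer(length(a))
    for (i in seq_len(k)) {
      d <- d + ((a %/% 4^(i - 1)) %% 4 != (b %/% 4^(i - 1)) %% 4)
    }
    d
  }
  pmin(mm(x1, x2), mm(x1, x2r))
}

#' Build the genotype space network
#'
#' Constructs the network of all canonical double-stranded k-mers, with
#' edges between sites that differ by a single point mutation or a single
#' one-base shift indel. For k = 8 this network has 32,896 nodes and
#' 523,728 edges.
#'
#' @param k site length (default 8).
#' @return an object of class `genotype_space`: a list with elements
#'   `k`, `n`, `sites` (sorted canonical sites), `graph` (an
#'   [igraph][igraph::make_graph] graph with vertex names), `edges`
#'   (two-column integer matrix of site indices), `adj` (adjacency list of
#'   site indices) and `deg` (integer degrees).
#' @examples
#' om <- build_omega(4)
#' om$n            # 136
#' @export
build_omega <- function(k = 8) {
  k <- .check_k(k)
  all_codes <- 0:(4^k - 1)
  codes <- sort(unique(pmin(all_codes, .revcomp_code(all_codes, k))))
  n <- length(codes)
  idx <- integer(4^k)
  idx[codes + 1] <- seq_len(n)

  mut <- .mutant_codes(codes, k)
  mutc <- pmin(mut, matrix(.revcomp_code(as.vector(mut), k), nrow = n))
  from <- rep(codes, times = ncol(mut))
  to <- as.vector(mutc)
  keep <- from != to
  a <- pmin(from[keep], to[keep])
  b <- pmax(from[keep], to[keep])
  u <- !duplicated(a * 4^k + b)
  ea <- idx[a[u] + 1]
  eb <- idx[b[u] + 1]

  sites <- codes_to_sites(codes, k)
  g <- igraph::make_graph(rbind(ea, eb), n = n, directed = FALSE)
  igraph::V(g)$name <- sites
  fa <- factor(c(ea, eb), levels = seq_len(n))
  adj <- unname(split(c(eb, ea), fa))
  deg <- lengths(adj)

  structure(
    list(k = k, n = n, sites = sites, codes = codes, graph = g,
         edges = cbind(from = ea, to = eb), adj = adj, deg = deg),
    class = "genotype_space")
}

#' @export
print.genotype_space <- function(x, ...) {
  cat(sprintf("genotype space: k = %d, %d sites, %d edges\n",
              x$k, x$n, nrow(x$edges)))
  invisible(x)
}

## site character vector -> indices into omega$sites (canonicalizing)
site_index <- function(sites, omega) {
  x <- sites_to_codes(sites, omega$k)
  x <- pmin(x, .revcomp_code(x, omega$k))
  i <- match(x, omega$codes)
  if (anyNA(i)) stop("site not in genotype space", call. = FALSE)
  i
}

#' Write the genotype space edge and node lists
#'
#' @param omega a `genotype_space`.
#' @param edges_path,nodes_path output TSV paths (`NULL` to skip one).
#' @return invisibly, the paths written.
#' @export
write_omega <- function(omega, edges_path, nodes_path = NULL) {
  el <- data.frame(from = omega$sites[omega$edges[, 1]],
                   to = omega$sites[omega$edges[, 2]])
  utils::write.table(el, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(nodes_path)) {
    nd <- data.frame(site = omega$sites, degree = omega$deg)
    utils::write.table(nd, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(edges_path, nodes_path))
}
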
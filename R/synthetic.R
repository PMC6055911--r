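## Synthetic data generator: motif-centered E-score landscapes, digital
## footprints with planted binding sites, and per-position allele
## frequency tables with a controllable diversity gradient. Emits the
## same formats the I/O modules consume, so the whole pipeline runs and
## is testable without any download.

#' Specification for synthetic data generation
#'
#' The E-score of site s for a TF with consensus site c is
#' `clamp(base_score - decay * d(s, c) + noise, -0.5, 0.5)`, where d is
#' the graph distance in the genotype space (so shift-indel structure is
#' exercised, not just Hamming distance). With the defaults
#' (base 0.45, decay 0.04, threshold 0.35) the bound set is a fuzzy ball
#' of graph radius 2-3 around the consensus, a few hundred sites —
#' comparable to typical empirical genotype-set sizes.
#'
#' @param n_tfs number of TFs.
#' @param k site length.
#' @param seed integer seed used for consensus choice and noise.
#' @param base_score E-score at the consensus site.
#' @param decay E-score decrease per mutational step.
#' @param noise_sd standard deviation of Gaussian score noise (0 gives
#'   exact distance balls).
#' @param consensus optional character vector of consensus sites (one per
#'   TF); sampled uniformly from the space when `NULL`.
#' @param domains optional TF-to-domain labels; defaults to cycling
#'   through four generic domain names.
#' @param paralog_pairs number of consecutive TF pairs forced to have
#'   consensus sites at graph distance 1 (planted overlap).
#' @param n_footprints_per_tf footprints planted per TF.
#' @param footprint_len_mean,footprint_len_sd,footprint_len_range
#'   footprint length model (defaults mirror promoter footprint data:
#'   mean about 16.6 bp, lengths 8-40 bp).
#' @param planted_prob probability a footprint carries a planted bound
#'   site of its TF.
#' @param decoy_frac fraction of extra footprints that fail the filters
#'   (too short or outside promoters).
#' @param poly_prob probability a planted site is polymorphic.
#' @param div_intercept,div_b_size,div_b_L,div_sd linear model for the
#'   planted per-TF mean diversity on standardized ranks of
#'   dominant-network size and characteristic path length, plus Gaussian
#'   noise; `div_b_L = 0` plants no partial effect of path length.
#' @param site_div_sd per-site spread of diversity around the TF target.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tfs = 10, k = 8, seed = 1,
                           base_score = 0.45, decay = 0.04, noise_sd = 0.02,
                           consensus = NULL, domains = NULL,
                           paralog_pairs = 0,
                           n_footprints_per_tf = 20,
                           footprint_len_mean = 16.56,
                           footprint_len_sd = 6,
                           footprint_len_range = c(8, 40),
                           planted_prob = 1, decoy_frac = 0.2,
                           poly_prob = 0.8,
                           div_intercept = 1.0, div_b_size = 0.35,
                           div_b_L = 0.35, div_sd = 0.35,
                           site_div_sd = 0.15) {
  stopifnot(n_tfs >= 1, decay > 0, base_score > -0.5, base_score <= 0.5)
  spec <- as.list(environment())
  class(spec) <- "synthetic_spec"
  spec
}

.default_domains <- c("bHLH", "Homeodomain", "Forkhead", "Zinc finger")

#' Generate a synthetic E-score table
#'
#' @param spec a `synthetic_spec`.
#' @param omega a `genotype_space` with matching `k`.
#' @return list with `table` (an `escore_table`), `meta` (TF metadata
#'   data.frame) and `truth` (consensus sites, noise-free bound-set
#'   sizes, seed).
#' @export
generate_escore_table <- function(spec, omega) {
  stopifnot(inherits(spec, "synthetic_spec"), omega$k == spec$k)
  set.seed(spec$seed)
  tfs <- sprintf("TF%02d", seq_len(spec$n_tfs))
  cons <- spec$consensus
  if (is.null(cons)) cons <- omega$sites[sample.int(omega$n, spec$n_tfs)]
  cons <- canonical(cons)
  if (spec$paralog_pairs > 0) {
    for (p in seq_len(min(spec$paralog_pairs, spec$n_tfs %/% 2))) {
      a <- 2 * p - 1
      nb <- neighbors(cons[a])
      cons[2 * p] <- nb[sample.int(length(nb), 1)]
    }
  }
  d <- igraph::distances(omega$graph, v = site_index(cons, omega))
  E <- spec$base_score - spec$decay * t(d)
  if (spec$noise_sd > 0)
    E <- E + matrix(stats::rnorm(length(E), sd = spec$noise_sd), nrow(E))
  E <- pmin(pmax(E, -0.5), 0.5)
  dimnames(E) <- list(omega$sites, tfs)
  domains <- spec$domains
  if (is.null(domains))
    domains <- rep_len(.default_domains, spec$n_tfs)
  meta <- data.frame(tf_id = tfs, species = "synthetic",
                     domain = domains, stringsAsFactors = FALSE)
  exact_sizes <- vapply(seq_len(spec$n_tfs), function(j)
    sum(spec$base_score - spec$decay * d[j, ] > 0.35), 0L)
  list(table = escore_table(E, spec$k), meta = meta,
       truth = list(consensus = stats::setNames(cons, tfs),
                    noise_free_size_tau035 = stats::setNames(exact_sizes, tfs),
                    seed = spec$seed))
}

## entropy of (p, (1-p)/3, (1-p)/3, (1-p)/3); invertible on p in [0.25, 1]
.entropy_grid <- local({
  p <- seq(0.25, 1, length.out = 2001)
  q <- (1 - p) / 3
  H <- ifelse(p > 0, -p * log2(p), 0) + 3 * ifelse(q > 0, -q * log2(q), 0)
  list(p = p, H = H)
})

## major-allele frequency giving per-position entropy h (bits, in [0, 2])
.p_major_for_entropy <- function(h) {
  h <- pmin(pmax(h, 0), 2)
  stats::approx(.entropy_grid$H, .entropy_grid$p, xout = h, rule = 2)$y
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate synthetic in-vivo inputs
#'
#' Lays out one footprint per synthetic promoter on a single chromosome,
#' plants a (randomly strand-oriented) site from the owning TF's dominant
#' genotype network in each footprint with probability `planted_prob`,
#' adds decoy footprints that fail the length/promoter filters, and draws
#' per-position allele frequencies so that the mean diversity of a TF's
#' planted sites follows the spec's linear model on network size and
#' characteristic path length.
#'
#' @param spec a `synthetic_spec`.
#' @param networks named list of dominant-network site vectors (source of
#'   planted sites), e.g. from [dominant_networks()].
#' @param intra data.frame from [intranetwork_report()] (needs `tf_id`,
#'   `dominant_size`, `L`).
#' @param seed integer seed for this draw (footprints, planting, allele
#'   frequencies); independent of the E-score seed so replicate in-vivo
#'   datasets can share one landscape.
#' @return list with `footprints` (BED-style data.frame), `sequences`
#'   (named character), `promoters` (BED-style data.frame), `freqs`
#'   (allele-frequency data.frame), and `truth` (per-footprint planted
#'   site table and the diversity model used).
#' @export
generate_invivo <- function(spec, networks, intra, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  tfs <- names(networks)
  stopifnot(all(tfs %in% intra$tf_id))
  intra <- intra[match(tfs, intra$tf_id), ]
  zr <- function(v) {          # standardized ranks; all-tied -> zeros
    r <- rank(v)
    if (stats::sd(r) == 0) return(rep(0, length(v)))
    as.vector(scale(r))
  }
  d_target <- spec$div_intercept +
    spec$div_b_size * zr(intra$dominant_size) +
    spec$div_b_L * zr(intra$L) +
    stats::rnorm(length(tfs), sd = spec$div_sd)
  d_target <- pmin(pmax(d_target, 0.05), 1.95)
  names(d_target) <- tfs

  k <- spec$k
  block <- 1200L                     # one gene/promoter per block
  n_main <- spec$n_footprints_per_tf * length(tfs)
  n_decoy <- ceiling(spec$decoy_frac * n_main)
  n_blocks <- n_main + n_decoy
  tss <- (seq_len(n_blocks) - 1L) * block + 700L
  promoters <- data.frame(chrom = "chr1", start = tss - 500L, end = tss)

  draw_len <- function(n) {
    l <- round(stats::rnorm(n, spec$footprint_len_mean, spec$footprint_len_sd))
    pmin(pmax(l, spec$footprint_len_range[1]), spec$footprint_len_range[2])
  }

  fp <- list(); seqs <- character(0); truth <- list(); freqs <- list()
  fid <- 0L
  for (t in seq_along(tfs)) {
    for (j in seq_len(spec$n_footprints_per_tf)) {
      fid <- fid + 1L
      len <- draw_len(1)
      start <- promoters$start[fid] + sample.int(500L - len, 1)
      seq <- .rand_dna(len)
      planted <- stats::runif(1) < spec$planted_prob
      site <- NA_character_; off <- NA_integer_; poly <- FALSE
      Dsite <- 0
      if (planted) {
        site <- networks[[t]][sample.int(length(networks[[t]]), 1)]
        oriented <- if (stats::runif(1) < 0.5) site else revcomp(site)
        off <- sample.int(len - k + 1L, 1)
        substr(seq, off, off + k - 1L) <- oriented
        poly <- stats::runif(1) < spec$poly_prob
        if (poly) {
          Dsite <- pmin(pmax(stats::rnorm(1, d_target[t], spec$site_div_sd),
                             0.02), 1.98)
          pmaj <- .p_major_for_entropy(rep(Dsite, k))
          bases <- strsplit(oriented, "")[[1]]
          fm <- matrix((1 - pmaj) / 3, nrow = k, ncol = 4,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
          fm[cbind(seq_len(k), match(bases, colnames(fm)))] <- pmaj
          freqs[[length(freqs) + 1L]] <- data.frame(
            chrom = "chr1", pos = start + off - 1L + seq_len(k), fm)
        }
      }
      nm <- sprintf("fp%05d", fid)
      fp[[fid]] <- data.frame(chrom = "chr1", start = start,
                              end = start + len, name = nm)
      seqs[nm] <- seq
      truth[[fid]] <- data.frame(footprint = nm, tf_id = tfs[t],
                                 planted = planted, site = site,
                                 start = if (planted) start + off - 1L else NA,
                                 polymorphic = poly, D = Dsite,
                                 stringsAsFactors = FALSE)
    }
  }
  ## decoys: alternately too short and outside any promoter
  for (j in seq_len(n_decoy)) {
    fid <- fid + 1L
    nm <- sprintf("fp%05d", fid)
    if (j %% 2 == 1) {             # too short, inside a promoter
      len <- sample(4:(k - 1), 1)
      start <- promoters$start[fid] + sample.int(400L, 1)
    } else {                       # long enough, downstream of the TSS
      len <- draw_len(1)
      start <- promoters$end[fid] + 50L
    }
    fp[[fid]] <- data.frame(chrom = "chr1", start = start, end = start + len,
                            name = nm)
    seqs[nm] <- .rand_dna(len)
    truth[[fid]] <- data.frame(footprint = nm, tf_id = NA_character_,
                               planted = FALSE, site = NA_character_,
                               start = NA_integer_, polymorphic = FALSE,
                               D = 0, stringsAsFactors = FALSE)
  }
  freqs <- if (length(freqs)) do.call(rbind, freqs) else
    data.frame(chrom = character(), pos = integer(), A = numeric(),
               C = numeric(), G = numeric(), `T` = numeric(),
               check.names = FALSE)
  list(footprints = do.call(rbind, fp), sequences = seqs,
       promoters = promoters, freqs = freqs,
       truth = list(footprints = do.call(rbind, truth),
                    d_target = d_target,
                    model = c(intercept = spec$div_intercept,
                              b_size = spec$div_b_size,
                              b_L = spec$div_b_L, sd = spec$div_sd),
                    seed = seed))
}

#' Write BED intervals
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (0-based half-open coordinates).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), colnames(df))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED intervals
#'
#' @param path BED path (3 or more columns, no header).
#' @return data.frame with `chrom`, `start`, `end` and, if present,
#'   `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  colnames(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) colnames(df)[4] <- "name"
  df[, seq_len(min(4, ncol(df)))]
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA sequences
#'
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write an allele frequency table
#'
#' @param freqs data.frame as produced by [generate_invivo()].
#' @param path output TSV path.
#' @export
write_allele_freqs <- function(freqs, path) {
  utils::write.table(freqs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write allele frequencies as a minimal VCF
#'
#' Each polymorphic position becomes one biallelic SNP record whose `AF`
#' INFO field is the total non-reference frequency, the reference allele
#' being the major allele and the alternate the most frequent minor
#' allele. This loses the minor-minor allele split and is intended for
#' round-trip testing of the VCF ingestion path.
#'
#' @param freqs allele-frequency data.frame.
#' @param path output VCF path.
#' @export
write_vcf_af <- function(freqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
               "##contig=<ID=chr1>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  al <- c("A", "C", "G", "T")
  for (r in seq_len(nrow(freqs))) {
    p <- as.numeric(freqs[r, al])
    ref <- which.max(p)
    minor <- order(p, decreasing = TRUE)[2]
    if (p[minor] <= 0) next
    writeLines(sprintf("chr1\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6f",
                       freqs$pos[r], al[ref], al[minor], 1 - p[ref]), con)
  }
  invisible(path)
}
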
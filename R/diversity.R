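## In-vivo analysis: DNase footprint filtering, putative binding-site
## assignment from E-scores, Shannon diversity of binding sites from
## population allele frequencies, and rank correlations between network
## structure and diversity.

## accept GRanges or 0-based half-open data.frame(chrom, start, end[, name])
.as_granges <- function(x, what = "intervals") {
  if (methods::is(x, "GRanges")) return(x)
  if (is.data.frame(x)) {
    need <- c("chrom", "start", "end")
    if (!all(need %in% colnames(x)))
      stop(what, " need columns chrom, start, end", call. = FALSE)
    if (any(x$end < x$start))
      stop(what, ": negative-length interval", call. = FALSE)
    gr <- GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(start = x$start + 1L, end = x$end))
    if ("name" %in% colnames(x)) names(gr) <- x$name
    return(gr)
  }
  stop(what, " must be a GRanges or a data.frame", call. = FALSE)
}

#' Filter digital footprints
#'
#' Keeps footprints that are at least `min_len` nucleotides long and
#' overlap a promoter interval by at least one base.
#'
#' @param footprints,promoters GRanges, or data.frames with 0-based
#'   half-open `chrom`, `start`, `end` (BED convention).
#' @param min_len minimum footprint length (default 8, one binding site).
#' @return GRanges of retained footprints.
#' @export
filter_footprints <- function(footprints, promoters, min_len = 8) {
  fp <- .as_granges(footprints, "footprints")
  pr <- .as_granges(promoters, "promoters")
  keep <- IRanges::width(fp) >= min_len &
    GenomicRanges::countOverlaps(fp, pr) > 0
  fp[keep]
}

#' Promoter intervals from transcription start sites
#'
#' The promoter of a gene is the `width` bp upstream of its TSS on the
#' gene's strand, as a 0-based half-open interval clipped at 0.
#'
#' @param tss data.frame with `chrom`, `pos` (0-based TSS coordinate) and
#'   `strand` (`"+"`/`"-"`).
#' @param width promoter width in bp (default 500).
#' @return GRanges of promoters.
#' @export
promoters_from_tss <- function(tss, width = 500) {
  start <- ifelse(tss$strand == "+", pmax(tss$pos - width, 0), tss$pos)
  end <- ifelse(tss$strand == "+", tss$pos, tss$pos + width)
  .as_granges(data.frame(chrom = tss$chrom, start = start, end = end),
              "promoters")
}

#' Assign putative binding sites to TFs within footprints
#'
#' Scans every k-mer window of each footprint (both strands, via
#' canonicalization); for each TF, windows with E-score above `tau`
#' qualify, and if a footprint holds several qualifying windows for one
#' TF a single window is chosen uniformly at random.
#'
#' @param footprints GRanges (or BED-style data.frame) of footprints.
#' @param sequences character vector (or
#'   [Biostrings::DNAStringSet]) of footprint sequences, parallel
#'   to `footprints`.
#' @param table an `escore_table`.
#' @param tau affinity threshold.
#' @param seed integer seed for the random window choice.
#' @return data.frame with one row per (TF, footprint) assignment:
#'   `tf_id`, `footprint`, `chrom`, `start` (0-based genomic start of the
#'   window), `window` (genomic-strand k-mer) and `site` (canonical
#'   k-mer).
#' @export
assign_sites <- function(footprints, sequences, table, tau = 0.35,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fp <- .as_granges(footprints, "footprints")
  seqs <- toupper(as.character(sequences))
  if (length(seqs) != length(fp))
    stop("one sequence per footprint required", call. = FALSE)
  if (any(nchar(seqs) != IRanges::width(fp)))
    stop("sequence length must equal footprint width", call. = FALSE)
  k <- table$k
  fp_names <- if (is.null(names(fp))) as.character(seq_along(fp)) else names(fp)
  rows <- vector("list", length(fp))
  for (f in seq_along(fp)) {
    len <- nchar(seqs[f])
    if (len < k) next
    off <- seq_len(len - k + 1L)
    wins <- substring(seqs[f], off, off + k - 1L)
    can <- canonical(wins)
    sc <- table$scores[can, , drop = FALSE]
    hits <- sc > tau
    picks <- lapply(seq_along(table$tfs), function(j) {
      w <- which(hits[, j])
      if (!length(w)) return(NULL)
      w[if (length(w) == 1) 1 else sample.int(length(w), 1)]
    })
    got <- !vapply(picks, is.null, TRUE)
    if (!any(got)) next
    wsel <- unlist(picks[got])
    rows[[f]] <- data.frame(
      tf_id = table$tfs[got], footprint = fp_names[f],
      chrom = as.character(GenomicRanges::seqnames(fp))[f],
      start = GenomicRanges::start(fp)[f] - 1L + wsel - 1L,
      window = wins[wsel], site = can[wsel], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(tf_id = character(), footprint = character(),
                      chrom = character(), start = integer(),
                      window = character(), site = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shannon's diversity index of a binding site
#'
#' `D = -(1/k) sum_i sum_j p_ij log2(p_ij)` over the k positions of the
#' site and the four nucleotides, with `0 log2 0 = 0`. D is 0 for a
#' monomorphic site and 2 when all four alleles are equally frequent at
#' every position.
#'
#' @param freqs numeric matrix, positions in rows and alleles A, C, G, T
#'   in columns; each row must sum to 1 (tolerance 1e-6).
#' @return diversity in `[0, 2]` bits.
#' @export
shannon_diversity <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 4) stop("freqs must have 4 allele columns", call. = FALSE)
  if (any(abs(rowSums(freqs) - 1) > 1e-6))
    stop("allele frequencies must sum to 1 at every position", call. = FALSE)
  if (any(freqs < 0)) stop("negative allele frequency", call. = FALSE)
  h <- ifelse(freqs > 0, -freqs * log2(freqs), 0)
  sum(h) / nrow(freqs)
}

#' Read a per-position allele frequency table
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `A`, `C`, `G`,
#'   `T`.
#' @return data.frame of the same columns.
#' @export
read_allele_freqs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "A", "C", "G", "T")
  if (!all(need %in% colnames(df)))
    stop("allele frequency table needs columns chrom, pos, A, C, G, T",
         call. = FALSE)
  df[, need]
}

#' Allele frequencies from a VCF
#'
#' Reads biallelic SNP records and converts their `AF` INFO field into a
#' per-position allele frequency table (reference allele gets `1 - AF`).
#' Positions without a record are monomorphic reference. Requires the
#' VariantAnnotation package.
#'
#' @param path VCF file path.
#' @return data.frame as from [read_allele_freqs()].
#' @export
allele_freqs_from_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("allele_freqs_from_vcf requires the VariantAnnotation package",
         call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  keep <- lengths(altl) == 1 & nchar(ref) == 1
  alt <- rep(NA_character_, length(ref))
  alt[keep] <- as.character(unlist(altl[keep]))
  keep <- keep & alt %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")
  af <- unlist(VariantAnnotation::info(vcf)$AF)[keep]
  ref <- ref[keep]; alt <- alt[keep]; rr <- rr[keep]
  m <- matrix(0, nrow = sum(keep), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(nrow(m)), match(ref, colnames(m)))] <- 1 - af
  m[cbind(seq_len(nrow(m)), match(alt, colnames(m)))] <- af
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr), m, stringsAsFactors = FALSE)
}

#' Shannon diversity of assigned binding sites
#'
#' Looks up the allele frequencies at the 8 genomic positions of each
#' assigned site; positions without a polymorphism record are treated as
#' monomorphic (entropy 0).
#'
#' @param assignments data.frame from [assign_sites()].
#' @param freqs allele frequency table (see [read_allele_freqs()]).
#' @param k site length (default 8).
#' @return `assignments` with added columns `D` and `polymorphic`.
#' @export
site_diversity <- function(assignments, freqs, k = 8) {
  key <- paste(freqs$chrom, freqs$pos)
  fm <- as.matrix(freqs[, c("A", "C", "G", "T")])
  if (any(abs(rowSums(fm) - 1) > 1e-6))
    stop("allele frequencies must sum to 1 at every position", call. = FALSE)
  D <- numeric(nrow(assignments))
  poly <- logical(nrow(assignments))
  for (r in seq_len(nrow(assignments))) {
    pos <- assignments$start[r] + seq_len(k)      # 1-based genomic positions
    i <- match(paste(assignments$chrom[r], pos), key)
    present <- !is.na(i)
    if (any(present)) {
      p <- fm[i[present], , drop = FALSE]
      h <- ifelse(p > 0, -p * log2(p), 0)
      D[r] <- sum(h) / k
      poly[r] <- any(apply(p, 1, max) < 1)
    }
  }
  assignments$D <- D
  assignments$polymorphic <- poly
  assignments
}

#' Partial Spearman correlation
#'
#' Spearman correlation of `x` and `y` controlling for `z`: Pearson
#' partial correlation of the rank-transformed variables, with a
#' two-sided t-test on `n - 3` degrees of freedom.
#'
#' @param x,y,z numeric vectors of equal length (n >= 4).
#' @return list with `rho` and `p`.
#' @export
partial_spearman <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- rank(x[ok]); y <- rank(y[ok]); z <- rank(z[ok])
  n <- length(x)
  if (n < 4) stop("insufficient data: need >= 4 complete cases", call. = FALSE)
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  tstat <- rho * sqrt((n - 3) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 3))
}

#' Correlations between network structure and binding site diversity
#'
#' Per-TF diversity is summarized as the mean (or median) Shannon
#' diversity of the TF's polymorphic assigned sites. Reported are the
#' Spearman correlation of diversity with dominant-network size, and
#' partial Spearman correlations (controlling for size) of diversity
#' with characteristic path length, route factor and assortativity.
#'
#' @param intra_table data.frame from [intranetwork_report()].
#' @param diversity data.frame from [site_diversity()].
#' @param summary `"mean"` (default) or `"median"` per-TF summary.
#' @return list with `per_tf` (merged per-TF table) and `correlations`
#'   (data.frame: metric, rho, p, type).
#' @export
structure_diversity_correlations <- function(intra_table, diversity,
                                             summary = c("mean", "median")) {
  summary <- match.arg(summary)
  fun <- if (summary == "mean") mean else stats::median
  poly <- diversity[diversity$polymorphic, ]
  d_tf <- stats::aggregate(D ~ tf_id, data = poly, FUN = fun)
  tab <- merge(intra_table, d_tf, by = "tf_id")
  tab <- tab[!tab$degenerate & stats::complete.cases(
    tab$D, tab$dominant_size, tab$L, tab$q, tab$r), ]
  if (nrow(tab) < 4)
    stop("insufficient data: < 4 TFs with diversity and metrics",
         call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(tab$D, tab$dominant_size, method = "spearman"))
  rows <- data.frame(metric = "dominant_size",
                     rho = unname(ct$estimate), p = ct$p.value,
                     type = "spearman", stringsAsFactors = FALSE)
  for (mt in c("L", "q", "r")) {
    ps <- partial_spearman(tab$D, tab[[mt]], tab$dominant_size)
    rows <- rbind(rows, data.frame(metric = mt, rho = ps$rho, p = ps$p,
                                   type = "partial_spearman_given_size"))
  }
  list(per_tf = tab, correlations = rows)
}
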
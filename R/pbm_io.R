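## Protein binding microarray E-score tables and TF metadata.
##
## An E-score table stores one affinity score in [-0.5, 0.5] per canonical
## site per TF. Two tab-separated dialects are accepted: the per-TF
## three-column layout "8mer <tab> 8mer_rc <tab> E-score" used by PBM
## repositories, and a wide matrix "8mer <tab> TF1 <tab> TF2 ...".

#' Construct an E-score table
#'
#' @param scores numeric matrix, sites in rows (rownames are canonical
#'   sites covering the full space returned by [enumerate_space()]),
#'   TFs in columns.
#' @param k site length.
#' @return an object of class `escore_table` with elements `scores`,
#'   `tfs`, `k`.
#' @export
escore_table <- function(scores, k = nchar(rownames(scores)[1])) {
  k <- .check_k(k)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores must have site rownames and TF colnames", call. = FALSE)
  space <- enumerate_space(k)
  if (!identical(rownames(scores), space)) {
    i <- match(space, rownames(scores))
    if (anyNA(i))
      stop("incomplete E-score table: ", sum(is.na(i)), " canonical ",
           k, "-mers missing", call. = FALSE)
    scores <- scores[i, , drop = FALSE]
  }
  rng <- range(scores, na.rm = TRUE)
  if (rng[1] < -0.5 || rng[2] > 0.5)
    stop("E-scores outside [-0.5, 0.5]", call. = FALSE)
  structure(list(scores = scores, tfs = colnames(scores), k = k),
            class = "escore_table")
}

#' @export
print.escore_table <- function(x, ...) {
  cat(sprintf("E-score table: %d canonical %d-mers x %d TFs\n",
              nrow(x$scores), x$k, length(x$tfs)))
  invisible(x)
}

## merge scores of a possibly-redundant (site, score) listing onto the
## canonical space, checking reverse-complement consistency
.merge_canonical_scores <- function(sites, scores, k, what) {
  can <- canonical(sites)
  ord <- order(can)
  can <- can[ord]
  scores <- scores[ord]
  dup <- duplicated(can)
  if (any(dup)) {
    first <- match(can[dup], can)
    bad <- abs(scores[dup] - scores[first]) > 1e-9
    if (any(bad))
      stop(what, ": conflicting E-scores for reverse-complement pair ",
           can[dup][bad][1], call. = FALSE)
  }
  list(sites = can[!dup], scores = scores[!dup])
}

.validate_scores <- function(x, what, line = NULL) {
  if (anyNA(x))
    stop(what, ": non-numeric or missing E-score", call. = FALSE)
  if (any(x < -0.5 | x > 0.5))
    stop(what, ": E-score outside [-0.5, 0.5]",
         if (!is.null(line)) paste0(" at line ", line[which(x < -0.5 | x > 0.5)[1]]),
         call. = FALSE)
}

#' Read an E-score table
#'
#' Auto-detects the dialect: a file whose second column contains k-mers is
#' read as a per-TF "8mer, 8mer_rc, E-score" listing (TF id taken from
#' `tf_id` or the file name); otherwise the file is read as a wide site x
#' TF matrix. Rows are canonicalized; the two rows of a reverse-complement
#' pair must agree in score.
#'
#' @param path TSV file path.
#' @param tf_id TF identifier for the per-TF dialect (default: file base
#'   name without extension).
#' @param allow_missing if `TRUE`, sites absent from the file get score
#'   `-0.5` (treated as unbound) with a warning; if `FALSE` (default) an
#'   incomplete table is an error.
#' @return an `escore_table`.
#' @export
read_escore_table <- function(path, tf_id = NULL, allow_missing = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("parse error: expected >= 2 tab-separated columns",
                         call. = FALSE)
  k <- nchar(as.character(df[[1]][1]))
  is_seq <- function(v) all(grepl("^[ACGTacgt]+$", as.character(v)))
  if (!is_seq(df[[1]]))
    stop("parse error at line 2: first column is not a DNA sequence",
         call. = FALSE)
  if (ncol(df) >= 2 && is_seq(df[[2]]) && all(nchar(as.character(df[[2]])) == k)) {
    ## per-TF dialect: 8mer, 8mer_rc, E-score [, ...]
    if (ncol(df) < 3) stop("parse error: per-TF dialect needs 3 columns",
                           call. = FALSE)
    if (is.null(tf_id))
      tf_id <- sub("\\.[^.]*$", "", basename(path))
    sc <- suppressWarnings(as.numeric(df[[3]]))
    .validate_scores(sc, basename(path), line = seq_len(nrow(df)) + 1L)
    m <- .merge_canonical_scores(as.character(df[[1]]), sc, k, basename(path))
    scores <- matrix(m$scores, ncol = 1,
                     dimnames = list(m$sites, tf_id))
  } else {
    tf <- colnames(df)[-1]
    sc <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(sc) <- "double"
    .validate_scores(sc, basename(path))
    merged <- lapply(seq_along(tf), function(j)
      .merge_canonical_scores(as.character(df[[1]]), sc[, j], k,
                              paste0(basename(path), ":", tf[j])))
    sites <- merged[[1]]$sites
    scores <- do.call(cbind, lapply(merged, `[[`, "scores"))
    dimnames(scores) <- list(sites, tf)
  }
  space <- enumerate_space(k)
  miss <- setdiff(space, rownames(scores))
  if (length(miss)) {
    if (!allow_missing)
      stop("incomplete E-score table: ", length(miss), " canonical ",
           k, "-mers missing (use allow_missing = TRUE to treat as unbound)",
           call. = FALSE)
    warning(length(miss), " missing sites treated as unbound (score -0.5)")
    fill <- matrix(-0.5, nrow = length(miss), ncol = ncol(scores),
                   dimnames = list(miss, colnames(scores)))
    scores <- rbind(scores, fill)
  }
  escore_table(scores[space, , drop = FALSE], k)
}

#' Read a directory of per-TF E-score files
#'
#' @param dir directory containing per-TF TSV files.
#' @param pattern file name pattern (default all `.tsv`/`.txt`).
#' @inheritParams read_escore_table
#' @return an `escore_table` with one column per file.
#' @export
read_escore_dir <- function(dir, pattern = "\\.(tsv|txt)$",
                            allow_missing = FALSE) {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop("no E-score files in ", dir, call. = FALSE)
  tabs <- lapply(files, read_escore_table, allow_missing = allow_missing)
  scores <- do.call(cbind, lapply(tabs, function(t) t$scores))
  escore_table(scores, tabs[[1]]$k)
}

#' Write an E-score table (wide dialect)
#'
#' @param table an `escore_table`.
#' @param path output TSV path.
#' @export
write_escore_table <- function(table, path) {
  df <- data.frame(`8mer` = rownames(table$scores), table$scores,
                   check.names = FALSE)
  colnames(df)[1] <- paste0(table$k, "mer")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read TF metadata
#'
#' @param path TSV with columns `tf_id`, `species`, `domain`.
#' @return data.frame with those columns.
#' @export
read_tf_meta <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("tf_id", "species", "domain")
  if (!all(need %in% colnames(df)))
    stop("TF metadata must have columns tf_id, species, domain",
         call. = FALSE)
  if (anyDuplicated(df$tf_id))
    stop("duplicate tf_id in metadata", call. = FALSE)
  df[, need]
}

#' Sites bound by a TF at threshold tau
#'
#' A site belongs to the genotype set of TF `tf_id` when its E-score is
#' strictly greater than `tau`; sites with score equal to or below `tau`
#' are unbound (or bound non-specifically).
#'
#' @param table an `escore_table`.
#' @param tf_id TF column name.
#' @param tau affinity threshold (default 0.35).
#' @return character vector of canonical bound sites.
#' @export
bound_sites <- function(table, tf_id, tau = 0.35) {
  if (!tf_id %in% table$tfs)
    stop("unknown TF: ", tf_id, call. = FALSE)
  rownames(table$scores)[table$scores[, tf_id] > tau]
}

#' Sites unbound by every TF in a list
#'
#' @param table an `escore_table`.
#' @param tf_list TF ids (default: all TFs in the table).
#' @inheritParams bound_sites
#' @return list with `sites` (character vector) and `fraction`
#'   (share of the genotype space that is unbound).
#' @export
unbound_sites <- function(table, tf_list = table$tfs, tau = 0.35) {
  if (!length(tf_list)) stop("empty tf_list", call. = FALSE)
  if (!all(tf_list %in% table$tfs))
    stop("unknown TF in tf_list", call. = FALSE)
  any_bound <- rowSums(table$scores[, tf_list, drop = FALSE] > tau) > 0
  sites <- rownames(table$scores)[!any_bound]
  list(sites = sites, fraction = length(sites) / nrow(table$scores))
}
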
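## Size-preserving null model: binding sites are randomly reassigned to
## TFs so that the number of sites per TF is unchanged, and every
## statistic is recomputed on the randomized genotype sets.

#' Randomize site-to-TF assignments
#'
#' Each phenotype receives a uniform random sample (without replacement
#' within the phenotype) of the same number of sites as its empirical
#' genotype set. By default sites are drawn from the whole genotype
#' space, so the null expectation of any mutation probability `phi[q, p]`
#' is the phenotype frequency `f_q`; with `universe = "bound"` sites are
#' drawn only from the union of empirically bound sites.
#'
#' @param sets named list of empirical genotype sets (site vectors), or a
#'   named integer vector of set sizes.
#' @param omega a `genotype_space`.
#' @param seed optional integer seed.
#' @param universe `"omega"` (default) or `"bound"`.
#' @return named list of randomized site vectors with preserved sizes.
#' @export
randomize_assignment <- function(sets, omega, seed = NULL,
                                 universe = c("omega", "bound")) {
  universe <- match.arg(universe)
  if (!is.null(seed)) set.seed(seed)
  sizes <- if (is.numeric(sets)) sets else lengths(sets)
  if (is.null(names(sizes))) stop("sets must be named", call. = FALSE)
  pool <- if (universe == "bound") {
    if (is.numeric(sets))
      stop("universe = 'bound' needs the site lists, not sizes", call. = FALSE)
    site_index(unique(unlist(sets)), omega)
  } else seq_len(omega$n)
  if (any(sizes > length(pool)))
    stop("set size exceeds sampling universe", call. = FALSE)
  out <- lapply(sizes, function(sz) sort(omega$sites[sample(pool, sz)]))
  names(out) <- names(sizes)
  out
}

#' Null ensemble of randomized genotype sets
#'
#' @inheritParams randomize_assignment
#' @param n_reps number of replicates (the reference analysis uses 1000;
#'   scale down for desk runs).
#' @param seed integer seed; replicate r uses `seed + r`.
#' @return list of `n_reps` randomized set lists (class `null_ensemble`).
#' @export
null_ensemble <- function(sets, omega, n_reps = 1000, seed = 1,
                          universe = c("omega", "bound")) {
  universe <- match.arg(universe)
  reps <- lapply(seq_len(n_reps), function(r)
    randomize_assignment(sets, omega, seed = seed + r, universe = universe))
  structure(reps, class = "null_ensemble", seed = seed)
}

#' Null distribution of a statistic
#'
#' Applies `metric_fn` to every replicate of a null ensemble and
#' summarizes the resulting distribution; optionally locates an empirical
#' value in it.
#'
#' @param metric_fn function taking one randomized set list and returning
#'   a single number (may return `NA`; such replicates are excluded and
#'   counted).
#' @param ensemble a `null_ensemble`.
#' @param empirical optional empirical value of the same statistic.
#' @return list with `values`, `mean`, `sd`, `quantiles` (2.5/50/97.5%),
#'   `n_na`, and when `empirical` is given, `empirical`, `percentile`
#'   (fraction of null values <= empirical) and `z`.
#' @export
null_distribution <- function(metric_fn, ensemble, empirical = NULL) {
  vals <- vapply(ensemble, function(rep) as.numeric(metric_fn(rep)), 0)
  n_na <- sum(is.na(vals))
  v <- vals[!is.na(vals)]
  out <- list(values = vals, mean = mean(v), sd = stats::sd(v),
              quantiles = stats::quantile(v, c(0.025, 0.5, 0.975)),
              n_na = n_na)
  if (!is.null(empirical)) {
    out$empirical <- empirical
    out$percentile <- mean(v <= empirical)
    out$z <- if (out$sd > 0) (empirical - out$mean) / out$sd else NaN
  }
  out
}

#' Null expectation of mutation probabilities
#'
#' Under random size-preserving reassignment over the whole genotype
#' space, the expected `phi[q, p]` equals the phenotype frequency
#' `f_q = |S(Gq)| / |Omega|`.
#'
#' @param sets named list of genotype sets (or dominant networks).
#' @param omega a `genotype_space`.
#' @return named numeric vector `f_q`.
#' @export
null_phi_expectation <- function(sets, omega) {
  vapply(.dominant_sets(sets), function(s) length(s) / omega$n, 0)
}
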
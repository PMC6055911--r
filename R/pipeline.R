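## End-to-end orchestration: space -> load -> networks -> intra -> inter
## -> null -> (optional) in-vivo, each stage writing TSVs plus a JSON
## manifest with seeds and checksums.

#' Summary statistics of the genotype space
#'
#' @param omega a `genotype_space`.
#' @param paths compute the all-pairs diameter and characteristic path
#'   length (one full BFS sweep; a few minutes at k = 8).
#' @return named list: `nodes`, `edges`, `max_degree`,
#'   `frac_max_degree`, `clustering`, `assortativity`, and with
#'   `paths = TRUE` also `diameter` and `L`.
#' @export
omega_report <- function(omega, paths = TRUE) {
  out <- list(nodes = omega$n, edges = nrow(omega$edges),
              max_degree = max(omega$deg),
              frac_max_degree = mean(omega$deg == max(omega$deg)),
              clustering = clustering_coefficient(omega),
              assortativity = degree_assortativity(omega))
  if (paths) {
    pm <- path_metrics(omega)
    out$diameter <- pm$diameter
    out$L <- pm$L
  }
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## mean-over-TFs intranetwork metrics on a list of genotype sets;
## used for the null-model stage
.mean_intra_metrics <- function(sets, omega) {
  vals <- lapply(sets, function(s) {
    gn <- genotype_networks(s, omega)
    if (length(gn$dominant) < 2)
      return(c(diameter = NA, L = NA, c = NA, r = NA))
    g <- induced_graph(gn$dominant, omega)
    pm <- path_metrics(g)
    c(diameter = pm$diameter, L = pm$L, c = clustering_coefficient(g),
      r = if (igraph::ecount(g) >= 1) degree_assortativity(g) else NaN)
  })
  colMeans(do.call(rbind, vals), na.rm = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages: genotype space, E-score loading, per-TF intranetwork metrics
#' (for `tau` and each value of `tau_grid`), internetwork matrices and
#' phenotype network at `tau` (TF or domain level), an optional
#' null-model comparison, and an optional in-vivo diversity analysis.
#' Every output is a TSV under `outdir`; `manifest.json` records the
#' configuration, seeds and MD5 checksums.
#'
#' @param escore an `escore_table`, or a path to a wide TSV/directory of
#'   per-TF files.
#' @param outdir output directory (created if needed).
#' @param meta optional TF metadata (data.frame or TSV path).
#' @param tau affinity threshold.
#' @param tau_grid extra thresholds for the sensitivity analysis
#'   (conventionally inside (0.35, 0.45)).
#' @param level `"tf"` or `"domain"` phenotype granularity for the
#'   internetwork stage.
#' @param null_reps null-model replicates (0 disables the stage).
#' @param seed integer seed for all randomized stages.
#' @param omega optional prebuilt `genotype_space` (rebuilt when `NULL`).
#' @param invivo optional list with `footprints`, `sequences`,
#'   `promoters`, `freqs` (objects or file paths) for the diversity
#'   stage.
#' @param omega_paths compute the expensive all-pairs space statistics in
#'   the space report (default `FALSE`).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(escore, outdir, meta = NULL, tau = 0.35,
                         tau_grid = NULL, level = c("tf", "domain"),
                         null_reps = 0, seed = 1, omega = NULL,
                         invivo = NULL, omega_paths = FALSE) {
  level <- match.arg(level)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)

  ## load
  table <- stage("load", {
    if (inherits(escore, "escore_table")) escore
    else if (dir.exists(escore)) read_escore_dir(escore)
    else read_escore_table(escore)
  })
  if (is.character(meta)) meta <- stage("load", read_tf_meta(meta))

  ## space
  if (is.null(omega)) omega <- stage("space", build_omega(table$k))
  rep_space <- stage("space", omega_report(omega, paths = omega_paths))
  files <- c(files, .write_tsv(
    data.frame(statistic = names(rep_space),
               value = unlist(rep_space)),
    file.path(outdir, "space_report.tsv")))

  ## intranetwork (tau + sensitivity grid)
  intra <- NULL
  for (t in unique(c(tau, tau_grid))) {
    it <- stage("intra", intranetwork_report(table, omega, meta, tau = t))
    if (t == tau) intra <- it
    files <- c(files, .write_tsv(
      it, file.path(outdir, sprintf("intra_tau%.3f.tsv", t))))
  }

  ## internetwork
  nets <- stage("inter", {
    if (level == "domain") {
      if (is.null(meta)) stop("domain level requires TF metadata")
      sets <- domain_coarse_grain(table, meta, tau)
      lapply(sets, function(s) genotype_networks(s, omega)$dominant)
    } else dominant_networks(table, omega, tau)
  })
  O <- stage("inter", overlap_matrix(nets, omega))
  phi <- stage("inter", phi_matrix(nets, omega))
  A <- stage("inter", accessibility_matrix(nets, omega))
  files <- c(files,
             write_matrix(O, file.path(outdir, "overlap.tsv")),
             write_matrix(phi, file.path(outdir, "phi.tsv")),
             write_matrix(A, file.path(outdir, "accessibility.tsv")))
  files <- c(files, .write_tsv(
    data.frame(phenotype = names(global_connectivity(phi)),
               Phi = global_connectivity(phi),
               f_q = null_phi_expectation(nets, omega)),
    file.path(outdir, "connectivity.tsv")))
  files <- c(files, .write_tsv(stage("inter", phenotype_network(nets, omega)),
                               file.path(outdir, "phenotype_network.tsv")))
  unb <- stage("inter", unbound_sites(table, tau = tau))
  files <- c(files, .write_tsv(
    stage("inter", unbound_interface(nets, unb$sites, omega)),
    file.path(outdir, "unbound_interface.tsv")))

  ## null model
  if (null_reps > 0) {
    ens <- stage("null", null_ensemble(nets, omega, n_reps = null_reps,
                                       seed = seed))
    emp <- .mean_intra_metrics(nets, omega)
    rows <- lapply(names(emp), function(mn) {
      nd <- null_distribution(function(sets)
        .mean_intra_metrics(sets, omega)[[mn]], ens, empirical = emp[[mn]])
      data.frame(metric = mn, empirical = emp[[mn]], null_mean = nd$mean,
                 null_sd = nd$sd, percentile = nd$percentile)
    })
    files <- c(files, .write_tsv(do.call(rbind, rows),
                                 file.path(outdir, "null_summary.tsv")))
  }

  ## in-vivo
  if (!is.null(invivo)) {
    res <- stage("invivo", {
      fp <- invivo$footprints
      if (is.character(fp)) fp <- read_bed(fp)
      pr <- invivo$promoters
      if (is.character(pr)) pr <- read_bed(pr)
      seqs <- invivo$sequences
      if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs))
        seqs <- read_fasta(seqs)
      fr <- invivo$freqs
      if (is.character(fr)) fr <- read_allele_freqs(fr)
      kept <- filter_footprints(fp, pr)
      seqs <- seqs[names(kept)]
      asg <- assign_sites(kept, seqs, table, tau = tau, seed = seed)
      div <- site_diversity(asg, fr, k = table$k)
      sdc <- structure_diversity_correlations(intra, div)
      list(div = div, sdc = sdc)
    })
    files <- c(files,
               .write_tsv(res$div, file.path(outdir, "site_diversity.tsv")),
               .write_tsv(res$sdc$correlations,
                          file.path(outdir, "diversity_correlations.tsv")))
  }

  manifest <- list(
    package = "tfgpmap",
    version = as.character(utils::packageVersion("tfgpmap")),
    config = list(tau = tau, tau_grid = tau_grid, level = level,
                  null_reps = null_reps, seed = seed, k = table$k),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## ---- minimal command-line front end --------------------------------------

.cli_args <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        flags[[key]] <- args[i + 1]; i <- i + 2
      } else { flags[[key]] <- TRUE; i <- i + 1 }
    } else i <- i + 1
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `space` (build and export the genotype space), `synth`
#' (write a synthetic dataset), `run` (full pipeline on an E-score
#' table), `report` (genotype-space statistics). Invoked by the
#' `inst/exec/gpmap` script; may also be called directly.
#'
#' @param args character vector of command-line arguments (default: the
#'   trailing arguments of the Rscript call).
#' @return invisibly, the subcommand's result.
#' @export
gpmap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: gpmap <space|synth|run|report> [--flags]")
    return(invisible(NULL))
  }
  cmd <- args[1]
  fl <- .cli_args(args[-1])
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  res <- switch(
    cmd,
    space = {
      om <- build_omega(num(fl$k, 8))
      write_omega(om, fl$out %||% "edges.tsv", fl$nodes)
    },
    synth = {
      spec <- synthetic_spec(n_tfs = num(fl[["n-tfs"]], 10),
                             k = num(fl$k, 8), seed = num(fl$seed, 1))
      om <- build_omega(spec$k)
      gen <- generate_escore_table(spec, om)
      dir.create(fl$outdir %||% "synth", showWarnings = FALSE, recursive = TRUE)
      od <- fl$outdir %||% "synth"
      write_escore_table(gen$table, file.path(od, "escores.tsv"))
      .write_tsv(gen$meta, file.path(od, "meta.tsv"))
      od
    },
    run = {
      run_pipeline(fl$escores, fl$outdir %||% "out",
                   meta = fl$meta, tau = num(fl$tau, 0.35),
                   null_reps = num(fl$reps, 0), seed = num(fl$seed, 1))
    },
    report = {
      om <- build_omega(num(fl$k, 8))
      rep <- omega_report(om, paths = !isTRUE(fl$`no-paths`))
      for (n in names(rep))
        cat(sprintf("%-16s %s\n", n,
                    format(rep[[n]], digits = 6, big.mark = ",")))
      rep
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
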
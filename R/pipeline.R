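# End-to-end screening pipeline: read or simulate -> JIP-test table ->
# band analysis -> biochemical indices -> Hedges effect matrix -> PCA with
# oblimin rotation -> hierarchical k-means classification -> report.

#' Default screening configuration
#'
#' @param seed master seed for the simulate branch and any stochastic step.
#' @return a config list: either a `simulate` block (see
#'   [default_simulation_config()]) or `transients_csv` / `biochem_csv`
#'   paths, plus `markers`, `band_windows`, `retain_pct`, `k`,
#'   `cluster_input` ("mean_diff" or "d_corrected") and `seed`.
#' @export
default_screening_config <- function(seed = 1L) {
  list(simulate = default_simulation_config(seed),
       markers = as.list(default_markers()),
       band_windows = default_band_windows(),
       retain_pct = 80,
       k = "auto",
       cluster_input = "mean_diff",
       seed = as.integer(seed))
}

read_screening_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    cfg <- yaml::read_yaml(config)
  } else if (is.list(config)) cfg <- config
  else stop("config must be a list or a YAML file path")
  base <- default_screening_config(cfg$seed %||% 1L)
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$simulate) && is.list(cfg$simulate)) {
    sim <- default_simulation_config(base$seed)
    for (nm in names(cfg$simulate)) sim[[nm]] <- cfg$simulate[[nm]]
    if (!is.null(cfg$simulate$genotypes))
      sim$genotypes <- unlist(cfg$simulate$genotypes)
    sim$seed <- as.integer(sim$seed)
    sim$replication <- lapply(sim$replication, as.integer)
    base$simulate <- sim
  }
  base$seed <- as.integer(base$seed)
  base
}

#' Run the full screening analysis
#'
#' Executes read/simulate -> JIP parameters -> K/L band analysis ->
#' biochemical indices -> genotype x parameter Hedges effect matrix ->
#' correlation PCA of per-genotype mean differences with direct oblimin
#' rotation -> hierarchical k-means clustering of genotypes, and (when
#' `out_dir` is given) writes all TSV tables plus a JSON report.  The run
#' is a pure function of (inputs, config, seed): identical config and seed
#' reproduce identical outputs byte for byte.
#'
#' @param config a config list or YAML path, see
#'   [default_screening_config()].
#' @param out_dir optional output directory; created if missing, partial
#'   outputs removed on failure.
#' @param quiet suppress per-stage log messages.
#' @return object of class `screening_report`: jip_table, band_k, band_l,
#'   index_table, cmi_table, effects, pca, rotation, clusters, truth (when
#'   simulated), provenance.
#' @export
run_screening <- function(config = default_screening_config(), out_dir = NULL,
                          quiet = FALSE) {
  cfg <- read_screening_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("[%s] done in %.1f s", name, proc.time()[["elapsed"]] - s)
    res
  }

  truth <- NULL; cmi_raw <- NULL
  if (!is.null(cfg$simulate)) {
    ds <- stage("simulate", simulate_experiment(cfg$simulate, cfg$seed))
    ts <- ds$transients; biochem_raw <- ds$biochem
    truth <- ds$truth; cmi_raw <- ds$cmi
  } else {
    ts <- stage("read", read_transients(cfg$transients_csv,
                                        time_unit = cfg$time_unit %||% "us"))
    biochem_raw <- if (!is.null(cfg$biochem_csv))
      utils::read.csv(cfg$biochem_csv, stringsAsFactors = FALSE) else NULL
  }
  say("[input] %d transients, %s biochem rows", length(ts),
      if (is.null(biochem_raw)) "no" else nrow(biochem_raw))

  markers <- unlist(cfg$markers)
  jip <- stage("jip", jip_table(ts, markers))

  band_k <- stage("band_K", band_table(ts, "K", markers,
                                       unlist(cfg$band_windows$K)))
  band_l <- stage("band_L", band_table(ts, "L", markers,
                                       unlist(cfg$band_windows$L)))

  index_table <- NULL
  if (!is.null(biochem_raw))
    index_table <- stage("biochem",
                         biochem_table(biochem_raw, synthetic_proline_calibration()))
  cmi_table <- NULL
  if (!is.null(cmi_raw))
    cmi_table <- stage("cmi", cmi_screen_table(cmi_raw))

  eff <- stage("effects", effect_matrix(jip, jip_parameter_names()))

  # second-stage PCA: genotype x parameter matrix of stress-minus-control
  # differences, standardized per parameter
  M <- if (identical(cfg$cluster_input, "d_corrected")) eff$d_corrected else eff$mean_diff
  keep <- apply(M, 2, function(x) all(is.finite(x)) && stats::sd(x) > 0)
  pca <- stage("pca", pca_with_supplementary(M[, keep, drop = FALSE],
                                             retain_pct = cfg$retain_pct,
                                             n_retain = cfg$n_retain))
  nr <- max(pca$n_retained, 2L)
  rot <- stage("rotation",
               oblimin_rotation(pca$loadings_unrotated[, seq_len(nr), drop = FALSE]))
  clusters <- stage("cluster",
                    hierarchical_kmeans(pca$scores[, seq_len(pca$n_retained), drop = FALSE],
                                        k = cfg$k %||% "auto", seed = cfg$seed))

  report <- structure(list(
    jip_table = jip, band_k = band_k, band_l = band_l,
    index_table = index_table, cmi_table = cmi_table,
    effects = eff, pca = pca, rotation = rot, clusters = clusters,
    truth = truth,
    provenance = list(config = cfg, seed = cfg$seed,
                      package_version = as.character(utils::packageVersion("ojipscreen")))),
    class = "screening_report")
  say("[total] %.1f s", proc.time()[["elapsed"]] - t0)

  if (!is.null(out_dir)) {
    ok <- FALSE
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    on.exit(if (!ok) unlink(out_dir, recursive = TRUE))
    write_screening_report(report, out_dir)
    ok <- TRUE
  }
  report
}

#' Per-genotype cell membrane integrity from PEG-test conductivities
#'
#' Pairs each PEG-treated replicate with the control-mean leakage ratios of
#' the same genotype and runs the across-genotype one-way ANOVA with Tukey
#' letters on the per-replicate CMI values.
#'
#' @param raw data.frame with columns genotype, replicate, p_deh, p_reh,
#'   p_tot, c_deh, c_reh, c_tot.
#' @return list(table = per-genotype data.frame(genotype, cmi, se, n,
#'   letters), anova).
#' @export
cmi_screen_table <- function(raw) {
  per_rep <- lapply(split(raw, raw$genotype), function(g) {
    cset <- conductivity_set(mean(g$c_deh), mean(g$c_reh), mean(g$c_tot))
    vapply(seq_len(nrow(g)), function(i)
      cell_membrane_integrity(
        conductivity_set(g$p_deh[i], g$p_reh[i], g$p_tot[i]), cset), 0)
  })
  an <- anova_oneway_tukey(per_rep)
  tab <- data.frame(genotype = names(per_rep),
                    cmi = vapply(per_rep, mean, 0),
                    se = vapply(per_rep, function(x) stats::sd(x) / sqrt(length(x)), 0),
                    n = lengths(per_rep),
                    letters = vapply(names(per_rep), function(g) an$letters[[g]], ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$cmi), ]
  rownames(tab) <- NULL
  list(table = tab, anova = an)
}

#' Write all report tables and the JSON summary to a directory
#'
#' @param report a `screening_report` from [run_screening()].
#' @param out_dir target directory (must exist).
#' @return invisibly, the paths written.
#' @export
write_screening_report <- function(report, out_dir) {
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table(df, p)
    paths <<- c(paths, p)
  }
  wt(report$jip_table, "jip_parameters.tsv")
  wt(report$band_k$table, "band_k.tsv")
  wt(report$band_l$table, "band_l.tsv")
  if (!is.null(report$index_table)) wt(report$index_table, "biochem_indices.tsv")
  if (!is.null(report$cmi_table)) wt(report$cmi_table$table, "cmi_screen.tsv")
  wt(report$effects$table, "effects.tsv")
  ld <- data.frame(parameter = rownames(report$rotation$pattern),
                   report$rotation$pattern,
                   report$rotation$contributions_pct,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(ld) <- c("parameter",
                 paste0("pattern_", colnames(report$rotation$pattern)),
                 paste0("contrib_", colnames(report$rotation$contributions_pct)))
  wt(ld, "rotated_loadings.tsv")
  sc <- data.frame(genotype = rownames(report$pca$scores),
                   report$pca$scores[, seq_len(report$pca$n_retained), drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  wt(sc, "pca_scores.tsv")
  cl <- data.frame(genotype = names(report$clusters$labels),
                   cluster = unname(report$clusters$labels),
                   stringsAsFactors = FALSE)
  if (!is.null(report$truth))
    cl$true_archetype <- unname(report$truth[cl$genotype])
  wt(cl, "clusters.tsv")
  per_cluster_k <- tapply(
    report$band_k$table$amplitude[match(cl$genotype, report$band_k$table$genotype)],
    cl$cluster, mean)
  summary <- list(
    kmo = report$pca$kmo,
    explained_pct = report$pca$explained_pct[seq_len(report$pca$n_retained)],
    cum_explained_pct = report$pca$cum_explained_pct[report$pca$n_retained],
    n_retained = report$pca$n_retained,
    k = report$clusters$k,
    mean_silhouette = report$clusters$silhouette,
    clusters = split(cl$genotype, cl$cluster),
    mean_k_band_amplitude_per_cluster = as.list(per_cluster_k),
    seed = report$provenance$seed,
    package_version = report$provenance$package_version)
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  cat(sprintf("  %d plants, %d genotypes, %d JIP parameters\n",
              nrow(x$jip_table), length(unique(x$jip_table$genotype)),
              length(jip_parameter_names())))
  cat(sprintf("  PCA: KMO %.2f, %d components retained (%.1f%% cumulative)\n",
              x$pca$kmo, x$pca$n_retained,
              x$pca$cum_explained_pct[x$pca$n_retained]))
  cat(sprintf("  clusters: k = %d\n", x$clusters$k))
  if (!is.null(x$truth))
    cat(sprintf("  adjusted Rand index vs truth: %.3f\n",
                adjusted_rand_index(x$clusters$labels[names(x$truth)], x$truth)))
  invisible(x)
}
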
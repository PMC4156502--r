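#' Pipeline configuration
#'
#' Bundles all inputs and settings for [run_pipeline()]: paths to (or
#' in-memory matrices of) the log2-ratio transcription and expression
#' tables, fitting and selection settings, clustering settings,
#' classification thresholds, and the output directory.
#'
#' @param f,y Paths to TSV time-course tables ([read_timecourse_table()]
#'   format) or gene-by-time log2 matrices with identical dimnames.
#' @param time Time grid (min); required when `f`/`y` are matrices.
#' @param mutant Optional mutant-strain expression table (path or matrix)
#'   for regulator-dependence classification.
#' @param regulated,not_regulated Optional gene-id vectors (or file paths)
#'   of regulator-regulated / unaffected genes.
#' @param out_dir Output directory (created if missing).
#' @param n_clusters Number of clusters for the built-in clustering.
#' @param linkage Clustering linkage.
#' @param clusters Optional path to an external cluster assignment TSV
#'   (replaces the built-in clustering).
#' @param options A [fit_options()] object.
#' @param criteria A [selection_criteria()] object.
#' @param strong_cutoff,post_pol_cutoff Strategy thresholds (see
#'   [label_cluster_strategy()]).
#' @param baseline_theta Recession fraction for [returns_to_baseline()].
#' @param alpha,ratio_threshold Regulator-dependence settings.
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed is consumed only by upstream simulation).
#' @param overwrite Overwrite existing output files?
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(f, y, time = NULL, mutant = NULL,
                            regulated = NULL, not_regulated = NULL,
                            out_dir = "switchfit_out", n_clusters = 8,
                            linkage = "average", clusters = NULL,
                            options = fit_options(),
                            criteria = selection_criteria(),
                            strong_cutoff = 1.7, post_pol_cutoff = 1.2,
                            baseline_theta = 0.25, alpha = 0.05,
                            ratio_threshold = 1.5, seed = 1L,
                            overwrite = FALSE) {
  for (p in list(f, y, mutant)) {
    if (is.character(p) && !file.exists(p))
      stop("input file not found: ", p)
  }
  structure(list(f = f, y = y, time = time, mutant = mutant,
                 regulated = regulated, not_regulated = not_regulated,
                 out_dir = out_dir, n_clusters = n_clusters,
                 linkage = linkage, clusters = clusters, options = options,
                 criteria = criteria, strong_cutoff = strong_cutoff,
                 post_pol_cutoff = post_pol_cutoff,
                 baseline_theta = baseline_theta, alpha = alpha,
                 ratio_threshold = ratio_threshold, seed = seed,
                 overwrite = overwrite),
            class = "pipeline_config")
}

load_table_input <- function(x, time) {
  if (is.character(x)) {
    tt <- read_timecourse_table(x)
    list(values = tt$values, time = tt$time)
  } else if (is.matrix(x)) {
    check_time_grid(time)
    list(values = x, time = time)
  } else {
    stop("table inputs must be file paths or matrices")
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: read the paired tables, fit and select the kinetic
#' models per gene, compute profile statistics and response timing, cluster
#' the expression profiles (or import an external assignment), label
#' cluster strategies and return-to-baseline behavior, optionally classify
#' regulator dependence against a mutant time course, and write all result
#' tables plus a JSON run manifest. Identical configuration gives
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return Invisible list with all in-memory results (`fits`, `stats`,
#'   `timing`, `clusters`, `cluster_stats`, `labels`, `dependence`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- proc.time()[["elapsed"]]

  ftab <- stage("read", load_table_input(config$f, config$time))
  ytab <- stage("read", load_table_input(config$y, config$time))
  if (!identical(ftab$time, ytab$time))
    stop("[read] transcription and expression tables have different grids")
  common <- intersect(rownames(ftab$values), rownames(ytab$values))
  if (length(common) == 0L) stop("[read] no shared gene ids")
  f <- ftab$values[common, , drop = FALSE]
  y <- ytab$values[common, , drop = FALSE]
  time <- ftab$time
  say(sprintf("read: %d genes, %d time points", length(common),
              length(time)))

  fits <- stage("fit",
                fit_decay_models(f, y, time, options = config$options,
                                 criteria = config$criteria))
  say(sprintf("fit: %s", paste(sprintf("%s %d", names(table(fits$assigned)),
                                       table(fits$assigned)),
                               collapse = ", ")))

  stats <- stage("stats", profile_stats(f, y))
  complete <- !apply(is.na(f), 1L, any) & !apply(is.na(y), 1L, any)
  timing <- stage("stats",
                  transition_variance(f[complete, , drop = FALSE], time))

  clusters <- stage("cluster", {
    if (!is.null(config$clusters)) {
      load_external_clusters(config$clusters, cohort_genes = common)
    } else {
      cluster_profiles(y[complete, , drop = FALSE], config$n_clusters,
                       config$linkage)
    }
  })
  members <- cluster_members(clusters)
  say(sprintf("cluster: %d clusters over %d genes", length(members),
              length(clusters$assignment)))

  cluster_stats <- stage("classify", do.call(rbind, lapply(
    names(members),
    function(cid) median_mfc(members[[cid]], stats, cluster_id = cid))))
  strategy <- label_cluster_strategy(cluster_stats$medmfc_exp,
                                     cluster_stats$medmfc_pol,
                                     config$strong_cutoff,
                                     config$post_pol_cutoff)
  rtb <- lapply(names(members), function(cid) {
    prof <- colMeans(y[members[[cid]], , drop = FALSE])
    returns_to_baseline(prof, config$baseline_theta)
  })
  labels <- data.frame(cluster_id = cluster_stats$cluster_id,
                       n_genes = cluster_stats$n_genes,
                       medmfc_exp = cluster_stats$medmfc_exp,
                       medmfc_pol = cluster_stats$medmfc_pol,
                       strategy = strategy,
                       direction = vapply(rtb, `[[`, "", "direction"),
                       returns_to_baseline = vapply(rtb, `[[`, NA, "flag"),
                       stringsAsFactors = FALSE)

  dependence <- NULL
  if (!is.null(config$mutant) && !is.null(config$regulated) &&
      !is.null(config$not_regulated)) {
    dependence <- stage("classify", {
      mut <- load_table_input(config$mutant, config$time)
      reg <- if (is.character(config$regulated) &&
                 length(config$regulated) == 1L &&
                 file.exists(config$regulated))
        read_gene_set(config$regulated) else config$regulated
      notreg <- if (is.character(config$not_regulated) &&
                    length(config$not_regulated) == 1L &&
                    file.exists(config$not_regulated))
        read_gene_set(config$not_regulated) else config$not_regulated
      common_mut <- intersect(rownames(f), rownames(mut$values))
      mut_stats <- profile_stats(f[common_mut, , drop = FALSE],
                                 mut$values[common_mut, , drop = FALSE])
      wt_med <- setNames(cluster_stats$medmfc_exp,
                         cluster_stats$cluster_id)
      mut_med <- setNames(vapply(names(members), function(cid) {
        idx <- match(members[[cid]], mut_stats$gene_id)
        idx <- idx[!is.na(idx)]
        if (!length(idx)) return(NA_real_)
        median(mut_stats$mfc_exp[idx], na.rm = TRUE)
      }, numeric(1)), names(members))
      regulator_dependence(members, wt_med, mut_med,
                           reg, notreg, universe = common,
                           alpha = config$alpha,
                           ratio_threshold = config$ratio_threshold)
    })
    labels$dependence <- dependence$dependence[match(labels$cluster_id,
                                                     dependence$cluster_id)]
    labels$medmfc_ratio <- dependence$medmfc_ratio[match(labels$cluster_id,
                                                         dependence$cluster_id)]
  }

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ow <- config$overwrite
  paths <- list(fits = file.path(out_dir, "fits.tsv"),
                stats = file.path(out_dir, "stats.tsv"),
                timing = file.path(out_dir, "timing.tsv"),
                clusters = file.path(out_dir, "clusters.tsv"),
                cluster_stats = file.path(out_dir, "cluster_stats.tsv"),
                labels = file.path(out_dir, "labels.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  stage("write", {
    write_fit_table(fits, paths$fits, overwrite = ow)
    write_stats_table(stats, paths$stats, overwrite = ow)
    write_tsv(timing, paths$timing, overwrite = ow)
    write_tsv(data.frame(gene_id = names(clusters$assignment),
                         cluster_id = unname(clusters$assignment),
                         stringsAsFactors = FALSE),
              paths$clusters, overwrite = ow)
    write_tsv(cluster_stats, paths$cluster_stats, overwrite = ow)
    write_labels_table(labels, paths$labels, overwrite = ow)
    if (!is.null(dependence))
      write_tsv(dependence,
                file.path(out_dir, "dependence.tsv"), overwrite = ow)
    if (!is.null(clusters$hclust))
      export_dendrogram(clusters, file.path(out_dir, "dendrogram.nwk"))
  })

  manifest <- list(
    package = "switchfit",
    version = as.character(packageVersion("switchfit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_genes = length(common),
    n_complete = sum(complete),
    n_time_points = length(time),
    assignment_counts = as.list(table(fits$assigned)),
    n_exp_approach = sum(fits$exp_approach, na.rm = TRUE),
    n_clusters = length(members),
    parameters = list(
      n_clusters = config$n_clusters, linkage = config$linkage,
      strong_cutoff = config$strong_cutoff,
      post_pol_cutoff = config$post_pol_cutoff,
      baseline_theta = config$baseline_theta, alpha = config$alpha,
      ratio_threshold = config$ratio_threshold,
      max_iter = config$options$max_iter,
      k_bounds = config$options$k_bounds,
      criteria = unclass(config$criteria)),
    outputs = unname(vapply(paths, basename, character(1))))
  check_overwrite(paths$manifest, ow)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  say(sprintf("done in %.1f s; outputs in %s",
              proc.time()[["elapsed"]] - t0, out_dir))
  invisible(list(fits = fits, stats = stats, timing = timing,
                 clusters = clusters, cluster_stats = cluster_stats,
                 labels = labels, dependence = dependence,
                 manifest = manifest, paths = paths))
}
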
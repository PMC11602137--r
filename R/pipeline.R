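# Top-level pipeline driver: simulate -> strand assignment -> coverage ->
# flank matrices -> sense/antisense orientation -> stratification ->
# statistics -> figures, with a manifest recording parameters, seeds and
# content digests of every output file.

#' Run the full DSB nascent-RNA analysis on synthetic data
#'
#' Executes every stage of the pipeline on a simulated experiment and
#' writes a reproducible output tree: `annotation/` (genes, sites, sizes,
#' truth), `matrices/` (per-condition sense/antisense flank matrices),
#' `tables/` (site table, fold changes, test results, PCA coordinates,
#' exclusions), `figures/` and `manifest.json`. Identical `config` +
#' `seed` reproduce every numeric output exactly.
#'
#' @param config A [sim_config()]; the generator defines the experiment.
#' @param outdir Output directory (created; must be empty or absent).
#' @param seed Integer master seed for every source of randomness.
#' @param conditions Conditions to simulate; fold changes compare
#'   `damage_knockdown` to `damage_control` when both are present.
#' @param orientation If `FALSE`, the sense/antisense stage is skipped and
#'   stages that need it (fold changes, orientation figures) are skipped
#'   with a logged note.
#' @param figures If `FALSE`, no figures are rendered.
#' @param fc_width,fc_pseudocount Fold-change window width (bp, centred on
#'   the DSB) and pseudocount.
#' @return Invisibly, a list with the main in-memory results (site table,
#'   fold-change tables, test results, PCA, exclusions, manifest path).
#' @export
run_pipeline <- function(config = sim_config(), outdir, seed = config$seed,
                         conditions = c("no_damage", "damage_control",
                                        "damage_knockdown"),
                         orientation = TRUE, figures = TRUE,
                         fc_width = 500, fc_pseudocount = 0.01) {
  stopifnot(inherits(config, "sim_config"))
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("annotation", "matrices", "tables", "figures"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  log_lines <- character()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[dsbdart] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  note("stage annotation: generating synthetic annotation (seed %d)", seed)
  ann <- generate_annotation(config, seed)
  write_annotation(ann, file.path(outdir, "annotation"))
  sites <- ann$sites
  genes <- ann$genes
  flank <- as.integer(config$flank)

  # per-condition replicate-averaged stranded flank matrices
  note("stage coverage: %d condition(s) x %d replicate(s)",
       length(conditions), config$replicates)
  cond_mats <- list()
  pca_cols <- list()
  for (cond in conditions) {
    plus_l <- list(); minus_l <- list()
    for (rep_i in seq_len(config$replicates)) {
      sim <- simulate_chrRNA(ann, cond, replicate = rep_i, seed = seed)
      cov <- cpm_coverage(sim$reads, ann$sizes)
      plus_l[[rep_i]] <- compute_flank_matrix(cov, sites, flank, 1L, "plus")
      minus_l[[rep_i]] <- compute_flank_matrix(cov, sites, flank, 1L,
                                               "minus")
      pca_cols[[sprintf("%s_rep%d", cond, rep_i)]] <-
        window_track_sum(total_track(cov), sites, flank)
    }
    cond_mats[[cond]] <- list(plus = average_matrices(plus_l),
                              minus = average_matrices(minus_l))
  }

  # orientation
  oriented <- list()
  excluded <- character()
  if (orientation) {
    note("stage orientation: sense/antisense annotation")
    ov <- find_gene_flank_overlaps(sites, genes, flank, 1L)
    for (cond in conditions) {
      res <- build_orientation_matrices(cond_mats[[cond]]$plus,
                                        cond_mats[[cond]]$minus, ov)
      oriented[[cond]] <- res
      excluded <- res$excluded_sites
      write_flank_matrix(res$sense,
                         file.path(outdir, "matrices",
                                   sprintf("%s_sense.tsv", cond)))
      write_flank_matrix(res$antisense,
                         file.path(outdir, "matrices",
                                   sprintf("%s_antisense.tsv", cond)))
    }
    writeLines(excluded, file.path(outdir, "tables", "excluded_sites.txt"))
    note("excluded %d site(s) with no gene overlap in the flank: %s",
         length(excluded), paste(excluded, collapse = ", "))
  } else {
    note("stage orientation: disabled")
  }

  # stratification
  note("stage stratification")
  bless <- simulate_track(ann, "bless", seed = seed)
  eff <- rank_cleavage_efficiency(bless, sites,
                                  window = config$bless_window)
  cut_ids <- ann$truth$site_id[ann$truth$cut_status == "cut"]
  pathway <- NULL
  cut_sites <- sites[sites$name %in% cut_ids, , drop = FALSE]
  if (nrow(cut_sites) >= 2 * config$n_pathway && config$n_pathway > 0) {
    rad51 <- cpm_coverage(simulate_track(ann, "rad51", seed = seed),
                          ann$sizes)
    xrcc4 <- cpm_coverage(simulate_track(ann, "xrcc4", seed = seed),
                          ann$sizes)
    pathway <- classify_repair_pathway(rad51, xrcc4, cut_sites,
                                       k = config$n_pathway)
  }
  transcription <- NULL
  if (orientation && "no_damage" %in% conditions) {
    transcription <-
      classify_transcription_activity(oriented$no_damage$sense)
  }
  site_table <- dsb_site_table(
    eff, pathway, transcription,
    cut_status = stats::setNames(ann$truth$cut_status, ann$truth$site_id))
  write_table_tsv(site_table, file.path(outdir, "tables", "site_table.tsv"))

  # statistics
  note("stage statistics")
  fc_tables <- list()
  tests <- list()
  have_fc <- orientation &&
    all(c("damage_control", "damage_knockdown") %in% conditions)
  if (have_fc) {
    for (orient in c("sense", "antisense")) {
      fc <- log2_fold_change(oriented$damage_knockdown[[orient]],
                             oriented$damage_control[[orient]],
                             center_offset = 0, width = fc_width,
                             pseudocount = fc_pseudocount)
      fc$cut_status <- ann$truth$cut_status[match(fc$site_id,
                                                  ann$truth$site_id)]
      fc_tables[[orient]] <- fc
      write_table_tsv(fc, file.path(outdir, "tables",
                                    sprintf("log2fc_%s.tsv", orient)))
    }
    usable <- function(tab, status)
      tab$log2fc[!tab$zero_both & tab$cut_status == status]
    tests$sense_vs_antisense_cut <- rank_sum_test(
      usable(fc_tables$antisense, "cut"), usable(fc_tables$sense, "cut"))
    tests$cut_vs_uncut_antisense <- rank_sum_test(
      usable(fc_tables$antisense, "cut"),
      usable(fc_tables$antisense, "uncut"))
  } else if (!orientation) {
    note("fold-change stage skipped: needs the orientation stage")
  }
  pca_mat <- do.call(cbind, pca_cols)
  rownames(pca_mat) <- sites$name
  pca <- if (ncol(pca_mat) >= 2) pca_samples(pca_mat) else NULL
  if (!is.null(pca)) {
    coords <- data.frame(sample = rownames(pca$coords), pca$coords,
                         row.names = NULL)
    write_table_tsv(coords, file.path(outdir, "tables", "pca_coords.tsv"))
  }
  test_df <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(test = nm, U = t$U, p_value = t$p_value, method = t$method,
               n = t$n, m = t$m, stringsAsFactors = FALSE)
  }))
  if (!is.null(test_df))
    write_table_tsv(test_df, file.path(outdir, "tables",
                                       "rank_sum_tests.tsv"))

  # figures
  if (figures) {
    note("stage figures")
    figdir <- file.path(outdir, "figures")
    if (orientation && length(oriented)) {
      retained_cut <- setdiff(cut_ids, excluded)
      profs <- do.call(rbind, lapply(names(oriented), function(cond) {
        do.call(rbind, lapply(c("sense", "antisense"), function(o) {
          pr <- metagene_profile(oriented[[cond]][[o]], retained_cut,
                                 label = cond)
          pr$orientation <- o
          pr
        }))
      }))
      render_figures("metagene", list(profiles = profs),
                     file.path(figdir, "metagene_cut.png"))
      last <- oriented[[length(oriented)]]
      render_figures("heatmap",
                     list(matrix = last$antisense, efficiency = eff),
                     file.path(figdir, "heatmap_antisense.png"))
      render_figures("fillplot",
                     list(matrix = last$antisense,
                          site_id = last$antisense$site_ids[1]),
                     file.path(figdir, "fillplot.png"))
    }
    if (have_fc)
      render_figures("boxplot", list(fc_tables = lapply(fc_tables,
        function(t) t[t$cut_status == "cut", , drop = FALSE])),
        file.path(figdir, "log2fc_boxplot.png"))
    if (!is.null(pca)) {
      groups <- sub("_rep[0-9]+$", "", rownames(pca$coords))
      render_figures("pca_scatter",
                     list(pca = pca, sample_groups = groups),
                     file.path(figdir, "pca_samples.png"))
    }
  }

  # manifest
  writeLines(log_lines, file.path(outdir, "tables", "pipeline_log.txt"))
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  rel <- substring(files, nchar(outdir) + 2L)
  digest <- unname(tools::md5sum(files))
  manifest <- list(
    package = "dsbdart",
    package_version = as.character(utils::packageVersion("dsbdart")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    conditions = conditions,
    parameters = unclass(config),
    fc_window = c(center_offset = 0, width = fc_width,
                  pseudocount = fc_pseudocount),
    excluded_sites = as.list(excluded),
    files = stats::setNames(as.list(digest), rel))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(annotation = ann, site_table = site_table,
                 fc_tables = fc_tables, tests = tests, pca = pca,
                 excluded_sites = excluded,
                 manifest = file.path(outdir, "manifest.json")))
}

# full-precision TSV writer used for all numeric tables
write_table_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
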
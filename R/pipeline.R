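#' Run the full chronosequence analysis and write a report directory
#'
#' Executes every stage of the workflow on one inventory — diversity
#' (pooled and per plot), vertical structure, importance tables and stand
#' volume, Bray-Curtis/UPGMA similarity with cophenetic correlation and
#' bootstrap branch support, and the assumption-gated site comparisons —
#' and writes CSV, Newick and (when `jsonlite` is available) a JSON
#' summary under `output_dir`. CSVs carry full precision; rounding is left
#' to presentation.
#'
#' @param chrono a [chronosequence()]
#' @param output_dir directory to create/fill
#' @param n_boot bootstrap replicates for branch support
#' @param seed seed for the bootstrap
#' @param alpha routing level for [compare_metric()]
#' @param mc morphic coefficient for volumes
#' @param metrics per-plot metrics to compare across sites
#' @return invisibly, a list with every computed block
#' @export
run_analysis <- function(chrono, output_dir, n_boot = 999, seed = 1,
                         alpha = 0.05, mc = 0.5,
                         metrics = c("richness", "effective_species",
                                     "a_index", "abundance", "dominance",
                                     "volume")) {
  stopifnot(inherits(chrono, "chronosequence"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out_csv <- function(df, name) {
    utils::write.table(df, file.path(output_dir, name), sep = ",",
                       row.names = FALSE, quote = TRUE)
  }

  div_pooled <- site_diversity(chrono, "pooled")
  div_plot <- site_diversity(chrono, "plot")
  vert <- site_a_summary(chrono)
  imp <- importance_tables(chrono)
  vol <- site_volume(chrono, mc = mc)

  abund <- pooled_abundance(chrono)
  sim <- similarity_matrix(abund)
  d <- similarity_to_dist(sim)
  tree <- upgma(d)
  coph <- cophenetic_correlation(tree, d)
  support <- branch_support(abund, n_reps = n_boot, seed = seed)

  comparisons <- lapply(metrics, function(m) {
    compare_metric(chrono, m, alpha = alpha, mc = mc)
  })
  names(comparisons) <- metrics

  out_csv(div_pooled, "diversity_pooled.csv")
  out_csv(div_plot, "diversity_plot.csv")
  out_csv(vert, "vertical_site.csv")
  out_csv(attr(vert, "per_plot"), "vertical_plot.csv")
  out_csv(vol, "volume_site.csv")
  for (s in names(imp)) {
    out_csv(imp[[s]],
            paste0("importance_", gsub("[^A-Za-z0-9]+", "", s), ".csv"))
  }
  out_csv(as.data.frame(unclass(sim)), "similarity.csv")
  write_newick(support, file.path(output_dir, "dendrogram.nwk"))
  omnibus <- do.call(rbind, c(lapply(comparisons, function(cmp) {
    data.frame(metric = cmp$metric, route = cmp$route,
               levene_p = cmp$homoscedasticity$p_value,
               shapiro_w = cmp$normality$statistic,
               f_statistic = cmp$omnibus$statistic,
               df1 = cmp$omnibus$df1, df2 = cmp$omnibus$df2,
               p_value = cmp$omnibus$p_value)
  }), list(make.row.names = FALSE)))
  if (is.null(omnibus)) {
    omnibus <- data.frame(metric = character(0), route = character(0),
                          levene_p = numeric(0), shapiro_w = numeric(0),
                          f_statistic = numeric(0), df1 = numeric(0),
                          df2 = numeric(0), p_value = numeric(0))
  }
  out_csv(omnibus, "comparison_omnibus.csv")
  posthoc <- do.call(rbind, c(lapply(comparisons, function(cmp) {
    cbind(metric = cmp$metric, cmp$posthoc[c("group1", "group2", "diff",
                                             "p_adj")])
  }), list(make.row.names = FALSE)))
  if (is.null(posthoc)) {
    posthoc <- data.frame(metric = character(0), group1 = character(0),
                          group2 = character(0), diff = numeric(0),
                          p_adj = numeric(0))
  }
  out_csv(posthoc, "comparison_posthoc.csv")

  report <- list(
    diversity_pooled = div_pooled, diversity_plot = div_plot,
    vertical = vert, importance = imp, volume = vol,
    similarity = sim, tree = tree, cophenetic_correlation = coph,
    branch_support = support, comparisons = comparisons,
    provenance = list(seed = seed, n_boot = n_boot, alpha = alpha,
                      mc = mc, n_records = nrow(chrono$records))
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    json <- list(
      diversity_pooled = div_pooled,
      vertical = vert, volume = vol,
      similarity = as.data.frame(unclass(sim)),
      cophenetic_correlation = coph,
      newick = write_newick(support),
      omnibus = omnibus,
      provenance = report$provenance
    )
    jsonlite::write_json(json, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
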
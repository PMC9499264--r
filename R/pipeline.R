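#' Run the full treatment-evaluation pipeline
#'
#' Orchestrates every stage end to end: trait summaries and group tests,
#' alpha diversity and phylum abundance for both communities, qPCR fold
#' changes and upregulated-gene counts, the integrated evaluation matrix
#' with totals and means, and a PCA of the treatment x trait means. Inputs
#' are either file paths (TSVs in the package's formats) or, when omitted,
#' tables simulated from `config`. Stages whose inputs are missing are
#' skipped and enter the evaluation matrix as not-tested (`NA`) columns,
#' excluded from the affected treatments' totals and mean denominators.
#'
#' All outputs are written to `outdir` as TSVs plus a `run_log.txt`
#' recording the seed and every resolved analysis flag.
#'
#' @param outdir Output directory (created if missing).
#' @param config A `sim_config`; used to simulate any table not supplied
#'   as a file, and for the housekeeping/calibrator defaults.
#' @param traits,otu_bacteria,otu_fungi,ct Optional paths to input TSVs.
#'   Pass `NA` (not `NULL`) to skip a stage entirely instead of simulating
#'   it.
#' @param calibrator Calibrator treatment for fold changes (default
#'   `"Control"`).
#' @param alpha,adjust Group-test settings.
#' @param rank_digits Decimal places applied to parameter values before
#'   ranking (default 1, the printed precision of the packaged tables);
#'   `NULL` ranks full-precision values.
#' @return Invisible list with every intermediate result (`summaries`,
#'   `group_tests`, `diversity`, `abundance`, `fold_changes`, `up_counts`,
#'   `scores`, `ranking`, `pca`).
#' @export
run_all <- function(outdir, config = sim_config(), traits = NULL,
                    otu_bacteria = NULL, otu_fungi = NULL, ct = NULL,
                    calibrator = "Control", alpha = 0.05, adjust = "none",
                    rank_digits = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  load_or_sim <- function(path, reader, simulator) {
    if (is.null(path)) return(simulator())
    if (length(path) == 1L && is.na(path)) return(NULL)
    reader(path)
  }

  tt <- stage("traits", load_or_sim(traits, read_trait_table,
                                    function() simulate_traits(config)))
  otus <- list(
    bacteria = stage("otu_bacteria",
                     load_or_sim(otu_bacteria, read_otu_table,
                                 function() simulate_otu_table(config, "bacteria"))),
    fungi = stage("otu_fungi",
                  load_or_sim(otu_fungi, read_otu_table,
                              function() simulate_otu_table(config, "fungi"))))
  ct_tab <- stage("ct", load_or_sim(ct, function(p) read_ct_table(p, hk = config$hk),
                                    function() censor_ct(simulate_ct_table(config))))

  treatments <- unique(tt$treatment)
  res <- list()

  res$summaries <- stage("physiology", summarize_traits(tt))
  can_test <- all(tapply(tt$value, interaction(tt$treatment, tt$trait, drop = TRUE),
                         length) >= 2L)
  if (can_test) {
    res$group_tests <- stage("physiology", trait_report(tt, alpha = alpha, adjust = adjust))
    utils::write.table(res$group_tests, file.path(outdir, "trait_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    res$group_tests <- NULL
  }
  utils::write.table(res$summaries, file.path(outdir, "trait_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  res$diversity <- list(); res$abundance <- list()
  for (comm in names(otus)) {
    if (is.null(otus[[comm]])) next
    res$diversity[[comm]] <- stage("diversity", alpha_diversity(otus[[comm]]))
    res$abundance[[comm]] <- stage("diversity",
                                   relative_abundance(otus[[comm]], "phylum"))
    utils::write.table(res$diversity[[comm]],
                       file.path(outdir, paste0("diversity_", comm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$abundance[[comm]],
                       file.path(outdir, paste0("abundance_phylum_", comm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(ct_tab)) {
    res$fold_changes <- stage("expression",
                              fold_changes(ct_tab, hk = config$hk,
                                           calibrator = calibrator))
    res$up_counts <- stage("expression", count_upregulated(res$fold_changes))
    utils::write.table(res$fold_changes, file.path(outdir, "fold_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$up_counts, file.path(outdir, "up_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # parameter matrix: 9 trait means + 2 Shannon columns + 2 up-gene counts
  vals <- matrix(NA_real_, length(treatments), length(evaluation_parameters()),
                 dimnames = list(treatments, evaluation_parameters()))
  for (i in seq_len(nrow(res$summaries))) {
    vals[res$summaries$treatment[i], res$summaries$trait[i]] <- res$summaries$mean[i]
  }
  for (comm in names(res$diversity)) {
    sh <- treatment_shannon(otus[[comm]])
    col <- paste0("shannon_", comm)
    vals[intersect(names(sh), treatments), col] <-
      sh[intersect(names(sh), treatments)]
  }
  if (!is.null(ct_tab)) {
    for (tp in unique(res$up_counts$timepoint)) {
      col <- paste0("up_genes_", tolower(sub("DAS$", "das", tp)))
      if (!col %in% colnames(vals)) next
      u <- res$up_counts[res$up_counts$timepoint == tp, ]
      vals[intersect(u$treatment, treatments), col] <-
        u$n_up[match(intersect(u$treatment, treatments), u$treatment)]
    }
  }
  keep <- colSums(!is.na(vals)) >= 2L
  res$scores <- stage("evalmatrix",
                      build_score_matrix(vals[, keep, drop = FALSE],
                                         digits = rank_digits))
  res$ranking <- stage("evalmatrix",
                       write_score_matrix(res$scores,
                                          file.path(outdir, "score_matrix.tsv")))
  utils::write.table(res$ranking, file.path(outdir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  trait_means <- matrix(NA_real_, length(treatments), length(trait_levels()),
                        dimnames = list(treatments, trait_levels()))
  for (i in seq_len(nrow(res$summaries))) {
    trait_means[res$summaries$treatment[i], res$summaries$trait[i]] <-
      res$summaries$mean[i]
  }
  nz <- apply(trait_means, 2L, function(v) stats::sd(v) > 0)
  res$pca <- stage("pca", pca(trait_means[, nz, drop = FALSE], standardize = TRUE))
  write_pca(res$pca, outdir, prefix = "pca_traits")

  log_lines <- c(
    paste0("rhizorank ", as.character(utils::packageVersion("rhizorank"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("seed: ", config$seed),
    paste0("crop: ", config$crop),
    paste0("tie_rule: max-of-tied-positions"),
    paste0("rank_digits: ", if (is.null(rank_digits)) "full-precision" else rank_digits),
    paste0("mean_rounding: half-up, 1 decimal"),
    paste0("shannon_log: natural"),
    paste0("chao1: bias-corrected"),
    paste0("fc_averaging: geometric (ddCt scale)"),
    paste0("fc_thresholds: up >= 2, down <= 0.5 (inclusive)"),
    paste0("ct_ceiling: > 36 undetermined"),
    paste0("group_test: Kruskal-Wallis + Dunn, alpha = ", alpha,
           ", adjust = ", adjust),
    paste0("pca: correlation-matrix (standardized)"))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(res)
}
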
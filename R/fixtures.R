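#' Packaged per-treatment trait summaries for the two greenhouse trials
#'
#' Printed treatment means and standard deviations for the nine growth
#' traits of the wheat (12 treatments) and maize (8 treatments) trials.
#' These summaries ship with the package; the replicate-level measurements
#' behind them were not published, so [packaged_trait_table()] exposes the
#' means as single pseudo-replicates and [sim_config()] uses the mean/SD
#' pairs to parameterize the trait simulator.
#'
#' @param crop `"wheat"` or `"maize"`.
#' @return Data frame with columns `treatment`, `trait`, `mean`, `sd`;
#'   treatments in table order.
#' @export
packaged_trait_summary <- function(crop = c("wheat", "maize")) {
  crop <- match.arg(crop)
  path <- system.file("extdata", paste0(crop, "_trait_summary.tsv"),
                      package = "rhizorank", mustWork = TRUE)
  wide <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  traits <- trait_levels()
  long <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(treatment = wide$treatment, trait = tr,
               mean = wide[[tr]], sd = wide[[paste0("sd_", tr)]],
               stringsAsFactors = FALSE)
  }))
  long$treatment <- factor(long$treatment, levels = treatment_labels(crop))
  long <- long[order(long$treatment), ]
  long$treatment <- as.character(long$treatment)
  rownames(long) <- NULL
  long
}

#' Packaged trait means as a pseudo-replicate trait table
#'
#' @param crop `"wheat"` or `"maize"`.
#' @return A `trait_table` with one replicate per treatment carrying the
#'   printed means.
#' @export
packaged_trait_table <- function(crop = c("wheat", "maize")) {
  s <- packaged_trait_summary(crop)
  trait_table(data.frame(treatment = s$treatment, replicate = 1L,
                         trait = s$trait, value = s$mean,
                         stringsAsFactors = FALSE))
}

#' Packaged reference evaluation-matrix scores
#'
#' The published per-parameter scores, totals and means of the integrated
#' evaluation matrix for both trials: nine physiological columns, two
#' Shannon-index columns (bacteria, fungi), two upregulated-gene-count
#' columns (21 and 60 days after sowing), `total` and `mean`. `NA` marks
#' parameters not tested for a treatment.
#'
#' @param crop `"wheat"` or `"maize"`.
#' @return Data frame, one row per treatment.
#' @export
packaged_reference_scores <- function(crop = c("wheat", "maize")) {
  crop <- match.arg(crop)
  path <- system.file("extdata", paste0(crop, "_reference_scores.tsv"),
                      package = "rhizorank", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Parameter names of the packaged evaluation matrix
#' @return Character vector: nine trait columns followed by the two
#'   metagenomic and two gene-expression columns.
#' @export
evaluation_parameters <- function() {
  c(trait_levels(),
    "shannon_bacteria", "shannon_fungi", "up_genes_21das", "up_genes_60das")
}
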
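#' Collapse technical replicates to per-biological-replicate Ct means
#'
#' Arithmetic mean of the determined technical Ct values for every
#' (gene, treatment, timepoint, biological replicate) cell. Cells whose
#' technical replicates are all undetermined stay undetermined; cells with
#' a subset determined are flagged `partial`.
#'
#' @param x A `ct_table` (undetermined Ct as `NA`).
#' @return Data frame: `gene`, `treatment`, `timepoint`, `bio_rep`, `ct`
#'   (mean; `NA` if undetermined), `n_tech`, `n_determined`, `partial`.
#' @export
collapse_tech_reps <- function(x) {
  key <- interaction(x$gene, x$treatment, x$timepoint, x$bio_rep,
                     drop = TRUE, sep = "\r")
  mu <- tapply(x$ct, key, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  n_tech <- tapply(x$ct, key, length)
  n_det <- tapply(x$ct, key, function(v) sum(!is.na(v)))
  parts <- strsplit(names(mu), "\r", fixed = TRUE)
  out <- data.frame(gene = vapply(parts, `[[`, "", 1L),
                    treatment = vapply(parts, `[[`, "", 2L),
                    timepoint = vapply(parts, `[[`, "", 3L),
                    bio_rep = as.integer(vapply(parts, `[[`, "", 4L)),
                    ct = as.numeric(mu),
                    n_tech = as.integer(n_tech),
                    n_determined = as.integer(n_det),
                    stringsAsFactors = FALSE)
  out$partial <- out$n_determined > 0L & out$n_determined < out$n_tech
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' For every target gene, treatment and timepoint: technical replicates are
#' collapsed, `dCt = Ct_target - Ct_housekeeping` is formed per biological
#' replicate, `ddCt = dCt - dCt_calibrator` is referenced to the mean
#' calibrator `dCt` of the same gene and timepoint, and the fold change is
#' `2^-ddCt`. Biological replicates are averaged on the `ddCt` (log) scale
#' by default, i.e. the reported fold change is a geometric mean — the
#' natural choice for a multiplicative quantity, and it makes the
#' calibrator's own fold change exactly 1; `average = "arithmetic"`
#' averages the per-replicate `2^-ddCt` instead.
#'
#' A gene is classified `up` when `fc >= 2`, `down` when `fc <= 0.5` (both
#' thresholds inclusive), `unchanged` in between, and `undetermined` when
#' any required Ct (target, housekeeping, or calibrator) is undetermined.
#'
#' @param x A `ct_table`.
#' @param hk Housekeeping gene name (default `"18S"`).
#' @param calibrator Calibrator treatment (default `"Control"`).
#' @param average `"geometric"` (default) or `"arithmetic"` fold-change
#'   averaging across biological replicates.
#' @param up_threshold,down_threshold Inclusive classification thresholds
#'   (defaults 2 and 0.5).
#' @return A `fold_change_table` data frame: `gene`, `treatment`,
#'   `timepoint`, `n_bio`, `mean_dct`, `ddct`, `fc`, `status`.
#' @export
fold_changes <- function(x, hk = "18S", calibrator = "Control",
                         average = c("geometric", "arithmetic"),
                         up_threshold = 2, down_threshold = 0.5) {
  average <- match.arg(average)
  if (!hk %in% x$gene) stop("housekeeping gene '", hk, "' absent from Ct table")
  if (!calibrator %in% x$treatment) {
    stop("calibrator treatment '", calibrator, "' absent from Ct table")
  }
  cc <- collapse_tech_reps(x)
  hk_ct <- cc[cc$gene == hk, c("treatment", "timepoint", "bio_rep", "ct")]
  names(hk_ct)[4L] <- "hk_ct"
  tg <- cc[cc$gene != hk, ]
  m <- merge(tg, hk_ct, by = c("treatment", "timepoint", "bio_rep"),
             all.x = TRUE)
  m$dct <- m$ct - m$hk_ct
  cal <- m[m$treatment == calibrator, ]
  cal_key <- interaction(cal$gene, cal$timepoint, drop = TRUE, sep = "\r")
  cal_dct <- tapply(cal$dct, cal_key, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  m$cal_dct <- as.numeric(cal_dct[paste(m$gene, m$timepoint, sep = "\r")])
  m$ddct_rep <- m$dct - m$cal_dct
  key <- interaction(m$gene, m$treatment, m$timepoint, drop = TRUE, sep = "\r")
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  mean_dct <- tapply(m$dct, key, mean_or_na)
  n_bio <- tapply(m$ddct_rep, key, function(v) sum(!is.na(v)))
  if (average == "geometric") {
    ddct <- tapply(m$ddct_rep, key, mean_or_na)
    fc <- 2^(-as.numeric(ddct))
  } else {
    fc <- as.numeric(tapply(2^(-m$ddct_rep), key, mean_or_na))
    ddct <- -log2(fc)
  }
  parts <- strsplit(names(mean_dct), "\r", fixed = TRUE)
  out <- data.frame(gene = vapply(parts, `[[`, "", 1L),
                    treatment = vapply(parts, `[[`, "", 2L),
                    timepoint = vapply(parts, `[[`, "", 3L),
                    n_bio = as.integer(n_bio),
                    mean_dct = as.numeric(mean_dct),
                    ddct = as.numeric(ddct),
                    fc = as.numeric(fc),
                    stringsAsFactors = FALSE)
  out$status <- ifelse(is.na(out$fc), "undetermined",
                ifelse(out$fc >= up_threshold, "up",
                ifelse(out$fc <= down_threshold, "down", "unchanged")))
  out <- out[order(out$treatment, out$timepoint, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Count upregulated genes per treatment and timepoint
#'
#' Number of panel genes classified `up` (fold change at or above the
#' inclusive threshold) for each condition; undetermined genes are excluded
#' from the count but reported.
#'
#' @param x A `fold_change_table` from [fold_changes()].
#' @return Data frame: `treatment`, `timepoint`, `n_up`, `n_down`,
#'   `n_determined`, `n_undetermined`.
#' @export
count_upregulated <- function(x) {
  key <- interaction(x$treatment, x$timepoint, drop = TRUE, sep = "\r")
  cnt <- function(f) as.integer(tapply(seq_len(nrow(x)), key,
                                       function(i) sum(f(x$status[i]))))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(treatment = vapply(parts, `[[`, "", 1L),
                    timepoint = vapply(parts, `[[`, "", 2L),
                    n_up = cnt(function(s) s == "up"),
                    n_down = cnt(function(s) s == "down"),
                    n_determined = cnt(function(s) s != "undetermined"),
                    n_undetermined = cnt(function(s) s == "undetermined"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene x condition expression matrices for heatmap export
#'
#' Returns the per-gene `dCt` and `log2` fold-change matrices side by side,
#' conditions (treatment at timepoint) in columns.
#'
#' @param x A `fold_change_table`.
#' @return List of two matrices, `dct` and `log2_fc`, genes in rows.
#' @export
expression_matrices <- function(x) {
  cond <- paste(x$treatment, x$timepoint, sep = "@")
  genes <- sort(unique(x$gene))
  conds <- unique(cond)
  build <- function(v) {
    m <- matrix(NA_real_, length(genes), length(conds),
                dimnames = list(genes, conds))
    m[cbind(match(x$gene, genes), match(cond, conds))] <- v
    m
  }
  list(dct = build(x$mean_dct), log2_fc = build(log2(x$fc)))
}
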
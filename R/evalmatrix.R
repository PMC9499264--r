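#' Rank parameter values into treatment scores (maximum-tie rule)
#'
#' Scores a vector of per-treatment parameter values by ascending rank: the
#' smallest value scores 1 and the largest scores `n_conditions`. Tied
#' values all receive the *maximum* of their tied sort positions, so e.g.
#' eight equal smallest values out of twelve all score 8. This tie rule is
#' what makes score columns reproduce the published evaluation matrices;
#' average- or minimum-rank conventions do not.
#'
#' @param values Numeric vector of parameter values, one per ranked
#'   treatment; no missing values (handle unavailable parameters at the
#'   matrix level, see [build_score_matrix()]).
#' @param n_conditions Expected number of conditions; must equal
#'   `length(values)`. Defaults to the vector length.
#' @param direction `"higher"` (default) if larger values are better,
#'   `"lower"` to invert.
#' @return Integer vector of scores in `[1, n_conditions]`.
#' @examples
#' rank_scores(c(1, 2, 3))            # 1 2 3
#' rank_scores(c(5, 5, 2, 9))         # 3 3 1 4: ties take the max position
#' @export
rank_scores <- function(values, n_conditions = length(values),
                        direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (!is.numeric(values)) stop("values must be numeric")
  if (length(values) != n_conditions) {
    stop("length(values) = ", length(values), " but n_conditions = ", n_conditions)
  }
  if (n_conditions < 2L) stop("need at least 2 conditions to rank")
  if (anyNA(values)) stop("values must not contain NA; mask unavailable parameters upstream")
  v <- if (direction == "lower") -values else values
  as.integer(rank(v, ties.method = "max"))
}

#' Assemble a treatment x parameter score matrix
#'
#' Builds the integrated evaluation matrix: every column of `values` is
#' ranked across treatments with [rank_scores()] (maximum-tie rule, higher
#' is better). `NA` entries mark parameters not tested for a treatment;
#' such treatments are excluded from that column's ranking, and the maximum
#' attainable score of the column is the number of treatments actually
#' ranked on it. Columns listed in `prescored` are taken as already-ranked
#' integer scores and only validated — used when a data layer is available
#' only as published scores.
#'
#' @param values Numeric matrix or data frame, treatments in rows (row
#'   names required), parameters in columns.
#' @param prescored Character vector of column names that already contain
#'   scores rather than raw values.
#' @param digits Optional number of decimal places to round raw values to
#'   before ranking, to reproduce rankings computed from printed tables;
#'   `NULL` (default) ranks values as supplied.
#' @param direction Passed to [rank_scores()] for non-prescored columns.
#' @return A `score_matrix`: integer matrix with `NA` for untested cells
#'   and attribute `n_ranked` (per-column count of ranked treatments).
#' @export
build_score_matrix <- function(values, prescored = character(0), digits = NULL,
                               direction = "higher") {
  if (is.data.frame(values)) {
    rn <- if (!is.null(values$treatment)) values$treatment else rownames(values)
    values <- as.matrix(values[, setdiff(names(values), "treatment"), drop = FALSE])
    rownames(values) <- rn
  }
  if (is.null(rownames(values))) stop("values needs treatment row names")
  if (is.null(colnames(values))) stop("values needs parameter column names")
  bad <- setdiff(prescored, colnames(values))
  if (length(bad) > 0L) stop("prescored column(s) not in values: ", paste(bad, collapse = ", "))
  scores <- matrix(NA_integer_, nrow(values), ncol(values),
                   dimnames = dimnames(values))
  n_ranked <- integer(ncol(values))
  names(n_ranked) <- colnames(values)
  for (j in seq_len(ncol(values))) {
    avail <- !is.na(values[, j])
    n_ranked[j] <- sum(avail)
    if (n_ranked[j] < 2L) {
      stop("parameter '", colnames(values)[j], "' has ", n_ranked[j],
           " available treatment(s); need at least 2")
    }
    v <- values[avail, j]
    if (colnames(values)[j] %in% prescored) {
      s <- as.integer(v)
      if (any(s != v) || any(s < 1L) || any(s > n_ranked[j])) {
        stop("prescored column '", colnames(values)[j],
             "' must hold integer scores in [1, ", n_ranked[j], "]")
      }
      scores[avail, j] <- s
    } else {
      if (!is.null(digits)) v <- round(v, digits)
      scores[avail, j] <- rank_scores(v, direction = direction)
    }
  }
  structure(scores, n_ranked = n_ranked, class = c("score_matrix", class(scores)))
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (the convention of the published
#' totals: 79/9 prints as 8.8, 61/13 as 4.7), unlike R's banker's rounding.
#'
#' @param x Numeric vector (non-negative use case).
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Sum and average a score matrix into a treatment ranking
#'
#' Totals each treatment's available scores and divides by the number of
#' parameters it was actually ranked on, so treatments tested on fewer
#' parameters remain comparable. Means are rounded half-up to one decimal,
#' matching the published tables; the treatment(s) with the highest and
#' lowest mean are flagged.
#'
#' @param scores A `score_matrix` from [build_score_matrix()], or any
#'   integer matrix with `NA` for untested cells.
#' @return A `ranking` data frame: `treatment`, `total`, `n_params`,
#'   `mean`, `is_best`, `is_worst`.
#' @export
totals_and_means <- function(scores) {
  m <- unclass(scores)
  total <- rowSums(m, na.rm = TRUE)
  n_params <- rowSums(!is.na(m))
  if (any(n_params == 0L)) {
    stop("treatment(s) with no available parameter: ",
         paste(rownames(m)[n_params == 0L], collapse = ", "))
  }
  mn <- round_half_up(total / n_params, 1L)
  out <- data.frame(treatment = rownames(m),
                    total = as.integer(total),
                    n_params = as.integer(n_params),
                    mean = mn,
                    is_best = mn == max(mn),
                    is_worst = mn == min(mn),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ranking", "data.frame")
  out
}

#' @export
print.score_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "n_ranked") <- NULL
  disp <- ifelse(is.na(m), "n.t.", format(m))
  cat("score_matrix: ", nrow(m), " treatments x ", ncol(m), " parameters",
      " (max score per column = number of ranked treatments)\n", sep = "")
  print(as.data.frame(disp), ...)
  invisible(x)
}

#' Write a score matrix with totals as TSV
#'
#' Emits the evaluation-matrix layout: one row per treatment, per-parameter
#' score columns with the literal `n.t.` for untested cells, then `total`,
#' `n_params`, `mean` and the best/worst flags.
#'
#' @param scores A `score_matrix`.
#' @param path Output path.
#' @return The ranking data frame, invisibly.
#' @export
write_score_matrix <- function(scores, path) {
  rk <- totals_and_means(scores)
  m <- unclass(scores)
  attr(m, "n_ranked") <- NULL
  df <- as.data.frame(m)
  for (j in seq_along(df)) df[[j]] <- ifelse(is.na(df[[j]]), "n.t.", df[[j]])
  df <- cbind(treatment = rownames(m), df, rk[, c("total", "n_params", "mean", "is_best", "is_worst")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rk)
}

#' Reproduce and check a packaged evaluation matrix
#'
#' Re-ranks the packaged printed trait means for a crop (at printed
#' precision), attaches the published metagenomic and gene-expression score
#' columns as prescored inputs, and compares every physiological score cell
#' against the published matrix.
#'
#' @param crop `"wheat"` or `"maize"`.
#' @return List with elements `scores` (the recomputed `score_matrix`),
#'   `ranking` (recomputed totals/means), `reference` (published scores),
#'   `cells_compared`, `cells_matched` (physiological cells), and
#'   `mismatches` (data frame of deviating cells: treatment, parameter,
#'   computed, published).
#' @export
evaluate_packaged_study <- function(crop = c("wheat", "maize")) {
  crop <- match.arg(crop)
  s <- packaged_trait_summary(crop)
  treatments <- treatment_labels(crop)
  vals <- matrix(NA_real_, length(treatments), length(trait_levels()),
                 dimnames = list(treatments, trait_levels()))
  for (i in seq_len(nrow(s))) vals[s$treatment[i], s$trait[i]] <- s$mean[i]
  ref <- packaged_reference_scores(crop)
  stopifnot(setequal(ref$treatment, treatments))
  ref <- ref[match(treatments, ref$treatment), ]
  rownames(ref) <- NULL
  extra <- c("shannon_bacteria", "shannon_fungi", "up_genes_21das", "up_genes_60das")
  for (p in extra) vals <- cbind(vals, matrix(ref[[p]], dimnames = list(NULL, p)))
  sm <- build_score_matrix(vals, prescored = extra)
  phys <- trait_levels()
  comp <- unclass(sm)[, phys]
  pub <- as.matrix(ref[, phys]); rownames(pub) <- ref$treatment
  diff_idx <- which(comp != pub, arr.ind = TRUE)
  mism <- data.frame(treatment = rownames(comp)[diff_idx[, 1L]],
                     parameter = colnames(comp)[diff_idx[, 2L]],
                     computed = comp[diff_idx],
                     published = pub[diff_idx],
                     stringsAsFactors = FALSE)
  list(scores = sm,
       ranking = totals_and_means(sm),
       reference = ref,
       cells_compared = length(comp),
       cells_matched = length(comp) - nrow(mism),
       mismatches = mism)
}
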
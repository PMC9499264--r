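#' Dry-biomass percentage
#'
#' Percentage of oven-dry weight relative to fresh weight of the same
#' organ. Scale invariant: multiplying both weights by the same positive
#' factor leaves the percentage unchanged.
#'
#' @param dw Dry weight (g), `0 <= dw <= fw`.
#' @param fw Fresh weight (g), strictly positive.
#' @return `100 * dw / fw`, vectorized.
#' @export
dry_biomass_pct <- function(dw, fw) {
  if (any(fw <= 0, na.rm = TRUE)) stop("fresh weight must be > 0: dry-biomass percentage undefined")
  if (any(dw < 0, na.rm = TRUE)) stop("dry weight must be >= 0")
  if (any(dw > fw, na.rm = TRUE)) stop("dry weight exceeds fresh weight")
  100 * dw / fw
}

#' Per-treatment trait summaries
#'
#' Mean, sample standard deviation (n-1 denominator; 0 when n = 1) and
#' replicate count for every treatment x trait combination.
#'
#' @param x A `trait_table`.
#' @return A `trait_summary` data frame: `treatment`, `trait`, `mean`,
#'   `sd`, `n`.
#' @export
summarize_traits <- function(x) {
  stopifnot(inherits(x, "trait_table") || all(c("treatment", "trait", "value") %in% names(x)))
  key <- interaction(x$treatment, x$trait, drop = TRUE, sep = "\r")
  agg <- function(f) tapply(x$value, key, f)
  mu <- agg(mean)
  n <- agg(length)
  sdv <- agg(function(v) if (length(v) > 1L) stats::sd(v) else 0)
  parts <- strsplit(names(mu), "\r", fixed = TRUE)
  out <- data.frame(treatment = vapply(parts, `[[`, "", 1L),
                    trait = vapply(parts, `[[`, "", 2L),
                    mean = as.numeric(mu), sd = as.numeric(sdv),
                    n = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(match(out$trait, trait_levels()), out$treatment), ]
  rownames(out) <- NULL
  class(out) <- c("trait_summary", "data.frame")
  out
}

#' Dunn's post hoc test on ranks
#'
#' All-pairs z-tests on the joint midranks following a Kruskal-Wallis
#' omnibus, with the standard tie correction in the pooled variance.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length.
#' @param adjust P-value adjustment across pairs: `"none"` (default),
#'   `"holm"` or `"bonferroni"`.
#' @return Data frame with columns `group1`, `group2`, `z`, `p`.
#' @export
dunn_test <- function(values, groups, adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  lv <- levels(groups)
  pairs <- utils::combn(seq_along(lv), 2L)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(v0 * (1 / n[i] + 1 / n[j]))
    z[k] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
  }
  p <- 2 * stats::pnorm(-abs(z))
  p[is.na(p)] <- 1  # degenerate: all observations identical
  p <- stats::p.adjust(p, method = if (adjust == "none") "none" else adjust)
  data.frame(group1 = lv[pairs[1L, ]], group2 = lv[pairs[2L, ]],
             z = z, p = pmin(p, 1), stringsAsFactors = FALSE)
}

#' Compact letter display by insert-and-absorb
#'
#' Builds the familiar letter codes from a set of pairwise separations:
#' two groups share at least one letter exactly when they are *not*
#' significantly different.
#'
#' @param groups Character vector of group names.
#' @param sig_pairs Two-column matrix/data frame of group-name pairs that
#'   are significantly different.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(groups, sig_pairs) {
  sets <- list(groups)
  if (length(sig_pairs) > 0L && NROW(sig_pairs) > 0L) {
    sig_pairs <- as.matrix(sig_pairs)
    for (k in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[k, 1L]; b <- sig_pairs[k, 2L]
      hit <- which(vapply(sets, function(s) a %in% s && b %in% s, logical(1L)))
      for (h in hit) {
        s <- sets[[h]]
        sets[[h]] <- setdiff(s, a)
        sets[[length(sets) + 1L]] <- setdiff(s, b)
      }
      # absorb sets wholly contained in another
      keep <- rep(TRUE, length(sets))
      for (i in seq_along(sets)) {
        for (j in seq_along(sets)) {
          if (i != j && keep[i] && keep[j] &&
              all(sets[[i]] %in% sets[[j]]) &&
              (length(sets[[i]]) < length(sets[[j]]) || i > j)) {
            keep[i] <- FALSE
          }
        }
      }
      sets <- sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)), 1L))]
  letters_pool <- c(letters, paste0(rep(letters, each = 26L), letters))
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters_pool[k])
  }
  if (any(out == "")) {
    # a group separated from everything still needs its own letter
    for (g in names(out)[out == ""]) {
      out[g] <- letters_pool[sum(lengths(sets)) + match(g, names(out)[out == ""])]
    }
  }
  out
}

#' Nonparametric group comparison of one trait
#'
#' Kruskal-Wallis omnibus test across treatments followed by Dunn's
#' all-pairs post hoc z-tests and a compact letter display. A classical
#' one-way ANOVA p-value is reported alongside for transparency. Pairs are
#' declared different when the (optionally adjusted) Dunn p-value is below
#' `alpha`.
#'
#' @param x A `trait_table`.
#' @param trait One trait name from [trait_levels()].
#' @param alpha Significance level (default 0.05).
#' @param adjust Dunn p-value adjustment (`"none"`, `"holm"`,
#'   `"bonferroni"`).
#' @return A `group_test` list: `trait`, `omnibus_statistic`, `omnibus_p`
#'   (Kruskal-Wallis), `anova_p`, `pairwise` (symmetric p-value matrix),
#'   `letters`.
#' @export
group_test <- function(x, trait, alpha = 0.05, adjust = "none") {
  d <- x[x$trait == trait, ]
  if (nrow(d) == 0L) stop("no records for trait '", trait, "'")
  g <- factor(d$treatment, levels = unique(d$treatment))
  if (nlevels(g) < 2L) stop("need at least 2 treatments")
  if (any(tapply(d$value, g, length) < 2L)) {
    stop("need at least 2 replicates per treatment for group testing")
  }
  if (stats::var(d$value) == 0) {
    kw_stat <- 0; kw_p <- 1; an_p <- 1
  } else {
    kw <- stats::kruskal.test(d$value, g)
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
    if (is.na(kw_p)) { kw_stat <- 0; kw_p <- 1 }
    an <- stats::anova(stats::aov(value ~ g, data = data.frame(value = d$value, g = g)))
    an_p <- an[["Pr(>F)"]][1L]
  }
  dn <- dunn_test(d$value, g, adjust = adjust)
  lv <- levels(g)
  pm <- matrix(1, nlevels(g), nlevels(g), dimnames = list(lv, lv))
  for (k in seq_len(nrow(dn))) {
    pm[dn$group1[k], dn$group2[k]] <- pm[dn$group2[k], dn$group1[k]] <- dn$p[k]
  }
  sig <- dn[dn$p < alpha, c("group1", "group2"), drop = FALSE]
  lt <- compact_letters(lv, sig)
  structure(list(trait = trait, omnibus_statistic = kw_stat, omnibus_p = kw_p,
                 anova_p = an_p, pairwise = pm, letters = lt, alpha = alpha,
                 adjust = adjust),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat("group_test of '", x$trait, "': Kruskal-Wallis chi2 = ",
      format(x$omnibus_statistic, digits = 4), ", p = ",
      format(x$omnibus_p, digits = 4), " (one-way ANOVA p = ",
      format(x$anova_p, digits = 4), ")\n", sep = "")
  print(data.frame(treatment = names(x$letters), letters = unname(x$letters)))
  invisible(x)
}

#' Summary table in the published layout
#'
#' Per-treatment `mean +/- sd` with compact letters per trait, mirroring
#' the printed trait tables.
#'
#' @param x A `trait_table`.
#' @param alpha,adjust Passed to [group_test()].
#' @return Data frame: `treatment`, `trait`, `mean`, `sd`, `n`, `letters`.
#' @export
trait_report <- function(x, alpha = 0.05, adjust = "none") {
  s <- summarize_traits(x)
  s$letters <- NA_character_
  for (tr in unique(s$trait)) {
    gt <- group_test(x, tr, alpha = alpha, adjust = adjust)
    idx <- s$trait == tr
    s$letters[idx] <- gt$letters[s$treatment[idx]]
  }
  s
}
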
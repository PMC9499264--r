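#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over taxon proportions `p_i = c_i / sum(c)`;
#' zero counts contribute nothing. Natural log (nats) by default; pass
#' `base = 2` for bits.
#'
#' @param counts Non-negative numeric vector of taxon counts, `sum > 0`.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index, a non-negative scalar `<= log(S_obs, base)`.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0, na.rm = TRUE) || anyNA(counts)) {
    stop("counts must be non-negative and non-missing")
  }
  s <- sum(counts)
  if (s <= 0) stop("all-zero count vector: Shannon index undefined")
  p <- counts[counts > 0] / s
  -sum(p * log(p, base = base))
}

#' Chao-1 richness estimator
#'
#' Extrapolates unseen richness from singleton (`F1`) and doubleton (`F2`)
#' counts. The bias-corrected form
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` (default) is defined even when
#' no doubletons are observed; the classic form `S_obs + F1^2 / (2 * F2)`
#' requires `F2 > 0`.
#'
#' @param counts Non-negative integer vector of taxon counts, `sum > 0`.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness, always `>= S_obs`.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0, na.rm = TRUE) || anyNA(counts)) {
    stop("counts must be non-negative and non-missing")
  }
  if (sum(counts) <= 0) stop("all-zero count vector: Chao-1 undefined")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) stop("classic Chao-1 needs F2 > 0; use bias_corrected = TRUE")
    s_obs + f1^2 / (2 * f2)
  }
}

#' Per-sample alpha-diversity table
#'
#' Observed richness, singleton and doubleton counts, Shannon index and
#' Chao-1 for every sample of an OTU table.
#'
#' @param x An `otu_table`.
#' @param base Logarithm base for Shannon (default natural log).
#' @param bias_corrected Passed to [chao1()].
#' @return Data frame: `sample_id`, `treatment`, `S_obs`, `F1`, `F2`,
#'   `shannon`, `chao1`.
#' @export
alpha_diversity <- function(x, base = exp(1), bias_corrected = TRUE) {
  stopifnot(inherits(x, "otu_table"))
  cnt <- x$counts
  out <- data.frame(
    sample_id = colnames(cnt),
    treatment = x$samples$treatment[match(colnames(cnt), x$samples$sample_id)],
    S_obs = apply(cnt, 2L, function(v) sum(v > 0)),
    F1 = apply(cnt, 2L, function(v) sum(v == 1)),
    F2 = apply(cnt, 2L, function(v) sum(v == 2)),
    shannon = apply(cnt, 2L, shannon, base = base),
    chao1 = apply(cnt, 2L, chao1, bias_corrected = bias_corrected),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Relative abundance profiles at a taxonomic rank
#'
#' Aggregates OTU counts by the taxon at the requested rank and normalizes
#' each sample to proportions. Taxa whose proportion stays below
#' `floor` in every sample are pooled into `"Other"`.
#'
#' @param x An `otu_table`.
#' @param rank One of `kingdom`, `phylum` (default), `class`, `order`,
#'   `family`, `genus`.
#' @param floor Display floor in `[0, 1)`; `0` (default) pools nothing.
#' @return Long data frame: `sample_id`, `taxon`, `proportion`; per-sample
#'   proportions sum to 1.
#' @export
relative_abundance <- function(x, rank = "phylum", floor = 0) {
  stopifnot(inherits(x, "otu_table"))
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  if (!rank %in% ranks) {
    stop("unknown rank '", rank, "'; use one of: ", paste(ranks, collapse = ", "))
  }
  tax <- x$taxa[[rank]]
  agg <- rowsum(x$counts, group = tax)
  prop <- sweep(agg, 2L, colSums(agg), "/")
  if (floor > 0) {
    minor <- apply(prop, 1L, max) < floor
    if (any(minor)) {
      pooled <- colSums(prop[minor, , drop = FALSE])
      prop <- rbind(prop[!minor, , drop = FALSE], Other = pooled)
    }
  }
  out <- data.frame(sample_id = rep(colnames(prop), each = nrow(prop)),
                    taxon = rep(rownames(prop), times = ncol(prop)),
                    proportion = as.numeric(prop),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-treatment mean Shannon index
#'
#' Averages per-sample Shannon indices over the replicate soil samples of
#' each treatment — the quantity entered into the metagenomic columns of
#' the evaluation matrix.
#'
#' @param x An `otu_table`.
#' @param base Logarithm base.
#' @return Named numeric vector, one value per treatment.
#' @export
treatment_shannon <- function(x, base = exp(1)) {
  d <- alpha_diversity(x, base = base)
  vapply(split(d$shannon, d$treatment), mean, numeric(1L))
}

#' Rarefy an OTU table to a common depth
#'
#' Seeded subsampling without replacement to the minimum (or given) sample
#' depth. Not applied anywhere by default; provided for sensitivity checks.
#'
#' @param x An `otu_table`.
#' @param depth Target depth; default the minimum column sum.
#' @param seed Integer seed for reproducible subsampling.
#' @return A rarefied `otu_table`.
#' @export
rarefy_otu_table <- function(x, depth = min(colSums(x$counts)), seed = 1L) {
  stopifnot(inherits(x, "otu_table"), depth >= 1)
  if (any(colSums(x$counts) < depth)) stop("a sample is shallower than the target depth")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cnt <- apply(x$counts, 2L, function(v) {
    pool <- rep.int(seq_along(v), v)
    keep <- sample(pool, depth)
    tabulate(keep, nbins = length(v))
  })
  rownames(cnt) <- rownames(x$counts)
  storage.mode(cnt) <- "integer"
  otu_table(cnt, lineage = x$taxa$lineage, samples = x$samples)
}
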
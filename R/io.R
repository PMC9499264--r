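#' @keywords internal
read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA", quote = "\"",
                    comment.char = "")
}

#' Read a long-format trait table
#'
#' Expects a TSV (or CSV, by extension) with columns `treatment`,
#' `replicate`, `trait`, `value`: one row per plant per trait. Trait names
#' must come from [trait_levels()]; values must be non-negative numbers, and
#' dry weights may not exceed the fresh weight of the same organ and
#' replicate.
#'
#' @param path Path to the file.
#' @return A `trait_table` data frame (columns `treatment`, `replicate`,
#'   `trait`, `value`).
#' @export
read_trait_table <- function(path) {
  raw <- read_table_auto(path)
  need <- c("treatment", "replicate", "trait", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("trait table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(val) & !is.na(raw$value))
  if (length(bad) > 0L) {
    stop("trait table ", path, ": non-numeric value at data line ", bad[1L],
         " ('", raw$value[bad[1L]], "')")
  }
  out <- data.frame(treatment = as.character(raw$treatment),
                    replicate = as.integer(raw$replicate),
                    trait = as.character(raw$trait),
                    value = val,
                    stringsAsFactors = FALSE)
  trait_table(out)
}

#' Construct and validate a trait table
#'
#' @param x Data frame with columns `treatment`, `replicate`, `trait`,
#'   `value`.
#' @return The validated data frame with class `trait_table`.
#' @export
trait_table <- function(x) {
  stopifnot(all(c("treatment", "replicate", "trait", "value") %in% names(x)))
  unknown <- setdiff(unique(x$trait), trait_levels())
  if (length(unknown) > 0L) {
    stop("unknown trait(s): ", paste(unknown, collapse = ", "),
         "; allowed traits are: ", paste(trait_levels(), collapse = ", "))
  }
  neg <- which(!is.na(x$value) & x$value < 0)
  if (length(neg) > 0L) {
    stop("negative trait value at row ", neg[1L], " (", x$trait[neg[1L]],
         " = ", x$value[neg[1L]], ")")
  }
  # dry weight cannot exceed fresh weight for the same organ and plant
  for (organ in c("root", "shoot")) {
    fw <- x[x$trait == paste0(organ, "_fw_g"), ]
    dw <- x[x$trait == paste0(organ, "_dw_g"), ]
    if (nrow(fw) > 0L && nrow(dw) > 0L) {
      m <- merge(fw[, c("treatment", "replicate", "value")],
                 dw[, c("treatment", "replicate", "value")],
                 by = c("treatment", "replicate"), suffixes = c("_fw", "_dw"))
      viol <- m$value_dw > m$value_fw + 1e-12
      if (any(viol)) {
        w <- m[which(viol)[1L], ]
        stop(organ, " dry weight ", w$value_dw, " exceeds fresh weight ",
             w$value_fw, " for treatment ", w$treatment,
             ", replicate ", w$replicate)
      }
    }
  }
  rownames(x) <- NULL
  class(x) <- c("trait_table", "data.frame")
  x
}

#' Write a trait table as TSV
#' @param x A `trait_table`.
#' @param path Output path.
#' @export
write_trait_table <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("treatment", "replicate", "trait", "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a taxonomic lineage string
#'
#' Lineages are `;`-separated, kingdom to genus; greengenes-style
#' `k__`/`p__`/... prefixes are tolerated and stripped. Missing or
#' unparseable ranks become `"unassigned"`.
#'
#' @param lineage Character vector of lineage strings.
#' @return Data frame with columns `kingdom`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
parse_lineage <- function(lineage) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- sub("^\\s*[kpcofgs]__", "", trimws(p))
    p[p == "" | is.na(p)] <- "unassigned"
    length(p) <- 6L
    p[is.na(p)] <- "unassigned"
    p
  }, character(6L)))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  names(out) <- ranks
  out
}

#' Read a taxa-by-sample OTU count table
#'
#' Expects a TSV whose first column is the OTU identifier, second column the
#' lineage string, and remaining columns per-sample integer counts. Sample
#' ids of the form `<treatment>_<n>` are parsed into treatment and replicate
#' metadata.
#'
#' @param path Path to the TSV.
#' @return An `otu_table`: a list with `counts` (taxa x samples integer
#'   matrix), `taxa` (data frame: `otu_id`, `lineage` and the six parsed
#'   ranks) and `samples` (data frame: `sample_id`, `treatment`,
#'   `replicate`).
#' @export
read_otu_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 3L) stop("OTU table ", path, " needs otu_id, lineage and >=1 sample column")
  otu_id <- as.character(raw[[1L]])
  lineage <- as.character(raw[[2L]])
  counts <- as.matrix(raw[, -(1:2), drop = FALSE])
  num <- suppressWarnings(apply(counts, 2L, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(counts), dimnames = dimnames(counts))
  if (any(is.na(num))) stop("OTU table ", path, ": non-numeric count")
  if (any(num < 0) || any(abs(num - round(num)) > 1e-9)) {
    stop("OTU table ", path, ": counts must be non-negative integers")
  }
  storage.mode(num) <- "integer"
  rownames(num) <- otu_id
  otu_table(num, lineage = lineage)
}

#' Construct and validate an OTU table
#'
#' @param counts Taxa x samples non-negative integer matrix with OTU row
#'   names and sample column names.
#' @param lineage Character vector of lineage strings, one per row.
#' @param samples Optional sample metadata data frame (`sample_id`,
#'   `treatment`, `replicate`); derived from column names when omitted.
#' @return An `otu_table` object.
#' @export
otu_table <- function(counts, lineage, samples = NULL) {
  stopifnot(is.matrix(counts), length(lineage) == nrow(counts))
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate otu_id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("empty sample (all-zero counts): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  if (is.null(samples)) {
    ids <- colnames(counts)
    rep_no <- suppressWarnings(as.integer(sub("^.*_([0-9]+)$", "\\1", ids)))
    treat <- ifelse(grepl("_[0-9]+$", ids), sub("_[0-9]+$", "", ids), ids)
    samples <- data.frame(sample_id = ids, treatment = treat,
                          replicate = rep_no, stringsAsFactors = FALSE)
  }
  taxa <- cbind(data.frame(otu_id = rownames(counts),
                           lineage = as.character(lineage),
                           stringsAsFactors = FALSE),
                parse_lineage(lineage))
  structure(list(counts = counts, taxa = taxa, samples = samples),
            class = "otu_table")
}

#' Write an OTU table as TSV
#' @param x An `otu_table`.
#' @param path Output path.
#' @export
write_otu_table <- function(x, path) {
  df <- cbind(data.frame(otu_id = x$taxa$otu_id, lineage = x$taxa$lineage,
                         stringsAsFactors = FALSE),
              as.data.frame(x$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table: ", nrow(x$counts), " taxa x ", ncol(x$counts), " samples; ",
      "median depth ", stats::median(colSums(x$counts)), "\n", sep = "")
  invisible(x)
}

#' Read an RT-qPCR Ct table
#'
#' Expects a TSV with columns `gene`, `treatment`, `timepoint`, `bio_rep`,
#' `tech_rep`, `ct`. Ct values above the detection ceiling (strictly
#' `> ceiling`, default 36 cycles) and literal `NA` entries are marked
#' undetermined (`NA`) at read time; a raw Ct of exactly 36.0 is kept.
#'
#' @param path Path to the TSV.
#' @param ceiling Detection ceiling in cycles (default 36).
#' @param hk Housekeeping gene name used to warn about conditions that lack
#'   normalizer measurements (default `"18S"`; `NULL` disables the check).
#' @return A `ct_table` data frame; undetermined Ct values are `NA`.
#' @export
read_ct_table <- function(path, ceiling = 36, hk = "18S") {
  raw <- read_table_auto(path)
  need <- c("gene", "treatment", "timepoint", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("Ct table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  ct <- suppressWarnings(as.numeric(raw$ct))
  bad <- which(is.na(ct) & !is.na(raw$ct) & raw$ct != "NA")
  if (length(bad) > 0L) {
    stop("Ct table ", path, ": non-numeric Ct at data line ", bad[1L])
  }
  if (any(ct <= 0, na.rm = TRUE)) stop("Ct table ", path, ": Ct must be positive")
  ct[!is.na(ct) & ct > ceiling] <- NA_real_
  out <- data.frame(gene = as.character(raw$gene),
                    treatment = as.character(raw$treatment),
                    timepoint = as.character(raw$timepoint),
                    bio_rep = as.integer(raw$bio_rep),
                    tech_rep = as.integer(raw$tech_rep),
                    ct = ct, stringsAsFactors = FALSE)
  if (!is.null(hk)) {
    cells <- unique(out[, c("treatment", "timepoint")])
    hk_cells <- unique(out[out$gene == hk & !is.na(out$ct), c("treatment", "timepoint")])
    key <- function(d) paste(d$treatment, d$timepoint, sep = "|")
    missing_hk <- setdiff(key(cells), key(hk_cells))
    if (length(missing_hk) > 0L) {
      warning("no determined '", hk, "' housekeeping Ct for: ",
              paste(missing_hk, collapse = ", "),
              "; fold changes there will be undetermined")
    }
  }
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Write a Ct table as TSV
#' @param x A `ct_table` data frame.
#' @param path Output path.
#' @export
write_ct_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
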
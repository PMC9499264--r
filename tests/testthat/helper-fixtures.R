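# tiny in-code fixtures shared across test files

toy_otu <- function() {
  counts <- matrix(c(5L, 3L, 2L,
                     1L, 4L, 5L), nrow = 3,
                   dimnames = list(c("otu1", "otu2", "otu3"), c("Control_1", "Char_1")))
  otu_table(counts,
            lineage = c("k__Bacteria;p__Proteobacteria;c__Alpha",
                        "k__Bacteria;p__Bacteroidetes",
                        "k__Bacteria;p__Proteobacteria;c__Gamma"))
}

toy_trait_table <- function(values_by_treatment) {
  rows <- do.call(rbind, lapply(names(values_by_treatment), function(tr) {
    v <- values_by_treatment[[tr]]
    data.frame(treatment = tr, replicate = seq_along(v),
               trait = "spad", value = v, stringsAsFactors = FALSE)
  }))
  trait_table(rows)
}

noise_free_config <- function(crop = "wheat", ...) {
  sim_config(crop = crop, hk_ct_sd = 0, bio_sd = 0, tech_rep_sd = 0, ...)
}

# independent brute-force oracle for the max-tie scoring rule: ascending
# sort positions, every tied value takes the maximum position of its group
oracle_max_tie <- function(v) {
  pos <- integer(length(v))
  pos[order(v)] <- seq_along(v)
  vapply(seq_along(v), function(i) max(pos[v == v[i]]), integer(1))
}

letters_share <- function(a, b) {
  any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
}
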
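#' Derive a per-table seed from the master seed
#'
#' Each simulated table draws from its own stream, seeded from the master
#' seed and the table name, so adding one table to a study never perturbs
#' the others.
#'
#' @param seed Master integer seed.
#' @param name Table name, e.g. `"traits"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (131 * seq_along(utf8ToInt(name))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(derive_seed(seed, name))
  expr
}

default_phylum_profile <- function(community = c("bacteria", "fungi")) {
  community <- match.arg(community)
  if (community == "bacteria") {
    c(Proteobacteria = 0.55, Bacteroidetes = 0.11, Verrucomicrobia = 0.08,
      Actinobacteria = 0.07, Acidobacteria = 0.05, TM7 = 0.04,
      Gemmatimonadetes = 0.03, Other = 0.07)
  } else {
    c(Ascomycota = 0.55, Basidiomycota = 0.20, Aphelidiomycota = 0.10,
      Chytridiomycota = 0.07, Mucoromycota = 0.05, Other = 0.03)
  }
}

default_gene_panel <- function() {
  c("aceS3", "agpll1", "cer1", "fad1", "nmt1", "oy1", "pgd",
    "pgk", "pyrk", "P450", "psbp6", "sdq2", "sm2", "pal1")
}

default_planted_fc <- function(genes, treatments, timepoints) {
  fc <- array(1, dim = c(length(genes), length(treatments), length(timepoints)),
              dimnames = list(genes, treatments, timepoints))
  # consortium treatments induce part of the panel early; char-delivered
  # consortia with AMF induce a broad block of nine genes
  mc <- treatments[grepl("MC", treatments)]
  for (tr in mc) {
    fc[genes[1:5], tr, 1L] <- 2.5
    fc[genes[1:3], tr, 2L] <- 3
    fc[genes[12:13], tr, 2L] <- 0.4
  }
  strong <- intersect("Char_MC-C_AMF", treatments)
  if (length(strong) == 1L) fc[genes[1:9], strong, 1L] <- 4.5
  fc
}

#' Configuration of a synthetic biofertilizer study
#'
#' Bundles every parameter of the three simulators. Defaults reproduce the
#' shape of the packaged trials: 12 wheat (or 8 maize) treatments with the
#' packaged trait means/SDs, six replicate pots per treatment, duplicate
#' rhizosphere soil samples per treatment with a Proteobacteria-dominated
#' bacterial profile (55%, Bacteroidetes 11%, minor phyla 3-8%), a
#' 14-gene qPCR panel at two timepoints with two biological and three
#' technical replicates, an 18S housekeeping gene, and a 36-cycle
#' detection ceiling applied downstream at read time.
#'
#' @param crop `"wheat"` or `"maize"`.
#' @param n_replicates Replicate pots per treatment for traits (default 6).
#' @param seed Master seed; each table derives its own stream from it.
#' @param trait_means,trait_sds Optional treatment x trait matrices;
#'   default the packaged printed summaries for `crop`.
#' @param phylum_profile_bacteria,phylum_profile_fungi Named baseline
#'   phylum proportions, each summing to 1.
#' @param dispersion Dirichlet concentration scalar (larger = samples
#'   closer to the profile; default 200).
#' @param library_size Reads per sample (default 20000).
#' @param n_otus_per_phylum OTUs splitting each phylum, geometric within-
#'   phylum weights (default 8).
#' @param n_sample_reps Soil samples per treatment (default 2, duplicates).
#' @param genes Target gene panel (default 14 genes).
#' @param gene_offsets Named per-gene Ct offsets above the housekeeping Ct.
#' @param planted_fc `gene x treatment x timepoint` array of true fold
#'   changes (default: consortium treatments induce part of the panel).
#' @param timepoints Sampling timepoints (default `c("21DAS", "60DAS")`).
#' @param n_bio_reps,n_tech_reps Biological / technical qPCR replicates
#'   (defaults 2 and 3).
#' @param hk Housekeeping gene name (default `"18S"`).
#' @param hk_ct_mean,hk_ct_sd Housekeeping Ct distribution (defaults 15,
#'   0.2).
#' @param bio_sd Biological-replicate Ct noise SD (default 0.15).
#' @param tech_rep_sd Technical-replicate Ct noise SD (default 0.15).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(crop = c("wheat", "maize"),
                       n_replicates = 6L,
                       seed = 1L,
                       trait_means = NULL, trait_sds = NULL,
                       phylum_profile_bacteria = default_phylum_profile("bacteria"),
                       phylum_profile_fungi = default_phylum_profile("fungi"),
                       dispersion = 200,
                       library_size = 20000L,
                       n_otus_per_phylum = 8L,
                       n_sample_reps = 2L,
                       genes = default_gene_panel(),
                       gene_offsets = NULL,
                       planted_fc = NULL,
                       timepoints = c("21DAS", "60DAS"),
                       n_bio_reps = 2L, n_tech_reps = 3L,
                       hk = "18S", hk_ct_mean = 15, hk_ct_sd = 0.2,
                       bio_sd = 0.15, tech_rep_sd = 0.15) {
  crop <- match.arg(crop)
  treatments <- treatment_labels(crop)
  if (is.null(trait_means) || is.null(trait_sds)) {
    s <- packaged_trait_summary(crop)
    tm <- matrix(NA_real_, length(treatments), length(trait_levels()),
                 dimnames = list(treatments, trait_levels()))
    ts <- tm
    for (i in seq_len(nrow(s))) {
      tm[s$treatment[i], s$trait[i]] <- s$mean[i]
      ts[s$treatment[i], s$trait[i]] <- s$sd[i]
    }
    if (is.null(trait_means)) trait_means <- tm
    if (is.null(trait_sds)) trait_sds <- ts
  }
  if (is.null(gene_offsets)) {
    gene_offsets <- stats::setNames(seq(5, by = 0.5, length.out = length(genes)), genes)
  }
  if (is.null(planted_fc)) {
    planted_fc <- default_planted_fc(genes, treatments, timepoints)
  }
  cfg <- structure(list(
    crop = crop, treatments = treatments,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed),
    trait_means = trait_means, trait_sds = trait_sds,
    phylum_profile_bacteria = phylum_profile_bacteria,
    phylum_profile_fungi = phylum_profile_fungi,
    dispersion = dispersion, library_size = as.integer(library_size),
    n_otus_per_phylum = as.integer(n_otus_per_phylum),
    n_sample_reps = as.integer(n_sample_reps),
    genes = genes, gene_offsets = gene_offsets, planted_fc = planted_fc,
    timepoints = timepoints, n_bio_reps = as.integer(n_bio_reps),
    n_tech_reps = as.integer(n_tech_reps),
    hk = hk, hk_ct_mean = hk_ct_mean, hk_ct_sd = hk_ct_sd,
    bio_sd = bio_sd, tech_rep_sd = tech_rep_sd), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  for (prof in list(cfg$phylum_profile_bacteria, cfg$phylum_profile_fungi)) {
    if (abs(sum(prof) - 1) > 1e-9) {
      stop("phylum profile proportions must sum to 1 (got ", sum(prof), ")")
    }
    if (any(prof < 0)) stop("phylum proportions must be non-negative")
  }
  if (cfg$library_size <= 0) stop("library_size must be > 0")
  if (cfg$dispersion <= 0) stop("Dirichlet dispersion must be > 0")
  if (any(cfg$trait_sds < 0, na.rm = TRUE)) stop("trait SDs must be >= 0")
  if (any(cfg$planted_fc <= 0)) stop("planted fold changes must be positive")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  if (any(c(cfg$hk_ct_sd, cfg$bio_sd, cfg$tech_rep_sd) < 0)) {
    stop("noise SDs must be >= 0")
  }
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields map directly onto [sim_config()] arguments;
#' `phylum_profile_bacteria`/`_fungi` are name-to-proportion maps, and
#' `planted_fc` is a list of `{gene, treatment, timepoint, fc}` records
#' overriding the default fold changes of 1.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  fc_records <- y$planted_fc
  y$planted_fc <- NULL
  for (f in c("phylum_profile_bacteria", "phylum_profile_fungi")) {
    if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
  }
  cfg <- do.call(sim_config, y)
  if (!is.null(fc_records)) {
    for (r in fc_records) {
      cfg$planted_fc[r$gene, r$treatment, r$timepoint] <- r$fc
    }
    validate_sim_config(cfg)
  }
  cfg
}

# draw from Normal(mean, sd) truncated at 0 by resampling (keeps shape,
# unlike clipping); degenerate when sd = 0
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal resampling failed (mean ", mean, ", sd ", sd, ")")
  }
  out
}

# Beta draw parameterized by mean and sd via method of moments; the sd is
# capped just under the feasibility bound sqrt(m * (1 - m))
rbeta_ms <- function(n, m, s) {
  m <- min(max(m, 1e-6), 1 - 1e-6)
  if (s == 0) return(rep(m, n))
  smax <- sqrt(m * (1 - m))
  s <- min(s, 0.95 * smax)
  nu <- m * (1 - m) / s^2 - 1
  stats::rbeta(n, m * nu, (1 - m) * nu)
}

#' Simulate a replicate-level trait table
#'
#' Lengths, fresh weights and SPAD are drawn from Normal distributions
#' truncated at zero (by resampling) with the configured treatment means
#' and SDs. Dry weights are not drawn independently: each replicate's dry
#' weight is its fresh weight times a Beta-distributed dry fraction (mean
#' `dw_mean / fw_mean`, spread from the configured dry-biomass SD), which
#' guarantees `dw <= fw`; the dry-biomass percentage is derived from those
#' two, never drawn.
#'
#' @param config A `sim_config`.
#' @return A `trait_table` with `n_replicates` rows per treatment x trait.
#' @export
simulate_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "traits", {
    n <- config$n_replicates
    tm <- config$trait_means; ts <- config$trait_sds
    rows <- list()
    for (tr in config$treatments) {
      drawn <- list()
      for (trait in c("root_length_cm", "shoot_length_cm", "root_fw_g",
                      "shoot_fw_g", "spad")) {
        drawn[[trait]] <- rnorm_trunc0(n, tm[tr, trait], ts[tr, trait])
      }
      for (organ in c("root", "shoot")) {
        fw <- drawn[[paste0(organ, "_fw_g")]]
        m <- tm[tr, paste0(organ, "_dw_g")] / tm[tr, paste0(organ, "_fw_g")]
        s <- ts[tr, paste0(organ, "_dry_biomass_pct")] / 100
        frac <- rbeta_ms(n, m, s)
        drawn[[paste0(organ, "_dw_g")]] <- fw * frac
        drawn[[paste0(organ, "_dry_biomass_pct")]] <- 100 * frac
      }
      for (trait in trait_levels()) {
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr, replicate = seq_len(n), trait = trait,
          value = drawn[[trait]], stringsAsFactors = FALSE)
      }
    }
    trait_table(do.call(rbind, rows))
  })
}

# phylum multipliers emulating the reported community shifts: consortia
# raise the minor phyla (evenness up), char alone depresses them
treatment_phylum_multiplier <- function(treatment, profile) {
  mult <- rep(1, length(profile))
  names(mult) <- names(profile)
  minor <- names(profile)[-1L]
  if (grepl("MC", treatment, fixed = TRUE)) {
    mult[minor] <- 1.15
  } else if (grepl("Char", treatment, fixed = TRUE)) {
    mult[minor] <- 0.9
  }
  mult
}

#' Simulate a Dirichlet-multinomial OTU table
#'
#' Each phylum of the baseline profile is split into `n_otus_per_phylum`
#' OTUs with geometrically decaying within-phylum weights. Per sample, the
#' treatment-adjusted OTU proportions are drawn from a Dirichlet with
#' concentration `dispersion`, and counts from a Multinomial at the
#' configured library size. Every treatment contributes `n_sample_reps`
#' duplicate samples.
#'
#' @param config A `sim_config`.
#' @param community `"bacteria"` (16S-like) or `"fungi"` (ITS-like).
#' @return An `otu_table`.
#' @export
simulate_otu_table <- function(config, community = c("bacteria", "fungi")) {
  stopifnot(inherits(config, "sim_config"))
  community <- match.arg(community)
  profile <- config[[paste0("phylum_profile_", community)]]
  with_stream(config$seed, paste0("otu_", community), {
    K <- config$n_otus_per_phylum
    w <- 0.6^(seq_len(K) - 1L); w <- w / sum(w)
    phyla <- names(profile)
    kingdom <- if (community == "bacteria") "Bacteria" else "Fungi"
    otu_id <- as.vector(t(outer(phyla, seq_len(K), function(p, k)
      sprintf("%s_%s_%02d", toupper(substr(community, 1L, 1L)), p, k))))
    lineage <- as.vector(t(outer(phyla, seq_len(K), function(p, k)
      sprintf("k__%s;p__%s;c__unassigned;o__unassigned;f__unassigned;g__%s_g%02d",
              kingdom, p, p, k))))
    samples <- expand.grid(rep_no = seq_len(config$n_sample_reps),
                           treatment = config$treatments,
                           stringsAsFactors = FALSE)
    samples <- samples[order(match(samples$treatment, config$treatments)), ]
    sample_id <- paste(samples$treatment, samples$rep_no, sep = "_")
    counts <- matrix(0L, length(otu_id), nrow(samples),
                     dimnames = list(otu_id, sample_id))
    for (s in seq_len(nrow(samples))) {
      mult <- treatment_phylum_multiplier(samples$treatment[s], profile)
      ph <- profile * mult
      ph <- ph / sum(ph)
      prop <- as.vector(t(outer(ph, w)))  # phylum-major, matches otu_id order
      alpha <- config$dispersion * prop
      g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      if (sum(g) == 0) g[which.max(alpha)] <- 1
      counts[, s] <- stats::rmultinom(1L, config$library_size, g / sum(g))[, 1L]
    }
    keep_cols <- colSums(counts) > 0
    otu_table(counts[, keep_cols, drop = FALSE], lineage = lineage,
              samples = data.frame(sample_id = sample_id,
                                   treatment = samples$treatment,
                                   replicate = samples$rep_no,
                                   stringsAsFactors = FALSE)[keep_cols, ])
  })
}

#' Simulate an RT-qPCR Ct table
#'
#' Housekeeping Ct is Normal(`hk_ct_mean`, `hk_ct_sd`) per biological
#' replicate. Each target gene's Ct is the replicate's housekeeping Ct plus
#' the gene offset minus `log2` of the planted fold change, plus
#' biological noise; technical replicates add Normal(0, `tech_rep_sd`).
#' Values above the detection ceiling are emitted as-is — censoring to
#' undetermined is the reader's job ([read_ct_table()], [censor_ct()]).
#'
#' @param config A `sim_config`.
#' @return Data frame with `ct_table` columns (`gene`, `treatment`,
#'   `timepoint`, `bio_rep`, `tech_rep`, `ct`), uncensored.
#' @export
simulate_ct_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "ct", {
    rows <- vector("list", 0L)
    for (tp_i in seq_along(config$timepoints)) {
      tp <- config$timepoints[tp_i]
      for (tr in config$treatments) {
        for (b in seq_len(config$n_bio_reps)) {
          hk_base <- config$hk_ct_mean +
            if (config$hk_ct_sd > 0) stats::rnorm(1L, 0, config$hk_ct_sd) else 0
          rows[[length(rows) + 1L]] <- data.frame(
            gene = config$hk, treatment = tr, timepoint = tp, bio_rep = b,
            tech_rep = seq_len(config$n_tech_reps),
            ct = hk_base + if (config$tech_rep_sd > 0)
              stats::rnorm(config$n_tech_reps, 0, config$tech_rep_sd) else 0,
            stringsAsFactors = FALSE)
          for (g in config$genes) {
            base <- hk_base + config$gene_offsets[[g]] -
              log2(config$planted_fc[g, tr, tp_i]) +
              if (config$bio_sd > 0) stats::rnorm(1L, 0, config$bio_sd) else 0
            rows[[length(rows) + 1L]] <- data.frame(
              gene = g, treatment = tr, timepoint = tp, bio_rep = b,
              tech_rep = seq_len(config$n_tech_reps),
              ct = base + if (config$tech_rep_sd > 0)
                stats::rnorm(config$n_tech_reps, 0, config$tech_rep_sd) else 0,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Apply the detection ceiling to a raw Ct table
#'
#' Marks Ct values strictly above `ceiling` as undetermined (`NA`),
#' mirroring what [read_ct_table()] does at read time; exactly 36.0 is
#' kept.
#'
#' @param x Data frame with a `ct` column.
#' @param ceiling Detection ceiling in cycles (default 36).
#' @return The censored `ct_table`.
#' @export
censor_ct <- function(x, ceiling = 36) {
  x$ct[!is.na(x$ct) & x$ct > ceiling] <- NA_real_
  class(x) <- unique(c("ct_table", class(x)))
  x
}

#' Simulate a complete study
#'
#' Runs the three simulators with their independent streams and optionally
#' writes the four TSVs (`traits.tsv`, `otu_bacteria.tsv`,
#' `otu_fungi.tsv`, `ct.tsv`) to a directory.
#'
#' @param config A `sim_config`.
#' @param outdir Optional output directory (created if missing).
#' @return List with `traits`, `otu_bacteria`, `otu_fungi`, `ct` (raw,
#'   uncensored) and the `config`.
#' @export
simulate_study <- function(config = sim_config(), outdir = NULL) {
  out <- list(traits = simulate_traits(config),
              otu_bacteria = simulate_otu_table(config, "bacteria"),
              otu_fungi = simulate_otu_table(config, "fungi"),
              ct = simulate_ct_table(config),
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_trait_table(out$traits, file.path(outdir, "traits.tsv"))
    write_otu_table(out$otu_bacteria, file.path(outdir, "otu_bacteria.tsv"))
    write_otu_table(out$otu_fungi, file.path(outdir, "otu_fungi.tsv"))
    write_ct_table(out$ct, file.path(outdir, "ct.tsv"))
  }
  out
}
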
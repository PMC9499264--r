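test_that("same seed gives identical studies, different seeds differ", {
  a <- simulate_study(sim_config(seed = 7L))
  b <- simulate_study(sim_config(seed = 7L))
  c <- simulate_study(sim_config(seed = 8L))
  expect_identical(a$traits, b$traits)
  expect_identical(a$otu_bacteria$counts, b$otu_bacteria$counts)
  expect_identical(a$ct, b$ct)
  expect_false(identical(a$traits$value, c$traits$value))
  expect_false(identical(a$otu_bacteria$counts, c$otu_bacteria$counts))
})

test_that("per-table streams are independent of sibling tables", {
  cfg <- sim_config(seed = 3L)
  alone <- simulate_otu_table(cfg, "fungi")
  set.seed(999)  # whatever global state precedes must not matter
  invisible(simulate_traits(cfg))
  after <- simulate_otu_table(cfg, "fungi")
  expect_identical(alone$counts, after$counts)
})

test_that("zero-SD configuration degenerates to the configured means", {
  cfg <- sim_config(crop = "maize", n_replicates = 3L, seed = 1L)
  cfg$trait_sds[] <- 0
  tt <- simulate_traits(cfg)
  s <- summarize_traits(tt)
  expect_true(all(s$sd == 0))
  drawn <- c("root_length_cm", "shoot_length_cm", "root_fw_g", "shoot_fw_g",
             "root_dw_g", "shoot_dw_g", "spad")
  for (i in which(s$trait %in% drawn)) {
    expect_equal(s$mean[i], cfg$trait_means[s$treatment[i], s$trait[i]],
                 tolerance = 1e-12)
  }
})

test_that("a single replicate yields one record per treatment x trait", {
  tt <- simulate_traits(sim_config(n_replicates = 1L, seed = 2L))
  expect_equal(nrow(tt), 12 * 9)
  expect_true(all(tt$replicate == 1L))
})

test_that("simulated trait means recover the configured means (generator contract)", {
  # drawn traits are checked against their configured SDs; dry weights are
  # derived as FW x Beta fraction, so their sampling band comes from the
  # delta-method SD of that product (the printed DW SDs round to 0.0 in
  # several rows and cannot band a derived quantity); the dry-biomass
  # percentage is a derived ratio and not parameterized by its printed mean
  cfg0 <- sim_config(crop = "wheat", n_replicates = 6L)
  drawn <- c("root_length_cm", "shoot_length_cm", "root_fw_g", "shoot_fw_g", "spad")
  band_sd <- cfg0$trait_sds
  for (organ in c("root", "shoot")) {
    fw_m <- cfg0$trait_means[, paste0(organ, "_fw_g")]
    fw_s <- cfg0$trait_sds[, paste0(organ, "_fw_g")]
    m <- cfg0$trait_means[, paste0(organ, "_dw_g")] / fw_m
    s <- pmin(cfg0$trait_sds[, paste0(organ, "_dry_biomass_pct")] / 100,
              0.95 * sqrt(m * (1 - m)))
    band_sd[, paste0(organ, "_dw_g")] <- sqrt(m^2 * fw_s^2 + fw_m^2 * s^2 + fw_s^2 * s^2)
  }
  traits <- c(drawn, "root_dw_g", "shoot_dw_g")
  n_ok <- 0L; n_tot <- 0L
  for (seed in 1:100) {
    cfg <- sim_config(crop = "wheat", n_replicates = 6L, seed = seed)
    s <- summarize_traits(simulate_traits(cfg))
    s <- s[s$trait %in% traits, ]
    mu <- cfg0$trait_means[cbind(s$treatment, s$trait)]
    sd0 <- band_sd[cbind(s$treatment, s$trait)]
    ok <- abs(s$mean - mu) <= 2 * sd0 / sqrt(6) + 1e-12
    n_ok <- n_ok + sum(ok); n_tot <- n_tot + length(ok)
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("dry weights never exceed fresh weights in simulated tables", {
  tt <- simulate_traits(sim_config(seed = 5L))
  w <- reshape(as.data.frame(tt), idvar = c("treatment", "replicate"),
               timevar = "trait", direction = "wide")
  expect_true(all(w$value.root_dw_g <= w$value.root_fw_g))
  expect_true(all(w$value.shoot_dw_g <= w$value.shoot_fw_g))
})

test_that("Dirichlet-multinomial samples concentrate on the configured profile", {
  cfg <- sim_config(seed = 4L, dispersion = 1e9, library_size = 1000000L)
  x <- simulate_otu_table(cfg, "bacteria")
  ab <- relative_abundance(x, "phylum")
  # treatments without a community shift should sit on the baseline profile
  for (sm in c("Control_1", "Control_2", "AMF_1")) {
    got <- ab$proportion[ab$sample_id == sm]
    names(got) <- ab$taxon[ab$sample_id == sm]
    prof <- cfg$phylum_profile_bacteria
    expect_true(all(abs(got[names(prof)] - prof) < 0.005))
  }
  # Shannon of a high-concentration sample matches the analytic entropy
  phy_counts <- rowsum(x$counts[, "Control_1"], x$taxa$phylum)[, 1]
  p <- cfg$phylum_profile_bacteria
  expect_equal(shannon(phy_counts), -sum(p * log(p)), tolerance = 0.01)
})

test_that("a single-phylum profile gives zero phylum-level Shannon", {
  cfg <- sim_config(seed = 9L,
                    phylum_profile_bacteria = c(Proteobacteria = 1))
  x <- simulate_otu_table(cfg, "bacteria")
  phy <- rowsum(x$counts[, 1], x$taxa$phylum)[, 1]
  expect_equal(shannon(phy), 0)
})

test_that("noise-free Ct simulation inverts exactly through the ddCt stage", {
  cfg <- noise_free_config()
  fc <- fold_changes(censor_ct(simulate_ct_table(cfg)))
  planted <- cfg$planted_fc[cbind(match(fc$gene, cfg$genes),
                                  match(fc$treatment, cfg$treatments),
                                  match(fc$timepoint, cfg$timepoints))]
  expect_true(all(abs(fc$fc - planted) / planted < 1e-9))
})

test_that("a gene pushed past the Ct ceiling becomes undetermined downstream", {
  cfg <- noise_free_config()
  cfg$gene_offsets[["pgk"]] <- 30  # Ct = 45 > 36
  fc <- fold_changes(censor_ct(simulate_ct_table(cfg)))
  expect_true(all(fc$status[fc$gene == "pgk"] == "undetermined"))
  expect_true(all(fc$status[fc$gene == "pgd"] != "undetermined"))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(phylum_profile_bacteria = c(A = 0.5, B = 0.4)),
               "sum to 1")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(library_size = 0), "library_size")
  cfg <- sim_config(); cfg$trait_sds[1, 1] <- -1
  expect_error(validate_sim_config(cfg), "SDs")
})

test_that("YAML configs round into sim_config with planted overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("crop: maize", "seed: 21", "n_replicates: 4",
               "planted_fc:",
               "  - gene: pgk", "    treatment: Char_MC-C", "    timepoint: 21DAS",
               "    fc: 8"), path)
  cfg <- read_sim_config(path)
  expect_identical(cfg$crop, "maize")
  expect_equal(cfg$n_replicates, 4L)
  expect_equal(cfg$planted_fc["pgk", "Char_MC-C", "21DAS"], 8)
})
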
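make_ct <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], treatment = r[[2]], timepoint = "21DAS",
               bio_rep = as.integer(r[[3]]), tech_rep = as.integer(r[[4]]),
               ct = as.numeric(r[[5]]), stringsAsFactors = FALSE)
  }))
  class(df) <- c("ct_table", "data.frame")
  df
}

test_that("technical replicates collapse to determined-only means", {
  x <- make_ct(list("g", "Control", 1, 1, 20.0), list("g", "Control", 1, 2, 20.2),
               list("g", "Control", 1, 3, 20.4))
  cc <- collapse_tech_reps(x)
  expect_equal(cc$ct, 20.2)
  expect_false(cc$partial)

  x$ct[2] <- NA
  cc <- collapse_tech_reps(x)
  expect_equal(cc$ct, 20.2)            # mean of 20.0 and 20.4
  expect_true(cc$partial)
  expect_equal(cc$n_determined, 2L)

  x$ct[] <- NA
  cc <- collapse_tech_reps(x)
  expect_true(is.na(cc$ct))
  expect_false(cc$partial)
})

test_that("ddCt of 0 / -1 / +1 maps to fc 1 / 2 / 0.5 with inclusive thresholds", {
  # calibrator dCt = 20 - 15 = 5; treatments shift the target Ct only
  x <- make_ct(list("18S", "Control", 1, 1, 15), list("g", "Control", 1, 1, 20),
               list("18S", "T0", 1, 1, 15),      list("g", "T0", 1, 1, 20),
               list("18S", "Tup", 1, 1, 15),     list("g", "Tup", 1, 1, 19),
               list("18S", "Tdn", 1, 1, 15),     list("g", "Tdn", 1, 1, 21))
  fc <- fold_changes(x)
  get <- function(tr, col) fc[[col]][fc$treatment == tr]
  expect_equal(get("T0", "ddct"), 0);  expect_equal(get("T0", "fc"), 1)
  expect_identical(get("T0", "status"), "unchanged")
  expect_equal(get("Tup", "fc"), 2);   expect_identical(get("Tup", "status"), "up")
  expect_equal(get("Tdn", "fc"), 0.5); expect_identical(get("Tdn", "status"), "down")
  expect_equal(get("Control", "fc"), 1)   # calibrator self-test
})

test_that("an undetermined housekeeping Ct voids the whole condition", {
  x <- make_ct(list("18S", "Control", 1, 1, 15), list("g", "Control", 1, 1, 20),
               list("18S", "T", 1, 1, NA),       list("g", "T", 1, 1, 18))
  fc <- fold_changes(x)
  expect_identical(fc$status[fc$treatment == "T"], "undetermined")
  expect_true(is.na(fc$fc[fc$treatment == "T"]))
})

test_that("fold changes are invariant to a constant Ct shift within a condition", {
  cfg <- sim_config(seed = 13L)
  x <- censor_ct(simulate_ct_table(cfg))
  base <- fold_changes(x)
  shifted <- x
  idx <- shifted$treatment == "Char" & shifted$timepoint == "21DAS"
  shifted$ct[idx] <- shifted$ct[idx] + 3.7
  out <- fold_changes(shifted)
  expect_equal(out$fc, base$fc, tolerance = 1e-12)
})

test_that("calibrator fold change is exactly 1 under geometric averaging, even with noise", {
  cfg <- sim_config(seed = 14L)
  fc <- fold_changes(censor_ct(simulate_ct_table(cfg)))
  expect_equal(fc$fc[fc$treatment == "Control"],
               rep(1, sum(fc$treatment == "Control")), tolerance = 1e-12)
})

test_that("geometric and arithmetic biological-replicate averaging differ as expected", {
  # two bio reps with ddct -1 and +1: geometric fc = 1, arithmetic = (2 + 0.5)/2
  x <- make_ct(list("18S", "Control", 1, 1, 15), list("g", "Control", 1, 1, 20),
               list("18S", "Control", 2, 1, 15), list("g", "Control", 2, 1, 20),
               list("18S", "T", 1, 1, 15),       list("g", "T", 1, 1, 19),
               list("18S", "T", 2, 1, 15),       list("g", "T", 2, 1, 21))
  geo <- fold_changes(x)
  ari <- fold_changes(x, average = "arithmetic")
  expect_equal(geo$fc[geo$treatment == "T"], 1)
  expect_equal(ari$fc[ari$treatment == "T"], 1.25)
})

test_that("upregulated genes are counted per condition, excluding undetermined", {
  cfg <- noise_free_config()
  cfg$planted_fc[, , ] <- 1
  fc <- fold_changes(censor_ct(simulate_ct_table(cfg)))
  cu <- count_upregulated(fc)
  expect_true(all(cu$n_up == 0))               # all fc exactly 1

  cfg$planted_fc["pgk", "Char", 1] <- 2.0      # boundary: fc exactly 2 counts
  cfg$gene_offsets[["pgd"]] <- 30              # undetermined, must not count
  fc <- fold_changes(censor_ct(simulate_ct_table(cfg)))
  cu <- count_upregulated(fc)
  row <- cu[cu$treatment == "Char" & cu$timepoint == "21DAS", ]
  expect_equal(row$n_up, 1L)
  expect_equal(row$n_undetermined, 1L)
  expect_equal(row$n_determined, length(cfg$genes) - 1L)
})

test_that("expression matrices export dCt and log2 fold change side by side", {
  cfg <- noise_free_config()
  fc <- fold_changes(censor_ct(simulate_ct_table(cfg)))
  m <- expression_matrices(fc)
  expect_identical(dim(m$dct), dim(m$log2_fc))
  expect_equal(nrow(m$dct), length(cfg$genes))
  # noise-free: log2 fc equals the planted log2 fold change
  expect_equal(m$log2_fc["pgk", "Char_MC-C_AMF@21DAS"], log2(4.5))
})
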
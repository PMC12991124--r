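# Synthetic-data generator: determinism, geometry, intensity model,
# missingness calibration, and the add-back / tracing simulators.

test_that("seeded runs are reproducible end to end", {
  cfg <- quick_config(seed = 5)
  pr1 <- simulate_proteome(cfg)
  pr2 <- simulate_proteome(cfg)
  expect_identical(pr1, pr2)
  ex1 <- simulate_experiment(cfg, pr1)
  ex2 <- simulate_experiment(cfg, pr2)
  expect_identical(ex1, ex2)
  ab1 <- simulate_atp_addback(cfg, pr1)
  ab2 <- simulate_atp_addback(cfg, pr2)
  expect_identical(ab1, ab2)
  ft1 <- simulate_feature_table(cfg)
  ft2 <- simulate_feature_table(cfg)
  expect_identical(ft1, ft2)
  tr1 <- simulate_tracing(cfg)
  tr2 <- simulate_tracing(cfg)
  expect_identical(tr1, tr2)
})

test_that("every modified offset indexes a cysteine, in peptide and protein", {
  cfg <- quick_config(seed = 9)
  pr <- simulate_proteome(cfg)
  peps <- pr$enriched_peptides
  off <- as.integer(peps$offsets)
  expect_true(all(substring(peps$sequence, off, off) == "C"))
  # protein residue from the site id matches a C in the database sequence
  res <- as.integer(sub(".*_C", "", peps$site_id))
  seqs <- unclass(pr$database)[peps$accession]
  expect_true(all(substring(seqs, res, res) == "C"))
  # planted sites all exist in the simulated proteome
  expect_true(all(pr$truth$reactivity$site_id %in% pr$truth$sites$site_id))
  expect_true(all(pr$truth$atp$site_id %in% pr$truth$sites$site_id))
})

test_that("null model at zero noise gives exactly zero ratios", {
  cfg <- quick_config(
    seed = 2, noise_sd_log2 = 0, donor_sd_log2 = 0, missing_rate = 0,
    planted_expression = list(fraction = 0, effect_log2 = 0),
    planted_reactivity = list(fraction = 0, effect_log2 = 0),
    planted_atp = list(fraction = 0, effect_log2 = 0, state_specific = TRUE)
  )
  pr <- simulate_proteome(cfg)
  ex <- simulate_experiment(cfg, pr)
  nrm <- normalize_channels(ex$enriched, ex$layout)
  cr <- condition_ratios(nrm, ex$layout)
  expect_lt(max(abs(cr$log2_ratio)), 1e-9)
})

test_that("a single planted reactivity effect propagates exactly", {
  cfg <- quick_config(
    seed = 4, noise_sd_log2 = 0, donor_sd_log2 = 0, missing_rate = 0,
    planted_expression = list(fraction = 0, effect_log2 = 0),
    planted_reactivity = list(fraction = 0, effect_log2 = 0),
    planted_atp = list(fraction = 0, effect_log2 = 0, state_specific = TRUE)
  )
  pr <- simulate_proteome(cfg)
  # plant +2 log2 in D8C at one site, flat protein
  site <- pr$truth$sites[1, ]
  pr$truth$reactivity <- tibble(site_id = site$site_id,
                                accession = site$accession,
                                condition = "D8C", effect_log2 = 2)
  ex <- simulate_experiment(cfg, pr)
  s <- rollup_sites(condition_ratios(ex$enriched, ex$layout), pr$database)
  p <- rollup_proteins(condition_ratios(ex$unenriched, ex$layout))
  hit <- s[s$site_id == site$site_id & s$condition == "D8C", ]
  expect_equal(hit$log2_ratio, rep(2, nrow(hit)), tolerance = 1e-12)
  prot <- p[p$accession == site$accession & p$condition == "D8C", ]
  expect_equal(prot$log2_ratio, rep(0, nrow(prot)), tolerance = 1e-12)
})

test_that("missingness hits the configured rate and tracks intensity", {
  cfg <- simulation_config(n_proteins = 120L, n_donors = 3L,
                           missing_rate = 0.3, seed = 7)
  pr <- simulate_proteome(cfg)
  ex <- simulate_experiment(cfg, pr)
  cells <- c(is.na(ex$enriched$intensity), is.na(ex$unenriched$intensity))
  expect_gt(length(cells), 10000L)
  expect_lt(abs(mean(cells) - 0.3), 0.02)
  # intensity dependence: missing cells sit at lower expected intensity
  lay <- ex$layout
  by_pep <- ex$enriched %>%
    group_by(accession, sequence) %>%
    summarise(mean_int = mean(intensity, na.rm = TRUE),
              miss = mean(is.na(intensity)), .groups = "drop")
  expect_lt(cor(log2(by_pep$mean_int), by_pep$miss), -0.2)
})

test_that("the add-back simulator plants occlusions exactly at zero noise", {
  cfg <- quick_config(
    seed = 6, noise_sd_log2 = 0, donor_sd_log2 = 0, missing_rate = 0,
    planted_expression = list(fraction = 0, effect_log2 = 0),
    planted_reactivity = list(fraction = 0, effect_log2 = 0),
    planted_atp = list(fraction = 0.1, effect_log2 = -2,
                       state_specific = TRUE)
  )
  pr <- simulate_proteome(cfg)
  ab <- simulate_atp_addback(cfg, pr)
  expect_equal(sum(ab$layout$plex_id == "ab_donor1"), 16L)
  lc <- call_ligand_sensitivity(ab$enriched, ab$layout, pr$database,
                                normalize = FALSE)
  occluded <- pr$truth$atp$site_id
  # non-occluded sites: control and ATP intensities identical
  clean <- lc[!lc$site_id %in% occluded, ]
  expect_lt(max(abs(clean$delta_log2)), 1e-9)
  # occluded, state-specific: delta -2 in D8C exactly, 0 in D2
  occ_d8c <- lc[lc$site_id %in% occluded & lc$state == "D8C", ]
  expect_equal(occ_d8c$delta_log2, rep(-2, nrow(occ_d8c)),
               tolerance = 1e-12)
  occ_d2 <- lc[lc$site_id %in% occluded & lc$state == "D2", ]
  expect_lt(max(abs(occ_d2$delta_log2)), 1e-9)
})

test_that("ATP occlusion is independent of annotation class at odds 1", {
  cfg <- simulation_config(n_proteins = 10000L, atp_class_odds = 1,
                           seed = 11)
  pr <- simulate_proteome(cfg)
  occluded <- pr$truth$proteins$accession %in% pr$truth$atp$accession
  in_class <- pr$truth$proteins$accession %in%
    pr$annotations$nucleotide_binding
  p <- chisq.test(table(occluded, in_class))$p.value
  expect_gt(p, 0.01)
})

test_that("feature-table effects live on the per-volume scale", {
  cfg <- quick_config(seed = 13, metab_noise_sd = 0,
                      metab_missing_rate = 0,
                      planted_metab = list(fraction = 0.1, effect_log2 = 1))
  sim <- simulate_feature_table(cfg)
  norm <- normalize_cell_volume(sim$table)
  lm2 <- log2(norm$values)
  truth <- sim$truth[sim$truth$condition == "D8C", ]
  a <- norm$samples$sample_id[norm$samples$condition == "D8C"]
  b <- norm$samples$sample_id[norm$samples$condition == "D2"]
  fc <- rowMeans(lm2[, a]) - rowMeans(lm2[, b])
  expect_equal(unname(fc[truth$feature_id]), truth$effect_log2,
               tolerance = 1e-9)
  null_feat <- setdiff(rownames(lm2), sim$truth$feature_id)
  expect_lt(max(abs(fc[null_feat])), 1e-9)
})

test_that("tracing observations are the convolved true distributions", {
  cfg <- quick_config(seed = 15)
  tr <- simulate_tracing(cfg, frac_noise_sd = 0)
  one <- tr$observed[tr$observed$metabolite == "fumarate" &
                       tr$observed$condition == "D2" &
                       tr$observed$donor == 1, ]
  truth <- tr$true_mids[tr$true_mids$metabolite == "fumarate" &
                          tr$true_mids$condition == "D2" &
                          tr$true_mids$donor == 1, ]
  m <- build_correction_matrix(tr$carbons[["fumarate"]], p_nat = tr$p_nat)
  mid <- correct_mid(one$intensity, m)
  expect_equal(as.numeric(mid), truth$fraction, tolerance = 1e-9)
})
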
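# Channel normalization, ratio formation, and site/protein rollup.

test_that("channel normalization equalizes totals with exact factors", {
  lay <- make_layout(conditions = "D2", reps = 2L)  # channels ch1, ch2
  mat <- rbind(c(400, 100), c(200, 200))
  colnames(mat) <- c("ch1", "ch2")
  rec <- make_records(mat, accession = c("P1", "P2"),
                      sequence = c("AAAK", "CCCR"))
  out <- normalize_channels(rec, lay)
  f <- attr(out, "norm_factors")
  # column sums (600, 300), mean 450 -> factors (0.75, 1.5)
  expect_equal(f$factor, c(0.75, 1.5))
  sums <- tapply(out$intensity, out$channel, sum)
  expect_equal(as.numeric(sums[c("ch1", "ch2")]), c(450, 450))

  # equal sums: identity
  mat2 <- rbind(c(100, 100), c(50, 50))
  colnames(mat2) <- c("ch1", "ch2")
  rec2 <- make_records(mat2, c("P1", "P2"), c("AAAK", "CCCR"))
  out2 <- normalize_channels(rec2, lay)
  expect_equal(out2$intensity, rec2$intensity)
  expect_equal(attr(out2, "norm_factors")$factor, c(1, 1))

  # idempotence
  twice <- normalize_channels(out, lay)
  expect_equal(twice$intensity, out$intensity)
})

test_that("normalization uses complete cases and flags zero channels", {
  lay <- make_layout(conditions = "D2", reps = 2L)
  # record P2 is missing in ch2 and must not bias the totals
  mat <- rbind(c(400, 100), c(999, NA), c(200, 200))
  colnames(mat) <- c("ch1", "ch2")
  rec <- make_records(mat, c("P1", "P2", "P3"), c("AAAK", "WWWR", "CCCR"))
  out <- normalize_channels(rec, lay)
  expect_equal(attr(out, "norm_factors")$factor, c(0.75, 1.5))
  # incomplete record is still rescaled
  expect_equal(out$intensity[out$accession == "P2" & out$channel == "ch1"],
               999 * 0.75)

  mat0 <- rbind(c(10, 0))
  colnames(mat0) <- c("ch1", "ch2")
  rec0 <- make_records(mat0, "P1", "AAAK")
  expect_error(normalize_channels(rec0, lay), "zero total")
})

test_that("condition ratios are exact and antisymmetric", {
  lay <- make_layout(conditions = c("D2", "D8C"), reps = 2L)
  mat <- rbind(c(100, 100, 400, 400))
  colnames(mat) <- paste0("ch", 1:4)
  rec <- make_records(mat, "P1", "AAAK")
  cr <- condition_ratios(rec, lay)
  expect_equal(cr$log2_ratio[cr$condition == "D8C"], 2)
  expect_equal(cr$log2_ratio[cr$condition == "D2"], 0)

  # all channels equal -> all ratios zero
  mat_eq <- rbind(rep(250, 4))
  colnames(mat_eq) <- paste0("ch", 1:4)
  cr_eq <- condition_ratios(make_records(mat_eq, "P1", "AAAK"), lay)
  expect_true(all(cr_eq$log2_ratio == 0))

  # swapping two conditions' intensities negates their relative difference
  lay3 <- make_layout(conditions = c("D2", "D4A", "D8C"), reps = 1L)
  m1 <- rbind(c(100, 800, 200)); colnames(m1) <- paste0("ch", 1:3)
  m2 <- rbind(c(100, 200, 800)); colnames(m2) <- paste0("ch", 1:3)
  r1 <- condition_ratios(make_records(m1, "P1", "AAAK"), lay3)
  r2 <- condition_ratios(make_records(m2, "P1", "AAAK"), lay3)
  d1 <- r1$log2_ratio[r1$condition == "D4A"] -
    r1$log2_ratio[r1$condition == "D8C"]
  d2 <- r2$log2_ratio[r2$condition == "D4A"] -
    r2$log2_ratio[r2$condition == "D8C"]
  expect_equal(d1, -d2)
})

test_that("records without an observed reference channel are dropped and counted", {
  lay <- make_layout(conditions = c("D2", "D8C"), reps = 1L)
  mat <- rbind(c(100, 200), c(NA, 300))
  colnames(mat) <- c("ch1", "ch2")
  rec <- make_records(mat, c("P1", "P2"), c("AAAK", "CCCR"))
  cr <- condition_ratios(rec, lay)
  expect_false("P2" %in% cr$accession)
  expect_equal(attr(cr, "dropped_records"), 1L)
})

test_that("site rollup assigns residues, medians, and composite ids", {
  db <- protein_db(c(P1 = "MKCATRCK"))
  ratios <- tibble(
    plex_id = "donor1", accession = "P1",
    sequence = c("CATR", "CATR", "CATR"),
    offsets = "1",
    condition = "D8C",
    log2_ratio = c(0.8, 1.2, 3.0)
  )
  # three distinct peptides supporting the same site
  ratios$sequence <- c("CATR", "KCATR", "CATRCK")
  ratios$offsets <- c("1", "2", "1")
  s <- rollup_sites(ratios[1, ], db)
  expect_equal(s$site_id, "P1_C3")
  expect_equal(s$residue, 3L)

  s3 <- rollup_sites(ratios, db)
  # all three peptide forms support C3: median of (0.8, 1.2, 3.0)
  expect_equal(s3$site_id, "P1_C3")
  expect_equal(s3$log2_ratio, 1.2)
  expect_equal(s3$n_peptides, 3L)
  expect_false(any(s3$composite))

  multi <- tibble(plex_id = "donor1", accession = "P1",
                  sequence = "CATRCK", offsets = "1;5",
                  condition = "D8C", log2_ratio = 1)
  sm <- rollup_sites(multi, db)
  expect_true(sm$composite)
  expect_equal(sm$site_id, "P1_C3_C7")
  expect_true(is.na(sm$residue))

  expect_error(
    rollup_sites(tibble(plex_id = "d", accession = "P1", sequence = "WWWW",
                        offsets = "1", condition = "D8C", log2_ratio = 0),
                 db),
    "not found"
  )
})

test_that("median rollup is order-invariant and bounded", {
  db <- protein_db(c(P1 = "MKCATRCK"))
  ratios <- tibble(
    plex_id = "donor1", accession = "P1",
    sequence = c("CATR", "KCATR", "CATRC"),
    offsets = c("1", "2", "1"),
    condition = "D8C",
    log2_ratio = c(0.8, 3.0, 1.2)
  )
  s_fwd <- rollup_sites(ratios, db)
  s_rev <- rollup_sites(ratios[3:1, ], db)
  expect_equal(s_fwd$log2_ratio, s_rev$log2_ratio)
  expect_true(all(s_fwd$log2_ratio >= min(ratios$log2_ratio) &
                    s_fwd$log2_ratio <= max(ratios$log2_ratio)))
  expect_equal(s_fwd$n_peptides, 3L)
})

test_that("only the elevated site of a multi-site protein crosses 200% of reference", {
  # chaperone-like fixture: three cysteine sites, only the middle one
  # (nucleotide-pocket analog) gains reactivity relative to the reference
  db <- protein_db(c(HS = paste0("MK", "CAAAAR", "WWWK", "ACAAWR", "YYYK",
                                 "AACAFR")))
  lay <- make_layout(conditions = c("D2", "D8C"), reps = 2L)
  peps <- tibble(
    accession = "HS",
    sequence = c("CAAAAR", "ACAAWR", "AACAFR"),
    offsets = c("1", "2", "3")
  )
  base <- c(1000, 800, 1200)
  d8c <- base * c(1, 5, 1)  # only the middle site elevated
  mat <- cbind(ch1 = base, ch2 = base, ch3 = d8c, ch4 = d8c)
  rec <- make_records(mat, peps$accession, peps$sequence, peps$offsets,
                      enriched = TRUE)
  s <- rollup_sites(condition_ratios(rec, lay), db)
  d8c_vals <- s[s$condition == "D8C", ]
  over200 <- d8c_vals$site_id[d8c_vals$log2_ratio > 1]
  expect_equal(over200, "HS_C14")
  expect_length(over200, 1L)
})

test_that("protein rollup medians peptides and records support", {
  ratios <- tibble(
    plex_id = "donor1", accession = c("P1", "P2", "P2", "P2"),
    sequence = c("AAAK", "WWWR", "YYYK", "FFFR"), offsets = "",
    condition = "D8C", log2_ratio = c(0.7, 1.0, 2.0, 5.0)
  )
  p <- rollup_proteins(ratios)
  expect_equal(p$log2_ratio[p$accession == "P1"], 0.7)
  expect_equal(p$log2_ratio[p$accession == "P2"], 2.0)
  expect_equal(p$n_peptides[p$accession == "P2"][1], 3L)
  p_perm <- rollup_proteins(ratios[sample(4), ])
  expect_equal(arrange(p, accession), arrange(p_perm, accession))
})

test_that("cross-donor medians resist single-donor corruption", {
  vals <- tibble(
    site_id = "P1_C3", accession = "P1", residue = 3L, composite = FALSE,
    condition = "D8C", donor = paste0("donor", 1:5),
    log2_ratio = c(1, 1, 1, 1, 6), n_peptides = 2L
  )
  s <- make_site_quant(vals,
                       cys_peptides = tibble(accession = "P1",
                                             n_cys_peptides = 2L))
  p <- make_protein_quant(tibble(accession = "P1", condition = "D8C",
                                 donor = paste0("donor", 1:5),
                                 log2_ratio = 0))
  calls <- call_reactivity(s, p)
  expect_equal(calls$raw_log2fc, 1)  # corrupted donor ignored by the median
  vals2 <- mutate(vals, log2_ratio = c(1, 1, 1, 1, -4))
  calls2 <- call_reactivity(make_site_quant(vals2,
    cys_peptides = tibble(accession = "P1", n_cys_peptides = 2L)), p)
  expect_equal(calls2$raw_log2fc, 1)
})

test_that("site-set intersection reports shared and exclusive counts", {
  a <- tibble(site_id = c("P1_C3", "P2_C5", "P3_C9"))
  b <- tibble(site_id = c("P2_C5", "P3_C9", "P4_C1"))
  res <- intersect_sites(a, b)
  expect_equal(res$counts$n_both, 2L)
  expect_equal(res$counts$n_a_only, 1L)
  expect_equal(res$counts$n_b_only, 1L)
  expect_equal(res$counts$n_both + res$counts$n_a_only, res$counts$n_a)

  disjoint <- intersect_sites(a, tibble(site_id = "P9_C9"))
  expect_equal(nrow(disjoint$both), 0L)
  full <- intersect_sites(a, a)
  expect_equal(full$counts$n_both, 3L)
  expect_equal(full$counts$n_a_only, 0L)
})

test_that("normalized channel totals agree to 1e-9 on noisy simulated data", {
  cfg <- quick_config(seed = 42)
  pr <- simulate_proteome(cfg)
  ex <- simulate_experiment(cfg, pr)
  nrm <- normalize_channels(ex$enriched, ex$layout)
  for (px in unique(ex$layout$plex_id)) {
    chans <- ex$layout$channel[ex$layout$plex_id == px]
    sub <- nrm[nrm$plex_id == px, ]
    obs <- sub %>%
      group_by(accession, sequence, offsets) %>%
      summarise(n_obs = sum(!is.na(intensity)), .groups = "drop") %>%
      filter(n_obs == length(chans))
    tot <- sub %>%
      semi_join(obs, by = c("accession", "sequence", "offsets")) %>%
      group_by(channel) %>%
      summarise(total = sum(intensity), .groups = "drop")
    expect_lt(diff(range(tot$total)) / mean(tot$total), 1e-9)
  }
})
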
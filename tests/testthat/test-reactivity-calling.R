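# Evidence-tiered reactivity calling: rule examples, tiers, baselines,
# monotonicity, and equivalence with a literal reference implementation.

one_site <- function(raw, acc = "P1", n_cys = 3L, site = "P1_C3",
                     cond = "D8C") {
  make_site_quant(
    tibble(site_id = site, accession = acc, residue = 3L, composite = FALSE,
           condition = cond, donor = "donor1", log2_ratio = raw,
           n_peptides = 1L),
    cys_peptides = tibble(accession = acc, n_cys_peptides = n_cys)
  )
}

flat_protein <- function(acc = "P1", fc = 0, cond = "D8C") {
  make_protein_quant(tibble(accession = acc, condition = cond,
                            donor = "donor1", log2_ratio = fc))
}

test_that("the calling rule reproduces its defining examples", {
  # raw 0 -> no_change
  c0 <- call_reactivity(one_site(0), flat_protein())
  expect_equal(c0$verdict, "no_change")

  # raw +1.5, flat protein, 3 cysteine peptides -> higher reactivity change
  c1 <- call_reactivity(one_site(1.5), flat_protein())
  expect_equal(c1$verdict, "reactivity_change")
  expect_equal(c1$direction, "higher")
  expect_equal(c1$evidence_tier, "multi_peptide")
  expect_equal(c1$corrected_log2fc, 1.5)

  # raw +1.5 on a protein itself up 1.4-fold(log2) -> expression coupled
  c2 <- call_reactivity(one_site(1.5), flat_protein(fc = 1.4))
  expect_equal(c2$verdict, "expression_coupled")
  expect_equal(c2$corrected_log2fc, 0.1)

  # single-cysteine protein without unenriched match -> insufficient
  c3 <- call_reactivity(one_site(2, n_cys = 1L), proteins = NULL)
  expect_equal(c3$verdict, "insufficient_evidence")
  expect_true(is.na(c3$evidence_tier))

  # single peptide *with* matching proteome data is callable
  c4 <- call_reactivity(one_site(2, n_cys = 1L), flat_protein())
  expect_equal(c4$verdict, "reactivity_change")
  expect_equal(c4$evidence_tier, "single_peptide_with_proteome")
})

test_that("lower reactivity is called symmetrically", {
  c1 <- call_reactivity(one_site(-1.5), flat_protein())
  expect_equal(c1$verdict, "reactivity_change")
  expect_equal(c1$direction, "lower")
})

test_that("leave-one-out baseline excludes the site itself and needs two others", {
  sq <- make_site_quant(
    tibble(site_id = c("P1_C3", "P1_C9", "P1_C20"), accession = "P1",
           residue = c(3L, 9L, 20L), composite = FALSE, condition = "D8C",
           donor = "donor1", log2_ratio = c(2.0, 0.1, -0.1),
           n_peptides = 1L),
    cys_peptides = tibble(accession = "P1", n_cys_peptides = 3L)
  )
  calls <- call_reactivity(sq, proteins = NULL)
  hit <- calls[calls$site_id == "P1_C3", ]
  expect_equal(hit$baseline_source, "median_cysteine")
  expect_equal(hit$baseline_log2fc, 0)  # median of the other two sites
  expect_equal(hit$verdict, "reactivity_change")

  # a single-cysteine protein can never self-reference
  sq1 <- one_site(2, n_cys = 2L)
  calls1 <- call_reactivity(sq1, proteins = NULL,
                            params = call_params(baseline_mode =
                                                   "median_cysteine"))
  expect_equal(calls1$verdict, "insufficient_evidence")
  expect_equal(calls1$baseline_source, "none")

  # two sites only: leave-one-out leaves a single other site -> no baseline
  sq2 <- make_site_quant(
    tibble(site_id = c("P1_C3", "P1_C9"), accession = "P1",
           residue = c(3L, 9L), composite = FALSE, condition = "D8C",
           donor = "donor1", log2_ratio = c(2, 0), n_peptides = 1L),
    cys_peptides = tibble(accession = "P1", n_cys_peptides = 2L)
  )
  calls2 <- call_reactivity(sq2, proteins = NULL)
  expect_true(all(calls2$verdict == "insufficient_evidence"))
})

test_that("raising the fold threshold never adds a reactivity change", {
  cfg <- quick_config(seed = 21)
  pr <- simulate_proteome(cfg)
  ex <- simulate_experiment(cfg, pr)
  s <- rollup_sites(condition_ratios(normalize_channels(ex$enriched,
                                                        ex$layout),
                                     ex$layout), pr$database)
  p <- rollup_proteins(condition_ratios(normalize_channels(ex$unenriched,
                                                           ex$layout),
                                        ex$layout))
  key <- function(calls) {
    hits <- calls[calls$verdict == "reactivity_change", ]
    paste(hits$site_id, hits$condition)
  }
  sets <- lapply(c(2, 3, 4), function(th) {
    key(call_reactivity(s, p, call_params(fc_threshold = th)))
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("calling matches a literal reference implementation on a full run", {
  cfg <- simulation_config(n_proteins = 150L, n_donors = 3L, seed = 23)
  pr <- simulate_proteome(cfg)
  ex <- simulate_experiment(cfg, pr)
  s <- rollup_sites(condition_ratios(normalize_channels(ex$enriched,
                                                        ex$layout),
                                     ex$layout), pr$database)
  p <- rollup_proteins(condition_ratios(normalize_channels(ex$unenriched,
                                                           ex$layout),
                                        ex$layout))
  got <- call_reactivity(s, p) %>%
    select(site_id, condition, raw_log2fc, verdict, direction,
           evidence_tier) %>%
    arrange(site_id, condition)
  want <- reference_reactivity_calls(s, p) %>%
    arrange(site_id, condition)
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
})

test_that("empty inputs abort while empty call summaries count zeros", {
  expect_error(call_reactivity(tibble(), NULL), "empty")
  calls <- call_reactivity(one_site(0.1), flat_protein())
  summ <- summarize_calls(calls)
  expect_true(all(summ$n == 0L))
})

test_that("call summaries count directions and respect class splits", {
  calls <- structure(
    tibble(
      site_id = paste0("P", 1:5, "_C3"),
      accession = paste0("P", 1:5),
      condition = "D8C",
      raw_log2fc = c(2, 1.5, 1.2, -1.8, -1.1),
      verdict = "reactivity_change",
      direction = c("higher", "higher", "higher", "lower", "lower")
    ),
    class = c("reactivity_calls", class(tibble()))
  )
  summ <- summarize_calls(calls)
  expect_equal(summ$n[summ$direction == "higher"], 3L)
  expect_equal(summ$n[summ$direction == "lower"], 2L)
  expect_equal(sum(summ$n), 5L)

  # classes that partition the proteome conserve the totals
  ann <- annotation_set(list(a = c("P1", "P2"), b = c("P3", "P4", "P5")))
  summ2 <- summarize_calls(calls, ann)
  split_total <- sum(summ2$n[summ2$class != "all"])
  expect_equal(split_total, sum(summ2$n[summ2$class == "all"]))
})
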
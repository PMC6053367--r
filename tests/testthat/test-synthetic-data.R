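test_that("cohort simulation respects the configured range and is deterministic", {
  cfg <- sim_config(n_individuals = 100, age_range = c(20, 70), seed = 1)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 100)
  expect_true(all(co$age >= 20 & co$age <= 70))
  expect_true(all(co$gender %in% c(0L, 1L)))
  expect_false(anyDuplicated(co$donor_id) > 0)
  expect_identical(co, simulate_cohort(cfg))

  # law of large numbers: uniform mean is the midpoint
  big <- simulate_cohort(sim_config(n_individuals = 10000, seed = 7))
  expect_lt(abs(mean(big$age) - 45), 1)
})

test_that("sim_config rejects invalid fields", {
  expect_error(sim_config(age_range = c(70, 20)), "age_range")
  expect_error(sim_config(frac_age_assoc = 1.5), "frac_age_assoc")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_events = 0), "n_events")
  expect_error(sim_config(planted_driver = list(motif_id = "M_PTBP1",
                                                region = "nowhere",
                                                trend_class = "up")),
               "region")
})

test_that("PSI matrices satisfy the generative contract", {
  w <- small_world(seed = 2, frac = 0.2, missing_rate = 0.1)
  vals <- w$psi[w$psi != -1]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(sum(w$psi == -1) / length(w$psi), 0.1, tolerance = 0.15)
  # truth bookkeeping: exactly round(frac * n_events) flagged events
  expect_equal(sum(w$truth$events$is_age_assoc), round(0.2 * 150))
  expect_true(all(w$truth$events$trend_class[w$truth$events$beta_age > 0] == "up"))
  expect_true(all(w$truth$events$trend_class[w$truth$events$beta_age < 0] == "down"))
  # determinism
  w2 <- small_world(seed = 2, frac = 0.2, missing_rate = 0.1)
  expect_identical(w$psi, w2$psi)
})

test_that("degenerate PSI model is constant; strong effects are monotone in age", {
  cfg <- sim_config(n_individuals = 50, n_events = 20, frac_age_assoc = 0,
                    noise_sd = 0, n_hidden_factors = 0, missing_rate = 0,
                    gender_effect_sd = 0, seed = 3)
  co <- simulate_cohort(cfg)
  ps <- simulate_psi(co, cfg)
  expect_true(all(apply(ps$psi, 1, sd) < 1e-12))

  cfg2 <- sim_config(n_individuals = 80, n_events = 40, frac_age_assoc = 0.5,
                     effect_size = 0.05, noise_sd = 0, n_hidden_factors = 0,
                     missing_rate = 0, gender_effect_sd = 0, seed = 4)
  co2 <- simulate_cohort(cfg2)
  ps2 <- simulate_psi(co2, cfg2)
  fl <- which(ps2$truth$events$is_age_assoc)
  cors <- vapply(fl, function(i) cor(ps2$psi[i, ], co2$age), numeric(1))
  expect_equal(sign(cors), sign(ps2$truth$events$beta_age[fl]))
})

test_that("gene-level dropout masks whole genes per sample", {
  w <- small_world(seed = 5, missing_rate = 0, gene_dropout_rate = 0.2,
                   n_genes = 20)
  gene <- w$truth$events$gene_id
  for (j in sample(ncol(w$psi), 5)) {
    miss_genes <- unique(gene[w$psi[, j] == -1])
    for (g in miss_genes) {
      expect_true(all(w$psi[gene == g, j] == -1))
    }
  }
})

test_that("gene expression equals the sum of its transcripts exactly", {
  cfg <- sim_config(n_individuals = 60, n_genes = 30, seed = 6)
  co <- simulate_cohort(cfg)
  ex <- simulate_expression(co, cfg)
  for (g in rownames(ex$gene)) {
    tx_rows <- names(ex$tx2gene)[ex$tx2gene == g]
    expect_equal(ex$gene[g, ],
                 colSums(ex$transcript[tx_rows, , drop = FALSE]))
  }
})

test_that("isoform-switch genes move transcripts but not gene totals", {
  cfg <- sim_config(n_individuals = 200, n_genes = 40, frac_gene_assoc = 0,
                    frac_ratio_assoc = 0.25, expr_noise_sd = 0.1, seed = 7)
  co <- simulate_cohort(cfg)
  ex <- simulate_expression(co, cfg)
  sw <- ex$truth$genes$gene_id[ex$truth$genes$is_ratio_switch]
  expect_true(length(sw) == 10)
  # gene totals of switch genes carry no age trend
  g_cor <- vapply(sw, function(g) abs(cor(log(ex$gene[g, ]), co$age)),
                  numeric(1))
  # switching transcripts do
  tx1 <- paste0(sw, ".T1")
  t_cor <- vapply(tx1, function(tx) abs(cor(log(ex$transcript[tx, ]), co$age)),
                  numeric(1))
  expect_gt(mean(t_cor), mean(g_cor) + 0.3)
})

test_that("region simulation plants the driver motif where configured", {
  cfg <- sim_config(n_individuals = 60, n_events = 300, frac_age_assoc = 0.3,
                    seed = 8)
  co <- simulate_cohort(cfg)
  ps <- simulate_psi(co, cfg)
  rs <- simulate_regions_and_sf(ps$truth, co, cfg)
  expect_setequal(unique(rs$regions$region), region_names())
  se <- ps$truth$events[ps$truth$events$type == "SE", ]
  expect_equal(sort(unique(rs$regions$event_id)), sort(se$event_id))

  # planted motif count is elevated in the up-class target region only
  target <- rs$regions[rs$regions$region == "upstream_intron_3p", ]
  cnt <- count_iupac(target$seq, "YTCYCY")
  cls <- se$trend_class[match(target$event_id, se$event_id)]
  expect_gt(mean(cnt[cls == "up"]), mean(cnt[cls == "stable"]) + 1)
  # decoy at background rate everywhere
  cnt_d <- count_iupac(target$seq, "TGCATG")
  expect_lt(abs(mean(cnt_d[cls == "up"]) - mean(cnt_d[cls == "stable"])), 1)

  # driver SF expression declines with age (noiseless check via large n)
  sf_fit <- lm(log(rs$sf_expr["PTBP1", ]) ~ co$age)
  expect_lt(coef(sf_fit)[2], 0)
})

test_that("null planting (no driver) gives no class differences", {
  cfg <- sim_config(n_individuals = 60, n_events = 200, frac_age_assoc = 0.3,
                    planted_driver = NULL, seed = 9)
  co <- simulate_cohort(cfg)
  ps <- simulate_psi(co, cfg)
  rs <- simulate_regions_and_sf(ps$truth, co, cfg)
  se <- ps$truth$events[ps$truth$events$type == "SE", ]
  target <- rs$regions[rs$regions$region == "upstream_intron_3p", ]
  cnt <- count_iupac(target$seq, "YTCYCY")
  cls <- se$trend_class[match(target$event_id, se$event_id)]
  expect_gt(suppressWarnings(wilcox.test(cnt[cls == "up"],
                                         cnt[cls == "stable"])$p.value),
            0.01)
})

test_that("disease generator obeys its null and prevalence contracts", {
  # all coefficients zero: prevalence ~ 0.5
  cfg <- sim_config(n_individuals = 2000, n_events = 50, n_genes = 20,
                    disease_effect = 0,
                    disease_coefs = list(intercept = 0, age = 0, gender = 0,
                                         expr = 0),
                    seed = 10)
  co <- simulate_cohort(cfg)
  ps <- simulate_psi(co, cfg)
  ex <- simulate_expression(co, cfg)
  d <- simulate_disease(co, ps$psi, ex$gene, cfg)
  expect_equal(mean(d), 0.5, tolerance = 0.05)

  # strong PSI effect detectable by an exact 2x2 test at the median split
  cfg2 <- sim_config(n_individuals = 500, n_events = 80, n_genes = 20,
                     disease_effect = 2, seed = 11)
  co2 <- simulate_cohort(cfg2)
  ps2 <- simulate_psi(co2, cfg2)
  ex2 <- simulate_expression(co2, cfg2)
  d2 <- simulate_disease(co2, ps2$psi, ex2$gene, cfg2)
  comp <- attr(d2, "linpred")
  psi_pc <- spliceage:::pc_scores(spliceage:::impute_sentinels(ps2$psi), 1)[, 1]
  tab <- table(psi_pc > median(psi_pc), d2)
  expect_lt(fisher.test(tab)$p.value, 1e-4)
})
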
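test_that("ground truth is seed-deterministic and well shaped", {
  cfg <- sim_config(seed = 11, n_compounds = 12)
  t1 <- sample_truth(cfg)
  t2 <- sample_truth(cfg)
  expect_identical(t1, t2)
  expect_equal(dim(t1$true_pki), c(12, 26))
  expect_equal(colnames(t1$true_pki), KINASE_PANEL_26)
  expect_true(all(t1$true_hill == 1))
  t3 <- sample_truth(sim_config(seed = 12, n_compounds = 12))
  expect_false(identical(t1$true_pki, t3$true_pki))
  expect_error(sim_config(), class = "fragscreen_input_error")
  expect_error(sim_config(seed = 1, archetype_mix = c(promiscuous = 1,
                                                      selective = 1,
                                                      inactive = 0)),
               class = "fragscreen_input_error")
})

test_that("archetypes draw from their stated pKi distributions", {
  cfg <- sim_config(seed = 5, n_compounds = 60,
                    archetype_mix = c(promiscuous = 1, selective = 0,
                                      inactive = 0))
  tr <- sample_truth(cfg)
  mu <- mean(tr$true_pki)
  se <- 0.5 / sqrt(length(tr$true_pki))
  expect_lt(abs(mu - 5.0), 3 * se)

  cfg2 <- sim_config(seed = 5, n_compounds = 40,
                     archetype_mix = c(promiscuous = 0, selective = 0,
                                       inactive = 1))
  tr2 <- sample_truth(cfg2)
  expect_lt(abs(mean(tr2$true_pki) - 2.5), 3 * 0.3 / sqrt(length(tr2$true_pki)))
  # inactive library: expected S(50%) from the analytic forward model < 0.1
  ic50 <- 2 * 10^(6 - tr2$true_pki)     # ATP = Km doubles the IC50
  exp_inh <- 100 / (1 + ic50 / 100)
  expect_true(all(rowMeans(exp_inh > 50) < 0.1))

  cfg3 <- sim_config(seed = 9, n_compounds = 30,
                     archetype_mix = c(promiscuous = 0, selective = 1,
                                       inactive = 0))
  tr3 <- sample_truth(cfg3)
  # boosted targets stand out on average: row max sits ~1.5 pKi units
  # above the weak baseline the row median tracks
  gap <- apply(tr3$true_pki, 1, max) - apply(tr3$true_pki, 1, stats::median)
  expect_gt(mean(gap), 1)
  expect_lt(abs(mean(apply(tr3$true_pki, 1, stats::median)) - 3), 0.3)
})

test_that("noiseless forward screen equals the analytic response exactly", {
  cfg <- sim_config(seed = 3, n_compounds = 6, noise_sd_single_point = 0,
                    dropout = 0)
  tr <- sample_truth(cfg)
  # pin one cell: pKi 4 -> Ki 100 uM; at [ATP]=0 the IC50 equals Ki and a
  # 100 uM screen sits exactly at its midpoint
  tr$true_pki[1, 1] <- 4
  tr0 <- tr
  tr0$assay_conditions$atp_conc_uM[] <- 0
  expect_equal(forward_screen(tr0)$inhibition[1, 1], 50)
  # at ATP = Km the IC50 doubles: 100/(1+2)
  expect_equal(forward_screen(tr)$inhibition[1, 1], 100 / 3, tolerance = 1e-9)
  # whole matrix matches single_point_inhibition applied to the truth
  prof <- forward_screen(tr)
  ic50 <- 2 * 10^(6 - tr$true_pki)
  expect_equal(prof$inhibition,
               matrix(single_point_inhibition(ic50, 100), nrow(ic50),
                      dimnames = dimnames(ic50)))
})

test_that("noiseless selectivity from the screen equals analytic truth", {
  cfg <- sim_config(seed = 21, n_compounds = 15, noise_sd_single_point = 0,
                    dropout = 0)
  tr <- sample_truth(cfg)
  prof <- forward_screen(tr)
  ic50 <- 2 * 10^(6 - tr$true_pki)
  analytic <- rowMeans(100 / (1 + ic50 / 100) > 50)
  for (cid in rownames(tr$true_pki)) {
    expect_equal(s_compound(prof, cid)$score, unname(analytic[cid]))
  }
})

test_that("promiscuous screens look like the promiscuous fragment profile", {
  # library-average S(50%) for the promiscuous archetype lands near the
  # non-selective fragment benchmark 0.77 (within 0.15)
  scores <- unlist(lapply(1:12, function(s) {
    cfg <- sim_config(seed = s, n_compounds = 6, dropout = 0,
                      archetype_mix = c(promiscuous = 1, selective = 0,
                                        inactive = 0))
    tab <- selectivity_table(forward_screen(sample_truth(cfg)), 50)
    tab$score[tab$subject_type == "compound"]
  }))
  expect_lt(abs(mean(scores) - 0.77), 0.15)
})

test_that("selective archetype screens score like the selective fragment", {
  scores <- unlist(lapply(1:12, function(s) {
    cfg <- sim_config(seed = s, n_compounds = 6, dropout = 0,
                      archetype_mix = c(promiscuous = 0, selective = 1,
                                        inactive = 0))
    tab <- selectivity_table(forward_screen(sample_truth(cfg)), 50)
    tab$score[tab$subject_type == "compound"]
  }))
  # 1-3 boosted targets over 26 kinases: S(50%) ~ 0.04-0.12
  expect_lt(abs(mean(scores) - 0.08), 0.06)
})

test_that("forward curves are reproducible and recover truth when clean", {
  cfg <- sim_config(seed = 17, n_compounds = 8, noise_sd_curve = 0)
  tr <- sample_truth(cfg)
  sub <- data.frame(compound_id = "C01", kinase_id = "MPS1")
  cv1 <- forward_curves(tr, sub)
  cv2 <- forward_curves(tr, sub)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1), 8 * 3)
  f <- fit_4pl(cv1$conc_uM, cv1$response_pct)
  true_ic50 <- 2 * 10^(6 - tr$true_pki["C01", "MPS1"])
  if (!f$censored) expect_lt(abs(f$ic50 - true_ic50) / true_ic50, 1e-6)
  expect_error(forward_curves(tr, data.frame(compound_id = "zz",
                                             kinase_id = "MPS1")),
               class = "fragscreen_input_error")
})

test_that("generator calls leave the caller's RNG stream untouched", {
  set.seed(404)
  before <- .Random.seed
  invisible(sample_truth(sim_config(seed = 1, n_compounds = 4)))
  expect_identical(.Random.seed, before)
  draw1 <- rnorm(1)
  set.seed(404)
  invisible(rnorm(0))
  expect_equal(rnorm(1), draw1)
})

test_that("generate -> fit -> Cheng-Prusoff recovers pKi within tolerance", {
  # fast recovery check at reduced scale; the full 200-pair version is the
  # acceptance run
  cfg <- sim_config(seed = 71, n_compounds = 20)
  tr <- sample_truth(cfg)
  curves <- forward_curves(tr)
  keep <- unique(curves[c("compound_id", "kinase_id")])
  keep <- keep[seq_len(min(40, nrow(keep))), ]
  curves <- merge(curves, keep)
  fits <- fit_4pl_table(curves)
  fits <- fits[fits$converged & !fits$censored, ]
  ki <- cheng_prusoff_ki(fits$ic50_uM,
                         atp_conc = cfg$km_atp, km_atp = cfg$km_atp)
  dpki <- pki(ki) - tr$true_pki[cbind(fits$compound_id, fits$kinase_id)]
  expect_gt(length(dpki), 25)
  expect_lt(median(abs(dpki)), 0.05)
  expect_lt(abs(mean(dpki)), 0.05)
})
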
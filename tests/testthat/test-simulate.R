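test_that("simulated study has the declared shape and is seed-deterministic", {
  sp <- sim_spec(seed = 5)
  sim <- simulate_timecourse(sp)
  expect_equal(dim(sim$metab), c(273L, 30L))   # 273 analytes x 5 times x 6 reps
  expect_equal(dim(sim$trans), c(2869L, 10L))  # differential transcripts x 5 x 2
  expect_equal(sum(!is.na(sim$truth$trans$cluster)), 2869L)
  # null probes can fill the chip to full scale
  sp_chip <- sim_spec(seed = 5, n_trans_null = 34724L)
  expect_equal(sp_chip$n_trans + sp_chip$n_trans_null, 37593L)
  tab <- table(sim$truth$metab$class)
  expect_equal(as.integer(tab[c("AA", "AR", "eFA", "fFA", "OA", "SGD",
                                "ST", "UK")]),
               c(31, 7, 12, 12, 15, 41, 30, 125))
  sim2 <- simulate_timecourse(sim_spec(seed = 5))
  expect_identical(sim$metab$values, sim2$metab$values)
  expect_identical(sim$trans$values, sim2$trans$values)
  sim3 <- simulate_timecourse(sim_spec(seed = 6))
  expect_false(identical(sim$metab$values, sim3$metab$values))
})

test_that("all-null, noise-free simulations are flat", {
  sp <- sim_spec(seed = 2, n_metab = 10, class_counts = c(UK = 10L),
                 n_trans = 10, n_trans_null = 0L, noise_sd = 1e-9, frac_null = 1)
  sim <- simulate_timecourse(sp)
  rng <- apply(log(sim$metab$values), 1L, function(v) diff(range(v)))
  expect_lt(max(rng), 1e-6)
  expect_true(all(is.na(sim$truth$metab$cluster)))
})

test_that("spec validation rejects inconsistent settings", {
  expect_error(sim_spec(class_counts = c(UK = 10L), n_metab = 20),
               "class_counts")
  expect_error(sim_spec(k_metab = 1), ">= 2")
  expect_error(sim_spec(noise_sd = 0), "noise_sd")
})

test_that("planted categories are cluster-concentrated; background is uniform", {
  sim <- simulate_timecourse(sim_spec(seed = 9, n_metab = 10,
                                      class_counts = c(UK = 10L),
                                      n_trans = 400, n_trans_null = 0L, k_trans = 4))
  cat_ <- simulate_catalogs(sim$truth, n_categories = 10,
                            enriched_fraction = 0.5)
  expect_equal(sum(cat_$enriched), 5L)
  expect_true(all(cat_$n_members >= 2L))
  cl <- sim$truth$trans$cluster
  frac_in <- vapply(seq_len(nrow(cat_)), function(i) {
    m <- cat_$members[[i]]
    mean(cl[m] == cat_$target_cluster[i], na.rm = TRUE)
  }, 0)
  expect_true(all(frac_in[cat_$enriched] >= 0.8))
  # background categories: in-cluster overlap near the hypergeometric
  # expectation (cluster size / universe), far below the planted level
  expect_lt(max(vapply(cat_$members[!cat_$enriched], function(m)
    max(table(factor(cl[m], levels = 1:4))) / length(m), 0)), 0.8)
})

test_that("promoter planting respects rates and determinism", {
  sim <- simulate_timecourse(sim_spec(seed = 4, n_metab = 10,
                                      class_counts = c(UK = 10L),
                                      n_trans = 400, n_trans_null = 0L, k_trans = 4))
  motifs <- data.frame(motif_name = "TGBOXATPIN2", iupac = "AACGTG")
  pro <- simulate_promoters(sim$truth, motifs, motif_targets = 1L,
                            planted_rate = 1, background_rate = 0,
                            len = 300, seed = 21)
  hits <- scan_motif(pro, "AACGTG")
  cl <- sim$truth$trans$cluster[hits$gene_id]
  expect_true(all(hits$present[cl == 1]))  # every target promoter carries it
  # off-target promoters may still match by chance; compare to the binomial
  # expectation for a 6-mer on both strands of 300 bp
  p_chance <- 1 - (1 - 2 * (1 / 4)^6)^295
  off <- mean(hits$present[cl != 1])
  expect_lt(off, p_chance + 3 * sqrt(p_chance / sum(cl != 1)) + 0.02)
  pro2 <- simulate_promoters(sim$truth, motifs, motif_targets = 1L,
                             planted_rate = 1, background_rate = 0,
                             len = 300, seed = 21)
  expect_identical(as.character(pro), as.character(pro2))

  # empirical in-cluster planting frequency matches the rate at n = 400
  pro3 <- simulate_promoters(sim$truth, motifs, motif_targets = 1L,
                             planted_rate = 0.5, background_rate = 0,
                             genes = names(cl)[cl == 1], len = 300, seed = 3)
  planted <- attr(pro3, "truth")$planted
  expect_lt(abs(mean(planted) - 0.5), 3 * sqrt(0.25 / length(planted)))
})

test_that("planted correlations are realized exactly on time-point means", {
  sim <- simulate_timecourse(sim_spec(seed = 8, n_metab = 20,
                                      class_counts = c(UK = 20L), n_trans = 50, n_trans_null = 0L))
  mid <- feature_ids(sim$metab)[1]; tid <- feature_ids(sim$trans)[1]
  other <- feature_ids(sim$trans)[2]
  tmean <- function(x, id) tapply(log(x$values[id, ]), x$design$time, mean)
  for (r in c(1, 0.86, 0)) {
    tr2 <- plant_correlation(sim$metab, sim$trans,
                             data.frame(metab_id = mid, trans_id = tid,
                                        target_r = r), seed = 13)
    realized <- cor(tmean(sim$metab, mid), tmean(tr2, tid))
    expect_equal(realized, r, tolerance = 1e-8)
  }
  # untouched transcripts are untouched
  tr2 <- plant_correlation(sim$metab, sim$trans,
                           data.frame(metab_id = mid, trans_id = tid,
                                      target_r = 0.9), seed = 13)
  expect_identical(tr2$values[other, ], sim$trans$values[other, ])
})
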
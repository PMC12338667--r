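test_that("configuration is validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_per_group = 1), class = "flickerstress_config_error")
  expect_error(sim_config(spine_mix = c(long_thin = 0.5, filopodia = 0.5,
                                        stubby = 0.1, mushroom = 0)),
               class = "flickerstress_config_error")
  expect_error(sim_config(frac_stress_de = 1.2),
               class = "flickerstress_config_error")
  expect_error(
    sim_config(behavior_effects = list(male = list(stress = c(tail_flick = -1)))),
    class = "flickerstress_config_error"
  )
  # reversal for a frequency no stressed group receives
  cfg <- sim_config(groups = data.frame(stress = c(FALSE, TRUE),
                                        frequency_hz = c("none", "none")),
                    reversal_fraction = c("10" = 0.3))
  expect_error(simulate_counts(cfg), class = "flickerstress_config_error")
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 11, n_genes = 150, n_per_group = 3, n_spines = 50)
  expect_identical(simulate_behavior(cfg), simulate_behavior(cfg))
  d1 <- simulate_counts(cfg, cell_types = "neuron", sexes = "male")
  d2 <- simulate_counts(cfg, cell_types = "neuron", sexes = "male")
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth, d2$truth)
  expect_identical(simulate_spines(cfg), simulate_spines(cfg))
  s1 <- simulate_skeleton(cfg)
  expect_identical(s1, simulate_skeleton(cfg))
  # SWC text round-trip is stable too
  p <- withr::local_tempfile(fileext = ".swc")
  write_swc(s1, p)
  txt1 <- readLines(p)
  write_swc(simulate_skeleton(cfg), p)
  expect_identical(txt1, readLines(p))
})

test_that("null behavior generator centers every group on the control mean", {
  null_eff <- list(male = list(), female = list())
  cfg <- sim_config(seed = 5, n_per_group = 1000, behavior_effects = null_eff)
  beh <- simulate_behavior(cfg)
  by_grp <- dplyr::summarise(
    dplyr::group_by(beh, sex, group, assay),
    m = mean(value), se = sd(value) / sqrt(dplyr::n()), .groups = "drop"
  )
  ctrl <- dplyr::filter(by_grp, group == "control")
  joined <- dplyr::left_join(dplyr::filter(by_grp, group != "control"),
                             dplyr::select(ctrl, sex, assay, m_ctrl = m),
                             by = c("sex", "assay"))
  # family-wise bound: 56 simultaneous mean comparisons, Bonferroni at 0.005
  zcrit <- qnorm(1 - 0.005 / (2 * nrow(joined)))
  expect_true(all(abs(joined$m - joined$m_ctrl) <
                    zcrit * sqrt(2) * joined$se))
})

test_that("zero dispersion gives Poisson-like counts (variance ~ mean)", {
  cfg <- sim_config(seed = 3, n_genes = 400, nb_dispersion = 0, nb_mean = 100,
                    frac_stress_de = 0, n_samples_per_group = 50,
                    reversal_fraction = numeric(0),
                    groups = data.frame(stress = FALSE, frequency_hz = "none"))
  ds <- simulate_counts(cfg, cell_types = "neuron", sexes = "male")
  z <- sweep(ds$counts, 2, ds$samples$true_size_factor, "/")
  ratio <- apply(z, 1, var) / rowMeans(z)
  # index of dispersion concentrates near 1 for Poisson
  expect_lt(abs(mean(ratio) - 1), 0.05)
  # and strongly exceeds 1 when dispersion is planted
  cfg2 <- sim_config(seed = 3, n_genes = 400, nb_dispersion = 0.2, nb_mean = 100,
                     frac_stress_de = 0, n_samples_per_group = 50,
                     reversal_fraction = numeric(0),
                     groups = data.frame(stress = FALSE, frequency_hz = "none"))
  ds2 <- simulate_counts(cfg2, cell_types = "neuron", sexes = "male")
  z2 <- sweep(ds2$counts, 2, ds2$samples$true_size_factor, "/")
  expect_gt(mean(apply(z2, 1, var) / rowMeans(z2)), 5)
})

test_that("count truth table matches the planted design", {
  cfg <- sim_config(seed = 9, n_genes = 1000, frac_stress_de = 0.2,
                    frac_noncoding = 0.1,
                    reversal_fraction = c("10" = 0.4, "40" = 0.1))
  ds <- simulate_counts(cfg, cell_types = "astrocyte", sexes = "female")
  tr <- ds$truth
  n_coding <- sum(tr$biotype == "protein_coding")
  expect_equal(sum(tr$stress_de), round(0.2 * n_coding))
  expect_true(all(tr$biotype[tr$stress_de] == "protein_coding"))
  expect_equal(sum(tr$reversed_10hz), round(0.4 * sum(tr$stress_de)))
  expect_equal(sum(tr$reversed_40hz), round(0.1 * sum(tr$stress_de)))
  expect_true(all(tr$stress_de[tr$reversed_10hz]))
  expect_setequal(unique(abs(tr$planted_lfc[tr$stress_de])), cfg$planted_lfc)

  # zero DE fraction -> empty truth set
  cfg0 <- sim_config(seed = 9, n_genes = 200, frac_stress_de = 0,
                     reversal_fraction = numeric(0))
  expect_equal(sum(simulate_counts(cfg0, cell_types = "neuron",
                                   sexes = "male")$truth$stress_de), 0)
})

test_that("star skeletons have forced geometry", {
  cfg <- sim_config(morph_params = list(n_processes = 5, process_length = 15,
                                        kink_sd = 0))
  sk <- simulate_skeleton(cfg)
  prof <- sholl_crossings(sk, c(10, 20))
  expect_equal(prof$crossings, c(5L, 0L))
  expect_equal(arborization_length(sk), 5 * 15, tolerance = 1e-12)

  cfg0 <- sim_config(morph_params = list(n_processes = 0))
  expect_equal(arborization_length(simulate_skeleton(cfg0)), 0)
})

test_that("spine populations recover the planted class mixture", {
  cfg <- sim_config(seed = 21, n_spines = 200,
                    spine_mix = c(long_thin = 0, filopodia = 0, stubby = 0,
                                  mushroom = 1))
  sp <- classify_spines(simulate_spines(cfg))
  expect_gte(mean(sp$class == "mushroom"), 0.95)

  expect_equal(nrow(simulate_spines(sim_config(n_spines = 0))), 0)

  cfg2 <- sim_config(seed = 22, n_spines = 4000)
  sp2 <- classify_spines(simulate_spines(cfg2))
  props <- table(sp2$class) / nrow(sp2)
  # 99% binomial CI around 0.25 at n = 4000
  half <- 2.576 * sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(props - 0.25) < half))
  # recovered class equals the planted label for these parameters
  expect_equal(mean(as.character(sp2$class) == sp2$true_class), 1)
})
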
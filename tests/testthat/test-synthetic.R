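test_that("generators are deterministic given the seed", {
  d <- synthetic_design(n_taxa = 60, n_samples_per_group = 4, depth = 2000,
                        seed = 11)
  expect_identical(gen_paired_communities(d)$counts,
                   gen_paired_communities(d)$counts)
  expect_identical(gen_trait_reference(d), gen_trait_reference(d))
  fd <- forcing_design(n_days = 50, seed = 4)
  expect_identical(gen_forcing(fd, warmed = TRUE),
                   gen_forcing(fd, warmed = TRUE))
  pt1 <- gen_probe_table(50, groups = rep(c("WL", "CL"), each = 4), seed = 9)
  pt2 <- gen_probe_table(50, groups = rep(c("WL", "CL"), each = 4), seed = 9)
  expect_identical(pt1$intensity, pt2$intensity)
})

test_that("trait reference has the requested match structure", {
  d <- synthetic_design(n_taxa = 40, seed = 2)
  ref <- gen_trait_reference(d, match_fraction = 1, rrn_range = c(3, 3))
  expect_true(all(ref$matched))
  expect_true(all(ref$rrn_copies == 3))

  d2 <- synthetic_design(n_taxa = 10000, seed = 3)
  ref2 <- gen_trait_reference(d2, match_fraction = 0.2156)
  expect_identical(sum(ref2$matched), 2156L)
  expect_true(all(is.na(ref2$rrn_copies[!ref2$matched])))
  expect_true(all(ref2$rrn_copies[ref2$matched] >= 1))
})

test_that("null community design gives exchangeable groups", {
  d <- synthetic_design(n_taxa = 120, n_samples_per_group = 6, depth = 5000,
                        shared_fraction = 1, litterbag_pool_fraction = 1,
                        dispersion_scale = 1, habitat_sdlog = 0, seed = 5)
  comm <- gen_paired_communities(d)
  bc <- as.matrix(bray_curtis(comm, relative = TRUE))
  same <- outer(comm$samples$group, comm$samples$group, "==")
  lt <- lower.tri(bc)
  within <- mean(bc[lt & same])
  between <- mean(bc[lt & !same])
  expect_lt(abs(between - within) / within, 0.05)
})

test_that("planted litterbag enrichment is recovered across seeds", {
  hits <- vapply(1:30, function(s) {
    # shared pools and no habitat tilt, so the planted fold-change is the
    # only systematic litterbag/soil difference
    d <- synthetic_design(n_taxa = 150, n_samples_per_group = 4, depth = 5000,
                          shared_fraction = 1, litterbag_pool_fraction = 1,
                          habitat_sdlog = 0,
                          enrichment_effects = list(
                            list(taxa = sprintf("taxon%05d", 1:50), fold = 2)),
                          seed = s)
    comm <- gen_paired_communities(d)
    rel <- relative_abundance(comm)
    lit <- comm$samples$habitat == "litterbag"
    planted <- sprintf("taxon%05d", 1:50)
    mean(colMeans(rel[lit, planted])) > mean(colMeans(rel[!lit, planted]))
  }, logical(1))
  expect_gte(sum(hits), 28)  # >= 95% nominal, 30-seed battery
})

test_that("litterbag dispersion exceeds soil dispersion across seeds", {
  hits <- vapply(1:20, function(s) {
    d <- synthetic_design(n_taxa = 120, n_samples_per_group = 6, depth = 5000,
                          seed = s)
    comm <- gen_paired_communities(d)
    bc <- bray_curtis(comm, relative = TRUE)
    gd <- group_dispersion(bc, comm$samples$group, permutations = 0)
    gd$group_means[["WL"]] > gd$group_means[["WS"]]
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("relative abundances close to one (compositional closure)", {
  d <- synthetic_design(n_taxa = 50, n_samples_per_group = 3, depth = 1000,
                        seed = 8)
  rel <- relative_abundance(gen_paired_communities(d))
  expect_true(all(abs(rowSums(rel) - 1) < 1e-12))
})

test_that("enrichment of unknown taxa is rejected", {
  d <- synthetic_design(n_taxa = 20, seed = 1,
                        enrichment_effects = list(list(taxa = "nosuch",
                                                       fold = 2)))
  expect_error(gen_paired_communities(d), "not in taxon list")
  expect_error(synthetic_design(n_taxa = 20,
                                enrichment_effects = list(
                                  list(taxa = "taxon00001", fold = -1))),
               "fold")
})

test_that("forcing obeys the warming contract", {
  fd <- forcing_design(n_days = 120,
                       noise_sd = list(temperature = 0, moisture = 0,
                                       litter = 0), seed = 3)
  fc <- gen_forcing(fd, warmed = FALSE)
  fw <- gen_forcing(fd, warmed = TRUE)
  expect_equal(fw$temperature_C - fc$temperature_C, rep(1.8, 120))
  expect_equal(fw$moisture_vv, fc$moisture_vv * (1 - 0.17))
  expect_true(all(fc$litter_input >= 0))

  flat <- gen_forcing(forcing_design(n_days = 30, seasonal_amplitude = 0,
                                     noise_sd = list(temperature = 0,
                                                     moisture = 0,
                                                     litter = 0), seed = 1))
  expect_equal(length(unique(flat$temperature_C)), 1L)
  expect_error(forcing_design(seasonal_amplitude = -1), "amplitude")
})

test_that("warming offset is recovered from noisy series", {
  # sampling error of the mean difference at the default noise is ~0.034 degC
  fd <- forcing_design(n_days = 1095, seed = 42)
  diff <- mean(gen_forcing(fd, TRUE)$temperature_C) -
    mean(gen_forcing(fd, FALSE)$temperature_C)
  expect_lt(abs(diff - 1.8), 0.05 + 0.034)
})

test_that("observation generator ties the gene series to the enzyme pool", {
  f <- quick_forcing(150, seed = 2)
  p <- mend_params()
  obs0 <- gen_observations(p, mend_state(), f,
                           noise_sd_map = list(rh = 0, mbc = 0, gene = 0),
                           seed = 1)
  ep2 <- obs0$trajectory$states[obs0$series$gene$day, "EP2"]
  expect_equal(stats::cor(obs0$series$gene$value, ep2), 1)

  cors <- vapply(1:10, function(s) {
    obs <- gen_observations(p, mend_state(), f,
                            noise_sd_map = list(rh = 0, mbc = 0, gene = 0.1),
                            seed = s)
    stats::cor(obs$series$gene$value, ep2)
  }, numeric(1))
  expect_true(all(cors >= 0.9))
  expect_error(gen_observations(p, mend_state(), f,
                                noise_sd_map = list(rh = -1, mbc = 0,
                                                    gene = 0)),
               "negative noise")
})

test_that("probe generator handles edge cases", {
  expect_error(gen_probe_table(10, groups = rep("WL", 4),
                               effect_map = list(nosuchgene = 2)),
               "unknown gene")
  empty <- gen_probe_table(0, groups = rep(c("WL", "CL"), each = 3))
  expect_identical(nrow(empty$intensity), 0L)
  expect_identical(nrow(filter_probes(empty)$intensity), 0L)
})
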
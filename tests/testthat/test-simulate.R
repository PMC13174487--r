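test_that("identical configs give byte-identical outputs", {
  cfg <- sim_config(seed = 3, n_cells = 300)
  a <- simulate_cd8_counts(cfg)
  b <- simulate_cd8_counts(cfg)
  expect_identical(a, b)
  expect_identical(simulate_clonotypes(cfg, a$truth),
                   simulate_clonotypes(cfg, b$truth))
  expect_identical(simulate_tissue(cfg), simulate_tissue(cfg))
})

test_that("Poisson-limit sample means match the archetype table within 3 SE", {
  cfg <- sim_config(seed = 11, n_cells = 10000, nb_dispersion = Inf,
                    zero_inflation = 0,
                    state_mixture = c("stem-like" = 1))
  sim <- simulate_cd8_counts(cfg)
  arch <- cd8_archetypes(cfg$gene_panel)
  iv <- cfg$state_u[["stem-like"]]
  for (g in seq_len(nrow(arch))) {
    # oracle: expected mean under u ~ Uniform(iv), by numerical integration
    mu_expected <- arch$baseline[g] * stats::integrate(function(u) {
      archetype_multiplier(arch$class[g], u, cfg$marker_amp)
    }, iv[1], iv[2])$value / diff(iv)
    obs <- mean(sim$counts[g, ])
    # Poisson mixture: Var = E[mu] + Var(mu); bound with E[mu^2] proxy
    se <- sqrt((mu_expected + mu_expected^2) / cfg$n_cells)
    expect_lt(abs(obs - mu_expected), 3 * se + 1e-9)
  }
})

test_that("pure stem mixture puts CXCR5 above HAVCR2", {
  cfg <- sim_config(seed = 2, n_cells = 5000,
                    state_mixture = c("stem-like" = 1))
  sim <- simulate_cd8_counts(cfg)
  expect_gt(mean(sim$counts["CXCR5", ]), mean(sim$counts["HAVCR2", ]))
})

test_that("variance/mean ratio matches the configured NB dispersion", {
  # degenerate u interval so every cell shares one mean per gene
  cfg <- sim_config(seed = 8, n_cells = 10000, nb_dispersion = 2,
                    zero_inflation = 0,
                    state_mixture = c("stem-like" = 1),
                    state_u = list("stem-like" = c(0.1, 0.1)))
  sim <- simulate_cd8_counts(cfg)
  set.seed(42)
  for (g in c("TCF7", "CD8A", "HK05")) {
    y <- sim$counts[g, ]
    ratio <- var(y) / mean(y)
    expected <- 1 + mean(y) / 2
    boot <- replicate(200, {
      s <- sample(y, replace = TRUE)
      var(s) / mean(s)
    })
    ci <- quantile(boot, c(0.005, 0.995))
    expect_true(expected >= ci[1] && expected <= ci[2])
  }
})

test_that("zero stem preset forbids multi-stem expanded clones", {
  cfg <- sim_config(seed = 4, n_cells = 2000, frac_expanding_with_stem = 0)
  sim <- simulate_cd8_counts(cfg)
  clo <- simulate_clonotypes(cfg, sim$truth)
  is_stem <- stats::setNames(sim$truth$state == "stem-like", sim$truth$cell_id)
  stem_per_clone <- tapply(is_stem[clo$assignments$cell_id],
                           clo$assignments$clonotype_id, sum)
  sizes <- table(clo$assignments$clonotype_id)
  expect_true(all(stem_per_clone[sizes >= 3] < 2))
})

test_that("stem-content fraction of expanded clones hits its target", {
  cfg <- sim_config(seed = 9, n_cells = 8000, frac_expanding_with_stem = 0.5)
  sim <- simulate_cd8_counts(cfg)
  clo <- simulate_clonotypes(cfg, sim$truth)
  expd <- clo$clones[clo$clones$expanding, ]
  expect_gt(nrow(expd), 300)
  frac <- mean(expd$n_stem_planted >= 2)
  ci <- qbinom(c(0.025, 0.975), nrow(expd), 0.5) / nrow(expd)
  expect_true(frac >= ci[1] && frac <= ci[2])
})

test_that("clone sizes are conserved and singletons are non-expanding", {
  cfg <- sim_config(seed = 5, n_cells = 500)
  sim <- simulate_cd8_counts(cfg)
  clo <- simulate_clonotypes(cfg, sim$truth)
  expect_equal(sum(clo$clones$size), 500)
  expect_identical(sort(clo$assignments$cell_id), sort(sim$truth$cell_id))
  expect_true(all(!clo$clones$expanding[clo$clones$size < 3]))
  # size histogram recorded by the generator matches the assignments
  expect_equal(sort(as.integer(table(clo$assignments$clonotype_id))),
               sort(clo$clones$size))
})

test_that("tissue conserves cell counts with zero background", {
  cfg <- sim_config(seed = 6, background_immune_per_mm2 = 0,
                    aggregate_specs = list(list(
                      class = "Quiescent", n_cells = 200,
                      composition = c("CD8 T" = 0.5, "CD4 T" = 0.2,
                                      "B" = 0.1, "myeloid" = 0.2),
                      chemokine = 1, exhausted_frac = 0.1, stem_frac = 0.3)))
  tis <- simulate_tissue(cfg)
  expect_equal(nrow(tis$map), 200 + cfg$n_tumor_cells)
  expect_true(all(tis$map$x_um >= 0 & tis$map$x_um <= cfg$tissue_width_um))
  expect_true(all(tis$map$y_um >= 0 & tis$map$y_um <= cfg$tissue_height_um))
})

test_that("separated aggregates keep their planted distance", {
  spec2 <- list(
    list(class = "Quiescent", n_cells = 150,
         composition = c("CD8 T" = 0.5, "CD4 T" = 0.2, "B" = 0.1, "myeloid" = 0.2),
         chemokine = 1, exhausted_frac = 0.1, stem_frac = 0.3),
    list(class = "Lymphoid", n_cells = 150,
         composition = c("CD8 T" = 0.3, "CD4 T" = 0.2, "B" = 0.3, "myeloid" = 0.2),
         chemokine = 8, exhausted_frac = 0.15, stem_frac = 0.6))
  cfg <- sim_config(seed = 13, background_immune_per_mm2 = 0,
                    aggregate_specs = spec2, aggregate_sd_um = 20,
                    min_center_sep_um = 500)
  tis <- simulate_tissue(cfg)
  ids <- tis$truth$cell$aggregate_id
  a <- tis$map[which(ids == 1), ]; b <- tis$map[which(ids == 2), ]
  # brute force over emitted points
  dmin <- min(sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2))
  expect_gt(dmin, 300)
})

test_that("aggregate composition follows its multinomial spec", {
  comp <- c("CD8 T" = 0.3, "CD4 T" = 0.2, "B" = 0.3, "myeloid" = 0.2)
  cfg <- sim_config(seed = 21, background_immune_per_mm2 = 0,
                    aggregate_specs = list(list(
                      class = "Lymphoid", n_cells = 500, composition = comp,
                      chemokine = 8, exhausted_frac = 0.15, stem_frac = 0.6)))
  tis <- simulate_tissue(cfg)
  memb <- tis$map[!is.na(tis$truth$cell$aggregate_id), ]
  for (tp in names(comp)) {
    ci <- qbinom(c(0.025, 0.975), 500, comp[[tp]]) / 500
    frac <- mean(memb$cell_type == tp)
    expect_true(frac >= ci[1] && frac <= ci[2])
  }
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(sim_config(state_mixture = c("stem-like" = 0.7)), "state_mixture")
  expect_error(sim_config(zero_inflation = 1.2), "zero_inflation")
  expect_error(sim_config(gene_panel = c("CXCL13", "CXCR5")), "required genes")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  bad_spec <- default_aggregate_specs()
  bad_spec[[1]]$composition <- c("CD8 T" = 0.5, "B" = 0.1)
  expect_error(sim_config(aggregate_specs = bad_spec), "composition")
})
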
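test_that("clone building handles shared and distinct strings", {
  shared <- data.frame(cell_id = c("c1", "c2", "c3"),
                       clonotype_id = "TRA:0001|TRB:0001",
                       stringsAsFactors = FALSE)
  ct <- build_clonotypes(shared)
  expect_equal(ct$size, 3L)
  expect_true(ct$expanding)
  distinct <- data.frame(cell_id = c("c1", "c2", "c3"),
                         clonotype_id = sprintf("TRA:%04d|TRB:%04d", 1:3, 1:3),
                         stringsAsFactors = FALSE)
  ct2 <- build_clonotypes(distinct)
  expect_equal(nrow(ct2), 3)
  expect_true(all(!ct2$expanding))
  dup <- rbind(shared, shared[1, ])
  expect_error(build_clonotypes(dup), "duplicate")
})

test_that("cells without a TCR are excluded and counted", {
  asg <- data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                    clonotype_id = c("X", "X", NA, ""),
                    stringsAsFactors = FALSE)
  ct <- build_clonotypes(asg)
  expect_equal(attr(ct, "n_without_tcr"), 2L)
  expect_equal(sum(ct$size), 2L)
})

test_that("clone-size histogram matches the generator's record exactly", {
  cfg <- sim_config(seed = 14, n_cells = 1500)
  sim <- simulate_cd8_counts(cfg)
  clo <- simulate_clonotypes(cfg, sim$truth)
  ct <- build_clonotypes(clo$assignments, sim$truth |>
                           transform(state_label = state))
  rec <- clo$clones[match(ct$clonotype_id, clo$clones$clonotype_id), ]
  expect_equal(ct$size, rec$size)
  expect_equal(ct$expanding, rec$expanding)
  # per-state counts add up to clone sizes
  state_cols <- grep("^n_", names(ct), value = TRUE)
  expect_equal(unname(rowSums(ct[state_cols])), as.numeric(ct$size))
  # stem multiplicity equals the generator's planted count
  expect_equal(ct$stem_multiplicity, rec$n_stem_planted)
})

test_that("stem-content statistic matches a hand count", {
  ct <- data.frame(clonotype_id = sprintf("k%02d", 1:12),
                   size = c(rep(5, 10), 1, 2),
                   expanding = c(rep(TRUE, 10), FALSE, FALSE),
                   stem_multiplicity = c(2, 3, 0, 1, 5, 1, 0, 0, 1, 2, 0, 1),
                   stringsAsFactors = FALSE)
  res <- stem_content_statistic(ct)
  expect_true(res$computable)
  expect_equal(res$fraction, 0.40) # 4 of 10 expanding clones have >= 2
  expect_equal(res$n_expanding, 10L)
  expect_equal(res$max_stem_multiplicity, 5)
})

test_that("all-singleton repertoires are reported as not computable", {
  ct <- data.frame(clonotype_id = c("a", "b"), size = c(1L, 1L),
                   expanding = c(FALSE, FALSE), stem_multiplicity = c(1L, 0L),
                   stringsAsFactors = FALSE)
  res <- stem_content_statistic(ct)
  expect_false(res$computable)
  expect_match(res$reason, "no expanding")
})

test_that("outputs are invariant to cell-order permutations", {
  cfg <- sim_config(seed = 15, n_cells = 600)
  sim <- simulate_cd8_counts(cfg)
  clo <- simulate_clonotypes(cfg, sim$truth)
  states <- data.frame(cell_id = sim$truth$cell_id,
                       state_label = sim$truth$state)
  a <- build_clonotypes(clo$assignments, states)
  set.seed(1)
  perm <- sample(nrow(clo$assignments))
  b <- build_clonotypes(clo$assignments[perm, ], states)
  attr(a, "members") <- lapply(attr(a, "members"), sort)
  attr(b, "members") <- lapply(attr(b, "members"), sort)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("clone-level CXCL13/stem association recovers planted signs", {
  # perfect anti-ranking gives tau = -1
  ct <- data.frame(clonotype_id = sprintf("k%d", 1:6), size = rep(4L, 6),
                   expanding = TRUE, stem_multiplicity = 0:5 * 0L,
                   stringsAsFactors = FALSE)
  ct$stem_multiplicity <- as.integer(c(0, 1, 2, 3, 4, 4))
  cells <- split(sprintf("c%02d", 1:24), rep(1:6, each = 4))
  names(cells) <- ct$clonotype_id
  attr(ct, "members") <- cells
  expr <- matrix(0, 1, 24, dimnames = list("CXCL13", sprintf("c%02d", 1:24)))
  expr["CXCL13", ] <- rep(c(60, 50, 40, 30, 20, 10), each = 4)
  res <- clone_program_association(ct, expr)
  expect_true(res$computable)
  expect_lt(res$tau, -0.9)
  # degenerate expression is flagged not computable
  expr0 <- expr; expr0["CXCL13", ] <- 1
  res0 <- clone_program_association(ct, expr0)
  expect_false(res0$computable)
})

test_that("tau on a 5-clone example equals the brute-force enumeration", {
  ct <- data.frame(clonotype_id = sprintf("k%d", 1:5), size = rep(2L, 5),
                   expanding = FALSE,
                   stem_multiplicity = as.integer(c(0, 2, 1, 2, 0)),
                   stringsAsFactors = FALSE)
  cells <- split(sprintf("c%02d", 1:10), rep(1:5, each = 2))
  names(cells) <- ct$clonotype_id
  attr(ct, "members") <- cells
  expr <- matrix(rep(c(3, 1, 4, 1, 5), each = 2), 1, 10,
                 dimnames = list("CXCL13", sprintf("c%02d", 1:10)))
  res <- clone_program_association(ct, expr)
  expect_equal(res$tau,
               brute_tau_b(c(3, 1, 4, 1, 5), c(0, 2, 1, 2, 0) / 2),
               tolerance = 1e-12)
})
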
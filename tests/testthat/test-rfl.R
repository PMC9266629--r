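test_that("compute_rfl forms the drive/suppress ratio and flags undefined samples", {
  act <- compute_rfl(c(a = 0.4, b = 0.2), c(a = 0.4, b = 0.4))
  expect_equal(act$rfl, c(1.0, 0.5))
  expect_identical(act$sample, c("a", "b"))
  expect_message(
    act2 <- compute_rfl(c(0.4, 0.2), c(0.4, 0)),
    "undefined"
  )
  expect_true(is.na(act2$rfl[2]))
  expect_error(compute_rfl(c(1, 2), c(0, -1)), "every sample")
  expect_error(compute_rfl(1:3, 1:2), "equal length")
})

test_that("RFL is invariant to a common positive rescaling of both activities", {
  drive <- c(0.5, 0.8, 1.2, 0.3)
  suppress <- c(0.4, 0.9, 0.7, 0.6)
  base <- compute_rfl(drive, suppress)$rfl
  for (c_scale in c(0.01, 3, 1e4)) {
    expect_equal(compute_rfl(c_scale * drive, c_scale * suppress)$rfl, base,
                 tolerance = 1e-12)
  }
})

test_that("validate_rfl passes a well-formed synthetic cohort", {
  cohort <- cached_cohort()
  val <- validate_rfl(cohort$activity)
  expect_true(val$pass)
  expect_gt(val$r_drive, 0.2)
  expect_lt(val$r_suppress, -0.2)
})

test_that("validate_rfl flags degenerate components", {
  act <- compute_rfl(rep(0.5, 5), c(0.2, 0.4, 0.6, 0.8, 1.0))
  val <- validate_rfl(act)  # drive constant, rfl varies via suppress
  expect_true(is.na(val$p_drive) || !is.na(val$r_drive))
  # drive constant => r(rfl, drive) undefined => fail with NA diagnostic
  expect_true(is.na(val$r_drive))
  expect_false(val$pass)
  # suppress constant positive: rfl is proportional to drive => r = 1
  act2 <- compute_rfl(c(0.2, 0.5, 0.9, 1.4), rep(2, 4))
  val2 <- validate_rfl(act2)
  expect_equal(val2$r_drive, 1, tolerance = 1e-12)
  expect_error(validate_rfl(compute_rfl(c(1, 2), c(1, 1))), "at least 3")
})

test_that("assign_groups uses a strict boundary and needs an interior cutoff", {
  rfl <- c(0.2, 0.5, 0.9)
  expect_identical(assign_groups(rfl, 0.5), c("low", "low", "high"))
  expect_identical(assign_groups(rfl, 0.4), c("low", "high", "high"))
  expect_error(assign_groups(rfl, 0.95), "range")
  expect_error(assign_groups(rfl, 0.2), "range")
  expect_true(is.na(assign_groups(c(rfl, NA), 0.5)[4]))
})

test_that("raising the cutoff never moves a sample from low to high", {
  set.seed(11)
  rfl <- runif(40)
  cuts <- sort(runif(10, min = min(rfl) + 1e-3, max = max(rfl) - 1e-3))
  prev <- assign_groups(rfl, cuts[1])
  for (k in 2:length(cuts)) {
    cur <- assign_groups(rfl, cuts[k])
    expect_false(any(prev == "low" & cur == "high"))
    prev <- cur
  }
})

test_that("RFL tracks the latent ferroptosis activity on synthetic cohorts", {
  cohort <- cached_cohort()
  rho <- cor(cohort$activity$rfl, cohort$truth$f, method = "spearman",
             use = "complete.obs")
  expect_gt(rho, 0.8)
})

test_that("a null generator (effect_b = 0) yields no RFL-activity association", {
  cohort <- generate_cohort(sim_params(seed = 5, effect_b = 0, n_genes = 800,
                                       n_samples = 300))
  scores <- score_matrix(cohort$expr,
                         list(cohort$pair$drivers, cohort$pair$suppressors))
  act <- suppressMessages(compute_rfl(scores["drivers", ], scores["suppressors", ]))
  rho <- cor(act$rfl, cohort$truth$f, method = "spearman", use = "complete.obs")
  expect_lt(abs(rho), 0.2)
})

test_that("pseudobulk averages cells gene-wise per patient", {
  cells <- matrix(c(1, 3, 3, 5), nrow = 2, byrow = TRUE,
                  dimnames = list(c("c1", "c2"), c("g1", "g2")))
  pb <- pseudobulk(cells, c(c1 = "p1", c2 = "p1"))
  expect_equal(pb[, "p1"], c(g1 = 2, g2 = 4))
  # single cell: identity
  pb1 <- pseudobulk(cells[1, , drop = FALSE], c(c1 = "p1"))
  expect_equal(pb1[, "p1"], c(g1 = 1, g2 = 3))
  # two patients, disjoint cells, computed independently
  pb2 <- pseudobulk(cells, c(c1 = "p1", c2 = "p2"))
  expect_equal(pb2[, "p1"], c(g1 = 1, g2 = 3))
  expect_equal(pb2[, "p2"], c(g1 = 3, g2 = 5))
  expect_error(pseudobulk(cells, c(c1 = "p1")), "unmapped")
})

test_that("feature correlations recover exact and planted relationships", {
  set.seed(21)
  rfl <- runif(60)
  res <- correlate_rfl_with_features(
    rfl, data.frame(self = rfl, anti = -rfl)
  )
  expect_equal(res$r[res$feature == "self"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$feature == "anti"], -1, tolerance = 1e-12)
  # planted immune-like column: positively loaded on the same latent signal
  cohort <- cached_cohort()
  ok <- !is.na(cohort$activity$rfl)
  set.seed(22)
  immune <- cohort$truth$f + rnorm(length(cohort$truth$f), sd = 0.7)
  res2 <- correlate_rfl_with_features(cohort$activity$rfl[ok],
                                      data.frame(immune = immune[ok]))
  o <- oracle_pearson(cohort$activity$rfl[ok], immune[ok])
  expect_gt(res2$r, 0)
  expect_equal(res2$r, o$r, tolerance = 1e-12)
  expect_equal(res2$p, o$p, tolerance = 1e-10)
})

test_that("constant features are flagged undefined", {
  expect_warning(
    res <- correlate_rfl_with_features(runif(10), data.frame(k = rep(1, 10))),
    "constant"
  )
  expect_true(is.na(res$r))
})
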
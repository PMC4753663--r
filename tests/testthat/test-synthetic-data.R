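test_that("simulation_design validates its invariants", {
  expect_error(simulation_design(n_replicates = 1), "n_replicates")
  expect_error(simulation_design(noise_sd = 0), "noise_sd")
  expect_error(simulation_design(
    n_metabolites = 30,
    planted_effects = data.frame(index = 31, beta_g = 1, beta_b = 0,
                                 class = "E")), "planted index")
  d <- simulation_design()
  expect_equal(d$n_times, 4)
  expect_equal(d$sample_times_h, c(24, 48, 60, 80))
  expect_equal(d$n_metabolites, 97L)
})

test_that("fermentation time course has the four-phase shape", {
  tc <- simulate_fermentation(seed = 1)
  expect_true(all(diff(tc$time_h) > 0))
  expect_true(all(tc$od600 > 0))
  expect_true(all(tc[c("butanol", "acetate", "butyrate", "glucose")] >= 0))
  # butanol is a trace (<= 0.1 g/L) before the acid-peak onset, then rises
  onset <- 32
  expect_lte(max(tc$butanol[tc$time_h <= onset]), 0.1)
  expect_gt(tc$butanol[tc$time_h == 80], 10)
  # acids peak at the onset and fall afterwards
  expect_equal(tc$time_h[which.max(tc$acetate)], onset)
  expect_lt(tc$butyrate[tc$time_h == 80], max(tc$butyrate))
  # OD: flat-ish lag, exponential log, slow decline at the end
  expect_gt(tc$od600[tc$time_h == 44], 10 * tc$od600[tc$time_h == 12])
  expect_lt(tc$od600[tc$time_h == 84], tc$od600[tc$time_h == 64])
  # pH falls, bumps at onset, falls again
  expect_lt(tc$ph[tc$time_h == 12], tc$ph[tc$time_h == 0])
  expect_gt(tc$ph[tc$time_h == onset], tc$ph[tc$time_h == 12])
  expect_lt(tc$ph[tc$time_h == 84], tc$ph[tc$time_h == onset])
  expect_error(simulate_fermentation(times = c(0, 10, 5)), "increasing")
})

test_that("zero growth in every phase keeps OD at the inoculum", {
  tc <- simulate_fermentation(growth_rates = c(0, 0, 0, 0), od0 = 0.4)
  expect_equal(tc$od600, rep(0.4, nrow(tc)))
})

test_that("a pure exponential window is recovered exactly by compute_mu", {
  tc <- simulate_fermentation(times = seq(0, 40, by = 2),
                              growth_rates = c(0.07, 0.07, 0.07, 0.07))
  mu <- compute_mu(tc)
  expect_lt(max(abs(mu$mu - 0.07)), 1e-6)
})

test_that("metabolome generator honours the design and its null limits", {
  design <- simulation_design(seed = 3)
  tc <- simulate_fermentation(seed = 3)
  phen <- phenotype_rates(tc, design$sample_times_h)
  sim <- simulate_metabolome(phen, design)
  expect_equal(nrow(sim$table), 4 * 5)
  expect_equal(nrow(sim$ground_truth), 97)
  met_cols <- setdiff(names(sim$table), c("time_h", "replicate"))
  expect_true(all(as.matrix(sim$table[met_cols]) > 0))
  expect_true("IS_succinate_d4" %in% names(sim$table))

  # fewer than 2 distinct sampling times is rejected
  expect_error(simulate_metabolome(phen[1, ], design), "distinct sampling")

  # near-null model: no planted effects, tiny noise -> metabolite nearly
  # constant across samples after normalization
  d0 <- simulation_design(
    noise_sd = 1e-8,
    planted_effects = data.frame(index = integer(0), beta_g = numeric(0),
                                 beta_b = numeric(0), class = character(0)),
    seed = 5)
  s0 <- simulate_metabolome(phen, d0)
  a0 <- relative_abundance(s0$table,
                           phen$dcw[match(s0$table$time_h, phen$time_h)])
  cv <- apply(a0[, -(1:2)], 2, function(v) sd(v) / mean(v))
  expect_lt(max(cv), 1e-6)
})

test_that("identical seed and design give bit-identical outputs", {
  design <- simulation_design(seed = 11)
  tc1 <- simulate_fermentation(seed = 11, noise_sd = 0.05)
  tc2 <- simulate_fermentation(seed = 11, noise_sd = 0.05)
  expect_identical(tc1, tc2)
  phen <- phenotype_rates(tc1, design$sample_times_h)
  expect_identical(simulate_metabolome(phen, design),
                   simulate_metabolome(phen, design))
  gt <- simulate_metabolome(phen, design)$ground_truth
  l1 <- make_pathway_library(gt$metabolite, seed = 11)
  l2 <- make_pathway_library(gt$metabolite, seed = 11)
  expect_identical(l1, l2)
})

test_that("per-metabolite substreams: adding a metabolite does not reshuffle", {
  tc <- simulate_fermentation(seed = 2)
  pe <- data.frame(index = 1, beta_g = 0.6, beta_b = 0, class = "E")
  d_small <- simulation_design(n_metabolites = 30, planted_effects = pe,
                               seed = 7)
  d_big <- simulation_design(n_metabolites = 31, planted_effects = pe,
                             seed = 7)
  phen <- phenotype_rates(tc, d_small$sample_times_h)
  t_small <- simulate_metabolome(phen, d_small)$table
  t_big <- simulate_metabolome(phen, d_big)$table
  shared <- d_small$metabolite_ids
  expect_identical(t_small[shared], t_big[shared])
})

test_that("planted positive effect yields positive correlation with mu", {
  tc <- simulate_fermentation(seed = 1)
  d1 <- simulation_design(seed = 1)
  phen <- phenotype_rates(tc, d1$sample_times_h)
  pe <- data.frame(index = 1, beta_g = 3 * 0.2, beta_b = 0, class = "E")
  hits <- 0L
  for (s in 1:100) {
    d <- simulation_design(n_metabolites = 10, planted_effects = pe,
                           noise_sd = 0.2, seed = s)
    sim <- simulate_metabolome(phen, d)
    ar <- relative_abundance(sim$table,
                             phen$dcw[match(sim$table$time_h, phen$time_h)])
    mu_s <- phen$mu[match(ar$time_h, phen$time_h)]
    if (cor(ar[[d$metabolite_ids[1]]], mu_s) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("planted-signal monotonicity: |coefficient| grows with |beta|", {
  tc <- simulate_fermentation(seed = 1)
  d1 <- simulation_design(seed = 1)
  phen <- phenotype_rates(tc, d1$sample_times_h)
  betas <- c(0.2, 0.6, 1.8)
  mean_abs <- vapply(betas, function(b) {
    vals <- vapply(1:100, function(s) {
      pe <- data.frame(index = 1, beta_g = b, beta_b = 0, class = "E")
      d <- simulation_design(n_metabolites = 10, planted_effects = pe,
                             noise_sd = 0.2, seed = s)
      sim <- simulate_metabolome(phen, d)
      ar <- relative_abundance(sim$table,
                               phen$dcw[match(sim$table$time_h, phen$time_h)])
      X <- as.matrix(ar[, -(1:2)])
      m <- fit_pls(X, phen$mu[match(ar$time_h, phen$time_h)], ncomp = 1)
      abs(coef(m)[d$metabolite_ids[1]])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_abs) > 0))
})

test_that("pathway library: structure, planting and round-trip", {
  mets <- sprintf("C9%04d", 1:40)
  planted <- list(g_pos = mets[1:15])
  lib <- make_pathway_library(mets, planted = planted, n_pathways = 6,
                              size_range = c(4, 8), seed = 2)
  expect_s3_class(lib, "pathway_library")
  expect_length(lib$pathways, 6)
  p1 <- lib$pathways[[1]]
  expect_true(p1$planted)
  frac <- mean(p1$compounds %in% planted$g_pos)
  expect_gte(frac, 0.6)
  # graphs are DAGs on the compound set
  for (p in lib$pathways) {
    g <- igraph::graph_from_data_frame(p$edges, vertices = p$compounds)
    expect_true(igraph::is_dag(g))
  }
  # reject sizes < 2 and infeasible planted classes
  expect_error(make_pathway_library(mets, size_range = c(1, 3)), ">= 2")
  expect_error(make_pathway_library(mets, planted = list(x = mets[1:2]),
                                    size_range = c(10, 12)),
               "planted pathway")

  # GMT + SIF round-trip preserves membership and edge sets
  gmt <- tempfile(fileext = ".gmt"); sif <- tempfile(fileext = ".sif")
  write_pathway_library(lib, gmt, sif)
  lib2 <- read_pathway_library(gmt, sif)
  expect_identical(names(lib2$pathways), names(lib$pathways))
  for (id in names(lib$pathways)) {
    expect_setequal(lib2$pathways[[id]]$compounds,
                    lib$pathways[[id]]$compounds)
    e1 <- lib$pathways[[id]]$edges; e2 <- lib2$pathways[[id]]$edges
    expect_setequal(paste(e1$from, e1$to), paste(e2$from, e2$to))
  }
  unlink(c(gmt, sif))
})
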
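test_that("pool dimensions follow the design layout", {
  des <- pool_design(n_strains = 100L, n_controls = 12L,
                     n_reps_per_dose = 3L, generations = 5, seed = 3L)
  p <- generate_pool(des)
  expect_equal(dim(p$intensity), c(200L, 21L))
  expect_equal(nrow(p$design_table), 21L)
  expect_equal(sum(p$design_table$dose_group == "control"), 12L)
  des2 <- pool_design(n_strains = 10L, generations = c(5, 15), seed = 3L)
  expect_equal(nrow(generate_pool(des2)$design_table), 42L)
})

test_that("planted depletion appears as the treated-control mean difference", {
  des <- pool_design(n_strains = 80L, generations = 5, chip_sd = 0,
                     noise_sd = 0.05, seed = 9L)
  tr <- planted_truth("S0001", defect = 0.4, des)  # 0.4 * 5 g = -2.0 log2
  expect_equal(unique(tr$expected_log2_depletion[tr$generation == 5]), 2.0)
  p <- generate_pool(des, tr)
  vals <- regroup_tags(p$intensity)
  d <- p$design_table
  for (dd in c("25", "50", "100")) {
    diff <- mean(vals["S0001", d$chip[d$dose_group == dd]]) -
      mean(vals["S0001", d$chip[d$dose_group == "control"]])
    expect_lt(abs(diff - (-2.0)), 0.1)
  }
})

test_that("generation scaling and seeding behave as promised", {
  des <- pool_design(n_strains = 20L, generations = c(5, 15), seed = 5L)
  tr <- planted_truth("S0002", defect = 0.3, des)
  d5 <- tr$expected_log2_depletion[tr$generation == 5]
  d15 <- tr$expected_log2_depletion[tr$generation == 15]
  expect_equal(d15, 3 * d5)

  p1 <- generate_pool(des, tr)
  p2 <- generate_pool(des, tr)
  expect_identical(p1$intensity, p2$intensity)
  p3 <- generate_pool(pool_design(n_strains = 20L, generations = c(5, 15),
                                  seed = 6L), tr)
  expect_false(identical(p1$intensity, p3$intensity))
  expect_identical(p1$truth, p3$truth)  # truth is seed-independent
})

test_that("non-planted strains have fitness centered at zero across seeds", {
  scores <- vapply(1:50, function(s) {
    des <- pool_design(n_strains = 30L, generations = 5, seed = s,
                       chip_sd = 0.1, noise_sd = 0.2)
    p <- generate_pool(des)
    vals <- regroup_tags(p$intensity)
    cond <- list(dose_group = "100", generation = 5)
    mean(fitness_scores(vals, p$design_table, cond))
  }, numeric(1))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se + 1e-8)
})

test_that("generator rejects invalid designs and planted sets", {
  expect_error(pool_design(n_controls = 1L))
  expect_error(pool_design(dose_levels = c("25", "control")))
  des <- pool_design(n_strains = 10L, seed = 1L)
  expect_error(planted_truth(c("S0001", "S0001"), 0.2, des), "duplicate")
  expect_error(planted_truth("S0001", 1.5, des), "defect")
  expect_error(generate_pool(des, planted_truth("S9999", 0.2, des)),
               "not in pool")
})

test_that("pathway generator honors clustered/scattered planting", {
  for (seed in 1:5) {
    pwc <- generate_pathways(n_pathways = 3L, sizes = 10L, n_genes = 60L,
                             adjacency_mode = "clustered", n_planted = 3L,
                             seed = seed)
    pw <- pwc$pathways[[1L]]
    g <- igraph::graph_from_edgelist(pw$edges, directed = FALSE)
    expect_true(igraph::is_connected(
      igraph::induced_subgraph(g, pwc$planted_genes)))

    pws <- generate_pathways(n_pathways = 3L, sizes = 10L, n_genes = 60L,
                             adjacency_mode = "scattered", n_planted = 3L,
                             seed = seed)
    g2 <- igraph::graph_from_edgelist(pws$pathways[[1L]]$edges,
                                      directed = FALSE)
    pl <- pws$planted_genes
    for (i in 1:2) for (j in (i + 1):3)
      expect_false(igraph::are_adjacent(g2, pl[i], pl[j]))
  }
  # every pathway connected; determinism
  pw1 <- generate_pathways(seed = 42L)
  pw2 <- generate_pathways(seed = 42L)
  expect_identical(pw1, pw2)
  for (p in pw1$pathways) {
    g <- igraph::graph_from_edgelist(p$edges, directed = FALSE)
    expect_true(igraph::is_connected(g))
    expect_setequal(igraph::V(g)$name, p$nodes)
  }
})

test_that("interaction network has a dense planted module and heavy tail", {
  nd <- generate_network(n_nodes = 500L, planted_module_size = 12L, seed = 2L)
  g <- load_network(nd$edges, cutoff = 700)
  sub <- igraph::induced_subgraph(g, nd$module)
  expect_gt(igraph::edge_density(sub), igraph::edge_density(g))
  expect_identical(nd, generate_network(n_nodes = 500L,
                                        planted_module_size = 12L, seed = 2L))

  # degree tail heavier than Erdos-Renyi with matched size (max degree)
  n_e <- igraph::ecount(g)
  er_max <- vapply(1:20, function(s) {
    withr::with_seed(s, max(igraph::degree(
      igraph::sample_gnm(igraph::vcount(g), n_e))))
  }, numeric(1))
  expect_gt(max(igraph::degree(g)), max(er_max))
})

test_that("growth curves follow the logistic contract", {
  wells <- data.frame(well = c("a", "b"), dose = c(0, 1))
  cc <- generate_growth_curves(wells, dose_effect = 0, noise_sd = 0, seed = 1L)
  expect_equal(sum(cc$well == "a"), 97L)  # 15-min grid over 24 h
  expect_equal(cc$od[cc$well == "a"], cc$od[cc$well == "b"])  # no dose effect
  expect_false(is.unsorted(cc$od[cc$well == "a"]))  # monotone before noise

  # terminal OD approaches capacity
  longw <- data.frame(well = "a", dose = 0, rate = 0.6, lag = 1,
                      capacity = 1.3, od0 = 0.02)
  cl <- generate_growth_curves(longw, noise_sd = 0, t_end = 72, seed = 1L)
  expect_lt(abs(max(cl$od) - 1.3), 1e-6)

  # halved rate shrinks the AUC
  w2 <- data.frame(well = c("ctrl", "trt"), dose = c(0, 1),
                   rate_factor = c(1, 0.5))
  c2 <- generate_growth_curves(w2, noise_sd = 0, seed = 1L)
  auc_c <- growth_auc(c2$time_h[c2$well == "ctrl"], c2$od[c2$well == "ctrl"])
  auc_t <- growth_auc(c2$time_h[c2$well == "trt"], c2$od[c2$well == "trt"])
  expect_lt(auc_t, auc_c)

  expect_error(generate_growth_curves(
    data.frame(well = "a", dose = 0, rate = -1)), "positive")
})

test_that("shipped consensus fixtures parse with printed layout intact", {
  hq <- read_consensus_fixture("HQ")
  cat_tab <- read_consensus_fixture("CAT")
  bt <- read_consensus_fixture("BT")
  expect_equal(nrow(hq), 31L)
  expect_equal(nrow(cat_tab), 33L)
  expect_equal(nrow(bt), 12L)
  expect_equal(hq$g5_dose25[hq$orf == "YOL081W"], -2.5)
  expect_equal(hq$gene[hq$orf == "YOL081W"], "IRA2")
  # a resistant gene keeps its printed positive scores
  expect_equal(cat_tab$g15_dose25[cat_tab$orf == "YKL133C"], 2.8)
  # empty printed cells are missing, not zero
  expect_true(is.na(hq$g15_dose100[hq$orf == "YHL009C"]))
})
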
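test_that("fitness score is the treated-control mean difference", {
  vals <- matrix(c(rep(10, 12), rep(8, 3)), nrow = 1,
                 dimnames = list("s1", NULL))
  design <- data.frame(chip = paste0("c", 1:15),
                       compound = "HQ",
                       dose_group = rep(c("control", "100"), c(12, 3)),
                       generation = 5, replicate = 1)
  colnames(vals) <- design$chip
  cond <- list(compound = "HQ", dose_group = "100", generation = 5)
  expect_equal(unname(fitness_scores(vals, design, cond)), -2)

  # identical values give zero, and swapping labels flips the sign
  vals2 <- vals; vals2[1, ] <- 9
  expect_equal(unname(fitness_scores(vals2, design, cond)), 0)
  design_sw <- design
  design_sw$dose_group <- rep(c("100", "control"), c(12, 3))
  vals3 <- matrix(rnorm(15, 10), 1, dimnames = list("s1", design$chip))
  s1 <- fitness_scores(vals3, design, cond)
  s2 <- fitness_scores(vals3, design_sw,
                       list(compound = "HQ", dose_group = "100",
                            generation = 5))
  expect_equal(unname(s1), -unname(s2))
})

test_that("degenerate strains get p = 1 and BH matches a step-up oracle", {
  withr::with_seed(10, vals <- matrix(rnorm(15 * 20, 10, 0.2), 20))
  vals[1, ] <- 7  # constant in both groups
  rownames(vals) <- sprintf("s%02d", 1:20)
  design <- data.frame(chip = paste0("c", 1:15), compound = "HQ",
                       dose_group = rep(c("control", "100"), c(12, 3)),
                       generation = 5, replicate = 1)
  colnames(vals) <- design$chip
  res <- dssa_significance(vals, design,
                           list(dose_group = "100", generation = 5))
  expect_equal(res$p_value[1], 1)

  # brute-force BH step-up on <=10 p-values: q_i = min over j>=i of p_(j)*m/j
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m))
      q[o[i]] <- min(vapply(i:m, function(j) min(p[o[j]] * m / j, 1),
                            numeric(1)))
    q
  }
  withr::with_seed(11, {
    for (rep in 1:20) {
      p <- runif(sample(2:10, 1))
      expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
    }
  })
})

test_that("row-wise t statistics match t.test in both flavors", {
  withr::with_seed(12, {
    x <- matrix(rnorm(30, 10), 2, 15)
    rownames(x) <- c("a", "b")
    colnames(x) <- paste0("c", 1:15)
  })
  design <- data.frame(chip = paste0("c", 1:15), compound = "HQ",
                       dose_group = rep(c("control", "50"), c(12, 3)),
                       generation = 5, replicate = 1)
  cond <- list(dose_group = "50", generation = 5)
  pooled <- dssa_significance(x, design, cond)
  welch <- dssa_significance(x, design, cond, method = "welch")
  for (i in 1:2) {
    tp <- t.test(x[i, 13:15], x[i, 1:12], var.equal = TRUE)
    tw <- t.test(x[i, 13:15], x[i, 1:12])
    expect_equal(pooled$p_value[i], tp$p.value)
    expect_equal(pooled$t[i], unname(tp$statistic))
    expect_equal(welch$p_value[i], tw$p.value)
    expect_equal(welch$df[i], unname(tw$parameter))
  }
})

test_that("type-I error of the per-strain test is nominal under the null", {
  des <- small_design(n_strains = 2000L, seed = 21L)
  p <- generate_pool(des)
  vals <- regroup_tags(p$intensity)
  res <- dssa_significance(vals, p$design_table,
                           list(dose_group = "100", generation = 5))
  frac <- mean(res$p_value < 0.05)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / 2000)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("a strong planted effect is almost always discovered at q<0.05", {
  hits <- vapply(1:50, function(s) {
    des <- small_design(n_strains = 100L, seed = 100 + s, noise_sd = 0.2)
    tr <- planted_truth("S0001", defect = 4 / 5, des)  # -4 log2 at 5 g
    p <- generate_pool(des, tr)
    vals <- regroup_tags(p$intensity)
    res <- dssa_significance(vals, p$design_table,
                             list(dose_group = "100", generation = 5))
    res$q_value[res$strain == "S0001"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("planted fitness scores concentrate around the planted depletion", {
  scores <- vapply(1:100, function(s) {
    des <- pool_design(n_strains = 50L, generations = 5, chip_sd = 0,
                       noise_sd = 0.1, seed = 300 + s)
    tr <- planted_truth("S0001", defect = 3 / 5, des)  # -3 log2
    p <- generate_pool(des, tr)
    vals <- regroup_tags(p$intensity)
    unname(fitness_scores(vals, p$design_table,
                          list(dose_group = "100", generation = 5))["S0001"])
  }, numeric(1))
  expect_gte(mean(scores >= -3.2 & scores <= -2.8), 0.95)
})

test_that("discoveries grow with planted effect size", {
  n_sig <- vapply(c(0.5, 1.5, 3), function(eff) {
    des <- pool_design(n_strains = 200L, generations = 5, seed = 77L,
                       noise_sd = 0.3, chip_sd = 0.1)
    tr <- planted_truth(sprintf("S%04d", 1:20), eff / 5, des)
    p <- generate_pool(des, tr)
    vals <- regroup_tags(p$intensity)
    res <- dssa_significance(vals, p$design_table,
                             list(dose_group = "100", generation = 5))
    sum(res$significant)
  }, numeric(1))
  expect_true(all(diff(n_sig) >= 0))
})

test_that("consensus filter works on long tables and respects sign mode", {
  tab <- data.frame(
    strain = rep(c("g1", "g2", "g3"), each = 6),
    significant = c(rep(TRUE, 4), FALSE, FALSE,   # g1: 4 hits
                    TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,  # g2: 2
                    rep(TRUE, 3), rep(FALSE, 3)),  # g3: 3 (one positive)
    score = c(rep(-1, 6), rep(-1, 6), 2, -1, -1, -1, -1, -1))
  any_mode <- consensus_filter(tab, k_min = 3)
  expect_setequal(any_mode$genes, c("g1", "g3"))
  neg_mode <- consensus_filter(tab, k_min = 3, sign = "negative_only")
  expect_setequal(neg_mode$genes, "g1")

  # fixture layout: the CAT table's resistant gene counts under "any" only
  cat_tab <- read_consensus_fixture("CAT")
  expect_true("YKL133C" %in% consensus_filter(cat_tab, 3)$genes)
  expect_false("YKL133C" %in%
                 consensus_filter(cat_tab, 3, "negative_only")$genes)
})

test_that("planted-hit recovery meets sensitivity/FDP bounds", {
  # 30 planted strains at -2 log2, noise 0.3, 3 treated vs 12 control chips
  sens <- fdp <- numeric(50)
  for (s in 1:50) {
    des <- small_design(n_strains = 300L, seed = 500 + s)
    planted_ids <- sprintf("S%04d", 1:30)
    tr <- planted_truth(planted_ids, 2 / 5, des)
    p <- generate_pool(des, tr)
    vals <- regroup_tags(p$intensity)
    res <- dssa_significance(vals, p$design_table,
                             list(dose_group = "100", generation = 5))
    called <- res$strain[res$significant]
    sens[s] <- mean(planted_ids %in% called)
    fdp[s] <- if (length(called)) mean(!(called %in% planted_ids)) else 0
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdp), 0.1)
})
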
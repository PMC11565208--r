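test_that("average_subsamples collapses to one row per replicate", {
  raw <- data.frame(
    plant_id = rep(c("p1", "p2"), each = 4),
    genotype = "WT",
    density = c(46, 50, 53, 56, 60, 62, 64, 66)
  )
  avg <- average_subsamples(raw, "density", c("plant_id", "genotype"))
  expect_equal(nrow(avg), 2)
  expect_equal(avg$density, c(mean(c(46, 50, 53, 56)), mean(c(60, 62, 64, 66))))
  # single subsample passes through; mixed counts still take plain means
  mixed <- raw[c(1, 5, 6, 7), ]
  avg2 <- average_subsamples(mixed, "density", c("plant_id", "genotype"))
  expect_equal(avg2$density, c(46, 62))
})

test_that("one-way ANOVA reproduces the hand decomposition", {
  d <- data.frame(y = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  a0 <- one_way_anova(d, "y", "g")
  expect_equal(a0$statistic[1], 0)
  expect_equal(a0$p.value[1], 1)
  d2 <- data.frame(y = c(1, 2, 3, 7, 8, 9), g = rep(c("a", "b"), each = 3))
  a2 <- one_way_anova(d2, "y", "g")
  expect_equal(a2$sumsq, c(54, 4))
  expect_equal(a2$df, c(1, 4))
  expect_equal(a2$statistic[1], 54)
  # p-value agrees with direct numerical integration of the F(1, 4) density
  fdens <- function(x) df(x, 1, 4)
  p_int <- integrate(fdens, 54, Inf, rel.tol = 1e-10)$value
  expect_equal(a2$p.value[1], p_int, tolerance = 1e-6)
  empty_level <- data.frame(y = 1:4, g = factor(rep("a", 4), levels = c("a", "b")))
  expect_error(one_way_anova(empty_level, "y", "g"), "no observations")
})

test_that("one-way p-value matches a permutation null", {
  set.seed(17)
  y <- c(rnorm(6, 0), rnorm(6, 0.9), rnorm(6, 0.4))
  g <- factor(rep(c("a", "b", "c"), each = 6))
  p_f <- one_way_anova(data.frame(y = y, g = g), "y", "g")$p.value[1]
  p_perm <- perm_oneway_p(y, g, n_perm = 20000)
  expect_lt(abs(p_f - p_perm), 0.02)
})

test_that("two-way ANOVA handles interaction structure", {
  # balanced 2x2, additive cell means, no noise -> interaction SS exactly 0
  add <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:2)
  add$y <- ifelse(add$A == "a2", 3, 0) + ifelse(add$B == "b2", 5, 0)
  a_add <- two_way_anova(add, "y", "A", "B")
  expect_equal(a_add$sumsq[a_add$term == "A:B"], 0, tolerance = 1e-10)
  # {0,0;0,delta} pattern at delta = 4, n = 2: interaction partial SS = 8
  dd <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:2)
  dd$y <- ifelse(dd$A == "a2" & dd$B == "b2", 4, 0)
  a_int <- two_way_anova(dd, "y", "A", "B")
  expect_equal(a_int$sumsq[a_int$term == "A:B"], 8)
  # empty cell with interaction requested
  holey <- dd[!(dd$A == "a1" & dd$B == "b1"), ]
  expect_error(two_way_anova(holey, "y", "A", "B"), "empty cell")
})

test_that("Type-III partial SS equal classical sequential SS when balanced", {
  set.seed(23)
  d <- expand.grid(A = c("a1", "a2", "a3"), B = c("b1", "b2"), rep = 1:4)
  d$y <- rnorm(nrow(d)) + as.numeric(d$A) + 2 * (d$B == "b2")
  ours <- two_way_anova(d, "y", "A", "B")
  seq_ss <- anova(lm(y ~ A * B, data = d))
  expect_equal(ours$sumsq, seq_ss$`Sum Sq`, tolerance = 1e-10)
  expect_equal(ours$p.value, seq_ss$`Pr(>F)`, tolerance = 1e-10)
})

test_that("ANOVA sums of squares add to the total (balanced)", {
  set.seed(29)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"), rep = 1:3)
  d$y <- rnorm(nrow(d))
  ours <- two_way_anova(d, "y", "A", "B")
  expect_equal(sum(ours$sumsq), sum((d$y - mean(d$y))^2), tolerance = 1e-10)
})

test_that("repeated-measures ANOVA uses the split-plot-in-time strata", {
  # identical trajectories in both genotypes (subjects offset): genotype and
  # interaction F are exactly 0
  d <- expand.grid(subject = paste0("s", 1:6), day = 1:4)
  d$genotype <- ifelse(d$subject %in% paste0("s", 1:3), "WT", "mut")
  traj <- c(90, 70, 45, 20)
  off <- stats::setNames(c(-1, 0, 1, -1, 0, 1), paste0("s", 1:6))
  d$y <- traj[d$day] + off[as.character(d$subject)]
  a <- repeated_measures_anova(d, "y", "genotype", "day", "subject")
  expect_equal(a$statistic[a$term == "genotype"], 0, tolerance = 1e-10)
  # the within-stratum residual is also exactly 0 here, so check the SS
  expect_equal(a$sumsq[a$term == "genotype:day"], 0, tolerance = 1e-10)
  expect_true(a$stratum[a$term == "genotype"] == "subject")
  # diverging trajectories: strong genotype x day signal
  set.seed(37)
  d2 <- expand.grid(subject = paste0("s", 1:10), day = 1:5)
  d2$genotype <- ifelse(d2$subject %in% paste0("s", 1:5), "WT", "mut")
  slope <- ifelse(d2$genotype == "WT", -15, -5)
  d2$y <- 100 + slope * d2$day + rnorm(nrow(d2), 0, 3)
  a2 <- repeated_measures_anova(d2, "y", "genotype", "day", "subject")
  expect_lt(a2$p.value[a2$term == "genotype:day"], 0.05)
  # subject missing a day
  expect_error(repeated_measures_anova(d[-1, ], "y", "genotype", "day", "subject"),
               "incomplete")
})

test_that("Tukey HSD satisfies the two-group t-test identity", {
  set.seed(41)
  d <- data.frame(y = c(rnorm(8, 0), rnorm(8, 1)),
                  g = rep(c("a", "b"), each = 8))
  tk <- tukey_hsd(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tk$comparisons$q, sqrt(2) * abs(tt$statistic[[1]]),
               tolerance = 1e-6)
  expect_equal(tk$comparisons$p.adj, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey HSD agrees with stats::TukeyHSD on a balanced design", {
  set.seed(43)
  d <- data.frame(y = rnorm(24, rep(c(0, 0.5, 2), each = 8)),
                  g = rep(c("a", "b", "c"), each = 8))
  tk <- tukey_hsd(d, "y", "g")
  ref <- TukeyHSD(aov(y ~ g, data = d))$g
  # reference orders pairs as b-a, c-a, c-b with sign reversed vs group1-group2
  expect_equal(unname(tk$comparisons$p.adj), unname(ref[, "p adj"]),
               tolerance = 1e-8)
  expect_equal(unname(tk$comparisons$diff), unname(-ref[, "diff"]),
               tolerance = 1e-10)
})

test_that("Tukey letters separate a strongly shifted group", {
  set.seed(47)
  d <- data.frame(y = c(rnorm(6, 0, 1), rnorm(6, 0.2, 1), rnorm(6, 10, 1)),
                  g = rep(c("a", "b", "c"), each = 6))
  tk <- tukey_hsd(d, "y", "g")
  lett <- tk$groups
  expect_false(lett$letters[lett$group == "c"] %in%
                 lett$letters[lett$group != "c"])
  # identical data in every group: all adjusted p = 1
  d2 <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  tk2 <- tukey_hsd(d2, "y", "g")
  expect_true(all(tk2$comparisons$p.adj == 1))
  expect_true(all(tk2$groups$letters == "a"))
})

test_that("least-squares means match closed forms", {
  d <- data.frame(y = c(1, 2, 3, 7, 8, 9), g = rep(c("a", "b"), each = 3))
  ls1 <- lsmeans_se(d, "y", "g")
  expect_equal(ls1$lsmean, c(2, 8))
  msw <- 1  # pooled within-group variance
  expect_equal(ls1$se, rep(sqrt(msw / 3), 2))
  # unbalanced two-way: marginal lsmean is the unweighted mean of cell means
  ub <- data.frame(
    A = c("a1", "a1", "a1", "a1", "a1", "a1", "a2", "a2", "a2", "a2"),
    B = c("b1", "b1", "b2", "b2", "b2", "b2", "b1", "b1", "b2", "b2"),
    y = c(1, 3, 10, 10, 12, 12, 5, 7, 20, 22)
  )
  lsA <- lsmeans_se(ub, "y", "A", model_factors = c("A", "B"))
  cell_means <- aggregate(y ~ A + B, ub, mean)
  unweighted <- tapply(cell_means$y, cell_means$A, mean)
  expect_equal(lsA$lsmean, as.vector(unweighted))
  raw_marginal <- tapply(ub$y, ub$A, mean)
  expect_false(isTRUE(all.equal(lsA$lsmean, as.vector(raw_marginal))))
})

test_that("planned contrasts reproduce the pooled t-test and arithmetic", {
  set.seed(53)
  d <- data.frame(y = c(rnorm(7, 0), rnorm(7, 1)),
                  g = rep(c("a", "b"), each = 7))
  pc <- planned_contrast(d, "y", "g", c(a = 1, b = -1))
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(pc$statistic, tt$statistic[[1]], tolerance = 1e-8)
  expect_equal(pc$p.value, tt$p.value, tolerance = 1e-8)
  d3 <- data.frame(y = c(10, 12, 5, 7, 3, 5),
                   g = rep(c("WT", "l1", "l2"), each = 2))
  pc3 <- planned_contrast(d3, "y", "g", c(WT = 1, l1 = -0.5, l2 = -0.5))
  expect_equal(pc3$estimate, 11 - 0.5 * (6 + 4))
  expect_error(planned_contrast(d, "y", "g", c(a = 1, b = 1)), "sum to zero")
})

test_that("per-day Tukey flags the days on which genotypes separate", {
  set.seed(59)
  d <- expand.grid(pot = 1:6, day = 1:3)
  d$genotype <- ifelse(d$pot <= 3, "WT", "mut")
  shift <- c(0, 0, 8)  # genotypes separate only on day 3
  d$rswc <- 50 + shift[d$day] * (d$genotype == "mut") + rnorm(nrow(d), 0, 0.5)
  flags <- per_day_tukey(d, "rswc", "genotype")
  expect_equal(nrow(flags), 3)
  expect_false(flags$significant[flags$day == 1])
  expect_true(flags$significant[flags$day == 3])
})
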
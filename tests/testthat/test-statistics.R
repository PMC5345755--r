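make_ratings <- function(a, b, scale = "THREE_POINT") {
  rating_table(sprintf("C%03d", seq_along(a)), "PILOCYTIC", scale, a, b)
}

test_that("weighted kappa hits its analytic anchor points", {
  # perfect agreement over >= 2 categories
  k <- weighted_kappa(make_ratings(c(0, 1, 2, 3, 1, 2), c(0, 1, 2, 3, 1, 2)))
  expect_equal(k$kappa, 1)
  # degenerate point marginals: observed = expected pattern, kappa 0
  k0 <- weighted_kappa(make_ratings(rep(0L, 6), rep(1L, 6)))
  expect_equal(k0$kappa, 0)
  expect_error(weighted_kappa(make_ratings(rep(1L, 5), rep(1L, 5))),
               "fewer than 2")
})

test_that("weighted kappa agrees with an external reference", {
  # frozen from statsmodels.stats.inter_rater.cohens_kappa(wt='quadratic')
  # on this exact table (see the 40-pair fixture below)
  set.seed(7)
  a <- sample(0:3, 40, replace = TRUE, prob = c(.1, .3, .4, .2))
  b <- pmin(pmax(a + sample(-1:1, 40, replace = TRUE,
                            prob = c(.25, .5, .25)), 0), 3)
  k <- weighted_kappa(make_ratings(a, b))
  expect_equal(k$kappa, 0.7861635220, tolerance = 1e-9)
  expect_equal(k$z, 5.039319, tolerance = 1e-6)
  expect_equal(k$p, 4.67191e-07, tolerance = 1e-4)
  expect_equal(k$n_items, 40L)
  expect_equal(k$interpretation, "Substantial Agreement")
})

test_that("weighted kappa matches the definitional summation oracle", {
  set.seed(71)
  for (i in 1:20) {
    scale <- if (i %% 2 == 0) "THREE_POINT" else "FOUR_POINT"
    cats <- if (scale == "THREE_POINT") 0:3 else 0:4
    a <- sample(cats, 200, replace = TRUE)
    b <- pmin(pmax(a + sample(-2:2, 200, replace = TRUE,
                              prob = c(.1, .2, .4, .2, .1)),
                   0), max(cats))
    k <- weighted_kappa(make_ratings(a, b, scale), scale = scale)
    expect_equal(k$kappa, oracle_weighted_kappa(a, b, cats),
                 tolerance = 1e-10)
  }
})

test_that("squared weights reduce to unweighted kappa when flattened", {
  set.seed(72)
  a <- sample(0:3, 60, replace = TRUE)
  b <- sample(0:3, 60, replace = TRUE)
  if (length(unique(c(a, b))) < 2) a[1] <- 1L
  ku <- weighted_kappa(make_ratings(a, b), weighting = "unweighted")
  po <- mean(a == b)
  pe <- sum((table(factor(a, levels = 0:3)) / 60) *
              (table(factor(b, levels = 0:3)) / 60))
  expect_equal(ku$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
})

test_that("kappa is invariant to item order", {
  set.seed(73)
  a <- sample(0:4, 50, replace = TRUE)
  b <- sample(0:4, 50, replace = TRUE)
  perm <- sample(50)
  k1 <- weighted_kappa(make_ratings(a, b, "FOUR_POINT"))
  k2 <- weighted_kappa(make_ratings(a[perm], b[perm], "FOUR_POINT"))
  expect_equal(k1$kappa, k2$kappa)
  expect_equal(k1$z, k2$z)
})

test_that("agreement bands follow Landis-Koch with closed upper ends", {
  expect_equal(classify_agreement(c(-0.1, 0.1, 0.2, 0.3, 0.4, 0.5,
                                    0.6, 0.7, 0.8, 0.9)),
               c("Poor", "Slight Agreement", "Slight Agreement",
                 "Fair Agreement", "Fair Agreement",
                 "Moderate Agreement", "Moderate Agreement",
                 "Substantial Agreement", "Substantial Agreement",
                 "Almost Perfect Agreement"))
  expect_error(classify_agreement(1.2), "exceed")
})

test_that("concordance is a strict <1 point rule", {
  expect_equal(concordance_classify(2, 2), "CONCORDANT")
  expect_equal(concordance_classify(1, 2), "DISCORDANT")
  expect_equal(concordance_classify(2, 2.5), "CONCORDANT")
  set.seed(74)
  a <- sample(0:4, 100, replace = TRUE)
  b <- sample(0:4, 100, replace = TRUE)
  expect_equal(concordance_classify(a, b),
               ifelse(abs(a - b) < 1, "CONCORDANT", "DISCORDANT"))
})

test_that("discordance chi-square matches the closed form", {
  expect_equal(chi_square_discordance(c(30, 10), c(30, 10)), 1)
  # hand-computed Pearson statistic for (50,50) vs (90,10)
  m <- rbind(c(50, 50), c(90, 10))
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  expect_equal(chi_square_discordance(c(50, 50), c(90, 10)),
               pchisq(stat, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(chi_square_discordance(c(0, 0), c(5, 5)), "margin")
})

test_that("Tukey HSD p-values match the studentized-range oracle", {
  # identical groups: zero differences, all p = 1
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("REACTIVE", "RECURRENT_GB", "DE_NOVO_GB"), each = 4)
  cmp <- anova_tukey(v, g)
  expect_equal(cmp$p_adjusted, rep(1, 3))
  expect_equal(cmp$diff, rep(0, 3))

  # overwhelming two-group separation
  set.seed(75)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 10, 1)
  cmp2 <- anova_tukey(c(a, b), rep(c("A", "B"), each = 20))
  expect_lt(cmp2$p_adjusted, 1e-6)

  # unbalanced 4-group design vs independent Tukey-Kramer formula
  set.seed(76)
  vals <- c(rnorm(8, 0), rnorm(12, 0.5), rnorm(10, 1), rnorm(15, 0.2))
  grps <- rep(c("w", "x", "y", "z"), c(8, 12, 10, 15))
  cmp3 <- anova_tukey(vals, grps)
  for (i in seq_len(nrow(cmp3))) {
    expect_equal(cmp3$p_adjusted[i],
                 oracle_tukey_p(vals, grps, cmp3$group_a[i],
                                cmp3$group_b[i]),
                 tolerance = 1e-8)
  }
  expect_error(anova_tukey(c(1, 1, 1, 1), rep(c("a", "b"), each = 2)),
               "variance")
})

test_that("pooled t-test matches the textbook closed form", {
  same <- t_test_homoscedastic(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- t_test_homoscedastic(c(1, 2, 3), c(1, 2, 3) + 100)
  expect_lt(shifted$p, 1e-6)
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    got <- t_test_homoscedastic(a, b)
    want <- oracle_pooled_t(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(t_test_homoscedastic(c(1, 1), c(1, 1)), "variance")
})

test_that("rater averaging is the per-case arithmetic mean", {
  rt <- rating_table(c("a", "b"), "REACTIVE", "THREE_POINT",
                     c(2, 0), c(3, 0))
  avg <- average_raters(rt)
  expect_equal(avg$mean_score, c(2.5, 0))
  set.seed(78)
  a <- sample(0:3, 10, replace = TRUE)
  b <- sample(0:3, 10, replace = TRUE)
  rt2 <- make_ratings(a, b)
  expect_equal(average_raters(rt2)$mean_score[order(rt2$case_id)],
               ((a + b) / 2)[order(rt2$case_id)])
})

test_that("rating tables validate scores against their scale", {
  expect_error(rating_table("c1", "REACTIVE", "THREE_POINT", 4, 1),
               "out of range")
  expect_silent(rating_table("c1", "REACTIVE", "FOUR_POINT", 4, 1))
  expect_error(rating_table("c1", "REACTIVE", "FIVE_POINT", 1, 1),
               "scale")
})
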
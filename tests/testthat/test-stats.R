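test_that("exact Mann-Whitney p equals the permutation distribution", {
  set.seed(10)
  for (i in 1:10) {
    n1 <- sample(3:7, 1)
    n2 <- sample(3:7, 1)
    v <- sample(1000, n1 + n2) # distinct -> no ties
    x <- v[seq_len(n1)]
    y <- v[-seq_len(n1)]
    mw <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(mw$p, perm_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney mode selection and tie handling", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 5, 6, 7) # tie at 2
  expect_error(mann_whitney_u(x, y, mode = "exact"), "ties")
  mw <- mann_whitney_u(x, y) # auto -> asymptotic because of ties
  expect_equal(mw$method, "mann-whitney-asymptotic")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(mw$p, ref$p.value)
  expect_error(mann_whitney_u(1, c(1, 2)), "at least 2")
  # fully tied samples are degenerate, not an error
  expect_equal(mann_whitney_u(c(1, 1), c(1, 1))$p, 1)
})

test_that("Kruskal-Wallis reproduces a hand-computed example", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(g)
  # ranks 1..9, mean ranks 2/5/8: H = 12/(9*10) * 3*((3)^2 + 0 + 3^2) = 7.2
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$p, pchisq(7.2, df = 2, lower.tail = FALSE))
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p, 1)
  expect_error(kruskal_wallis(list(c(1, 2))), "2")
})

test_that("Pearson correlation matches the t-transform", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.2, 1.9, 3.3, 3.8, 5.1)
  pc <- pearson_correlation(x, y)
  expect_equal(pc$statistic, cor(x, y))
  r <- cor(x, y)
  tt <- r * sqrt(3 / (1 - r^2))
  expect_equal(pc$p, 2 * pt(abs(tt), df = 3, lower.tail = FALSE))
  expect_error(pearson_correlation(1:2, 1:2), "size >= 3")
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "zero variance")
})

test_that("pooled level means reduce to the mean under equal n", {
  expect_equal(pool_level_means(c(34.3, 32.8, 39.0), digits = 1), 35.4)
  expect_equal(pool_level_means(c(0.207, 0.251, 0.304), digits = 3), 0.254)
  expect_equal(pool_level_means(c(1, 2)), 1.5)
})

test_that("study summaries assign significance letters between levels", {
  set.seed(1)
  mk <- function(g, l, mu) data.frame(
    specimen = paste0(g, "_", 1:6), group = g, level = l, parameter = "bv_tv",
    value = mu + runif(6, -0.5, 0.5))
  data <- rbind(mk("sham", "L4", 10), mk("sham", "L5", 10), mk("sham", "L6", 30),
                mk("ovx", "L4", 5), mk("ovx", "L5", 5), mk("ovx", "L6", 5))
  sm <- summarize_study(data)
  cells <- sm$cells
  l6 <- cells$letters[cells$group == "sham" & cells$level == "L6"]
  expect_true(grepl("a", l6) && grepl("b", l6)) # differs from L4 and L5
  l4 <- cells$letters[cells$group == "sham" & cells$level == "L4"]
  expect_true(grepl("c", l4) && !grepl("b", l4))
  expect_equal(cells$letters[cells$group == "ovx"], rep("", 3))
  # between-group tests significant at every level
  expect_true(all(sm$between_group$p_value < 0.05))
  # totals pool all specimens of a group
  expect_equal(sm$totals$mean[sm$totals$group == "sham"],
               mean(data$value[data$group == "sham"]))
})

test_that("study summaries are invariant to record order", {
  set.seed(2)
  data <- data.frame(
    specimen = rep(sprintf("s%02d", 1:8), each = 2),
    group = rep(c("a", "b"), each = 8),
    level = "L4",
    parameter = rep(c("bv_tv", "fd"), times = 8),
    value = rnorm(16))
  s1 <- summarize_study(data)
  s2 <- summarize_study(data[sample(nrow(data)), ])
  expect_equal(s1$cells, s2$cells)
  expect_equal(s1$between_group, s2$between_group)
})

test_that("duplicate or incomplete records are rejected", {
  bad <- data.frame(specimen = c("s1", "s1"), group = "a", level = "L4",
                    parameter = "bv_tv", value = c(1, 2))
  expect_error(summarize_study(bad), "duplicate")
  expect_error(summarize_study(data.frame(specimen = "s1", value = 1)),
               "missing columns")
})
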
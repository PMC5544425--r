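test_that("relative fitness is the observed fraction over the null fraction", {
  expect_equal(relative_fitness(60, 150), 0.8)   # 40% mutants -> F = 0.8
  expect_equal(relative_fitness(75, 150), 1.0)
  expect_equal(relative_fitness(0, 150), 0)
  expect_error(relative_fitness(10, 0), "positive")
  expect_error(relative_fitness(200, 150), "mutant_count")
})

test_that("multiplicative null and synthetic effect arithmetic", {
  expect_equal(expected_double_fitness(1, 1), 1)
  expect_equal(expected_double_fitness(0.8, 1), 0.8)
  expect_equal(expected_double_fitness(0.8, 0.9), 0.72)
  expect_error(expected_double_fitness(-0.1, 1), "non-negative")

  expect_equal(synthetic_effect(0.7, 0.7), 0)
  expect_equal(synthetic_effect(0, 0.58), -0.58)
  # antisymmetry under exchanging the two roles
  set.seed(3)
  a <- runif(20); b <- runif(20)
  expect_equal(synthetic_effect(a, b), -synthetic_effect(b, a))
})

test_that("pair enumeration counts n(n-1)/2 unordered pairs", {
  expect_equal(nrow(enumerate_pairs(sprintf("g%02d", 1:13))), 78)
  expect_equal(nrow(enumerate_pairs(sprintf("g%02d", 1:14))), 91)
  expect_equal(nrow(enumerate_pairs(c("a", "b"))), 1)
  expect_error(enumerate_pairs(c("a", "a", "b")), "distinct")
  p <- enumerate_pairs(letters[1:5])
  expect_false(any(duplicated(paste(pmin(p$gene_a, p$gene_b),
                                    pmax(p$gene_a, p$gene_b)))))
})

test_that("plate validation enforces the schema and flags small plates", {
  plates <- data.frame(genotype_id = "g1", replicate_id = "r1",
                       mutant_count = 40, total_count = 100)
  expect_warning(validate_plates(plates), "150")
  plates$total_count <- 200
  expect_silent(validate_plates(plates))
  expect_error(validate_plates(plates[, -1]), "missing columns")
})

test_that("fitness estimation pools replicate counts", {
  plates <- data.frame(
    genotype_id = "g1", replicate_id = c("r1", "r2", "r3"),
    mutant_count = c(80, 90, 70), total_count = c(200, 200, 200)
  )
  est <- fitness_estimate(plates)
  expect_equal(est$F, (240 / 600) / 0.5)
  expect_equal(est$per_replicate_F, c(0.8, 0.9, 0.7))
  expect_equal(est$n_replicates, 3)
})

test_that("a no-interaction double gives epsilon 0, p 1, category none", {
  fit_a <- fitness_estimate(data.frame(
    genotype_id = "a", replicate_id = c("r1", "r2"),
    mutant_count = c(80, 80), total_count = c(200, 200)))
  fit_b <- fitness_estimate(data.frame(
    genotype_id = "b", replicate_id = c("r1", "r2"),
    mutant_count = c(100, 100), total_count = c(200, 200)))
  # double at exactly F_exp * null_fraction = 0.8 * 0.5 = fraction 0.4
  dbl <- data.frame(genotype_id = "a;b", replicate_id = c("r1", "r2"),
                    mutant_count = c(80, 80), total_count = c(200, 200))
  res <- call_interaction(dbl, fit_a, fit_b, m_tests = 78)
  expect_equal(res$epsilon, 0)
  expect_equal(res$p_raw, 1)
  expect_equal(res$category, "none")
  expect_false(res$significant)
})

test_that("a strong planted aggravating interaction is called significant", {
  # singles at F = 1, double at true fraction 0.1 (F_obs = 0.2, eps = -0.8)
  fit_a <- fitness_estimate(data.frame(
    genotype_id = "a", replicate_id = paste0("r", 1:3),
    mutant_count = rep(100, 3), total_count = rep(200, 3)))
  fit_b <- fitness_estimate(data.frame(
    genotype_id = "b", replicate_id = paste0("r", 1:3),
    mutant_count = rep(100, 3), total_count = rep(200, 3)))
  set.seed(17)
  dbl <- data.frame(genotype_id = "a;b", replicate_id = paste0("r", 1:3),
                    mutant_count = rbinom(3, 200, 0.1),
                    total_count = rep(200, 3))
  res <- call_interaction(dbl, fit_a, fit_b, m_tests = 78)
  expect_true(res$significant)
  expect_equal(res$category, "aggravating")
  expect_lt(res$epsilon, -0.5)
})

test_that("epsilon below the 0.20 threshold is never significant", {
  fit <- fitness_estimate(data.frame(
    genotype_id = "a", replicate_id = paste0("r", 1:3),
    mutant_count = rep(100, 3), total_count = rep(200, 3)))
  # F_obs = 0.9, F_exp = 1: eps = -0.1, huge counts make the test powered
  dbl <- data.frame(genotype_id = "a;a2", replicate_id = paste0("r", 1:3),
                    mutant_count = rep(900, 3), total_count = rep(2000, 3))
  res <- suppressWarnings(call_interaction(dbl, fit, fit, m_tests = 1))
  expect_lt(res$p_adj, 0.01)           # statistically clear difference
  expect_false(res$significant)        # but blocked by the effect threshold
  expect_equal(res$category, "none")
})

test_that("zero surviving double homozygotes are recorded as lethal", {
  fit <- fitness_estimate(data.frame(
    genotype_id = "a", replicate_id = paste0("r", 1:3),
    mutant_count = rep(100, 3), total_count = rep(200, 3)))
  dbl <- data.frame(genotype_id = "a;b", replicate_id = paste0("r", 1:3),
                    mutant_count = rep(0, 3), total_count = rep(200, 3))
  res <- call_interaction(dbl, fit, fit, m_tests = 78)
  expect_equal(res$category, "lethal")
  expect_equal(res$F_obs, 0)
  expect_true(is.na(res$p_raw))
  expect_true(res$significant)         # F_exp = 1 >= threshold
})

test_that("interaction summary reports rate, degree, matrix and edges", {
  results <- data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    F_obs = c(0.5, 1, 0), F_exp = c(1, 1, 0.9),
    epsilon = c(-0.5, 0, -0.9),
    p_raw = c(1e-6, 0.5, NA), p_adj = c(1e-4, 1, NA),
    n_replicates = 3,
    significant = c(TRUE, FALSE, TRUE),
    category = c("aggravating", "none", "lethal"),
    stringsAsFactors = FALSE
  )
  s <- interaction_summary(results)
  expect_equal(s$n_tested, 3)
  expect_equal(s$n_significant, 2)     # lethal counts as an interaction
  expect_equal(s$rate, 2 / 3)
  expect_equal(unname(s$degree[c("a", "b", "c")]), c(1, 2, 1))
  expect_true(s$lethal_matrix["b", "c"] && s$lethal_matrix["c", "b"])
  expect_equal(s$epsilon_matrix["a", "b"], -0.5)
  expect_equal(s$epsilon_matrix["b", "a"], -0.5)
  expect_equal(nrow(s$edges), 2)

  # screen-scale arithmetic: 11 of 78 pairs is ~14%
  fake <- data.frame(
    gene_a = sprintf("p%02d", 1:78), gene_b = sprintf("q%02d", 1:78),
    F_obs = 1, F_exp = 1, epsilon = 0, p_raw = 1, p_adj = 1,
    n_replicates = 3, significant = c(rep(TRUE, 11), rep(FALSE, 67)),
    category = c(rep("aggravating", 11), rep("none", 67)),
    stringsAsFactors = FALSE
  )
  expect_equal(interaction_summary(fake)$rate, 11 / 78)
  expect_equal(round(100 * interaction_summary(fake)$rate), 14)
})

test_that("simulated plates recover the true fitness", {
  # binomial SE at 600 pooled worms is ~0.04 in F units
  set.seed(101)
  for (f_true in c(0.2, 0.5, 0.8, 1.0)) {
    hits <- replicate(200, {
      m <- rbinom(1, 600, f_true / 2)
      abs(relative_fitness(m, 600) - f_true) < 0.1
    })
    expect_gte(mean(hits), 0.95)
  }
})
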
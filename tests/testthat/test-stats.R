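# hand-built per-animal normalized table: two groups, one tissue
make_norm <- function(values_by_species, group_sizes = c(control = 4, treated = 4)) {
  dplyr::bind_rows(lapply(names(values_by_species), function(sp) {
    v <- values_by_species[[sp]]
    tibble::tibble(
      animal_id = c(sprintf("c%02d", seq_len(group_sizes[["control"]])),
                    sprintf("t%02d", seq_len(group_sizes[["treated"]]))),
      group = rep(c("control", "treated"), group_sizes),
      tissue = "liver", species = sp, lipid_class = "TAG",
      value = v
    )
  }))
}

test_that("fold change and p behave correctly in degenerate two-group settings", {
  same <- make_norm(list("TAG 48:0" = c(2, 2, 2, 2, 2, 2, 2, 2)))
  st <- species_stats(same)
  expect_equal(st$fc, 1)
  expect_equal(st$p, 1)

  doubled <- make_norm(list("TAG 48:0" = c(1, 1, 1, 1, 2, 2, 2, 2)))
  st <- species_stats(doubled)
  expect_equal(st$fc, 2)
  expect_equal(st$p, 0)
  expect_equal(st$direction, "increased")
})

test_that("species t-test p-values agree with stats::t.test to 1e-10", {
  set.seed(314)
  for (rep in 1:5) {
    vals <- lapply(1:40, function(i) exp(rnorm(8, sd = 0.3)))
    names(vals) <- paste0("TAG ", 40 + 2 * (1:40), ":0")
    norm <- make_norm(vals)
    st <- species_stats(norm)
    oracle <- oracle_t_p(norm)
    expect_lt(max(abs(st$p - oracle[st$species])), 1e-10)
    welch <- species_stats(norm, var_equal = FALSE)
    oracle_w <- oracle_t_p(norm, var_equal = FALSE)
    expect_lt(max(abs(welch$p - oracle_w[welch$species])), 1e-10)
  }
})

test_that("preconditions are enforced: group sizes and nonzero control mean", {
  small <- make_norm(list("TAG 48:0" = c(1, 1, 2)),
                     group_sizes = c(control = 1, treated = 2))
  expect_error(species_stats(small), ">= 2 animals")
  zero <- make_norm(list("TAG 48:0" = c(0, 0, 0, 0, 1, 1, 1, 1)))
  expect_error(species_stats(zero), "control mean is zero")
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  st <- make_norm(list("TAG 48:0" = rnorm(8) + 10,
                       "TAG 50:1" = rnorm(8) + 10,
                       "TAG 50:2" = rnorm(8) + 10))
  st <- species_stats(st)
  st$p <- c(0.01, 0.02, 0.03)
  q <- bh_fdr(st)$q
  expect_equal(q, c(0.03, 0.03, 0.03))

  st1 <- st[1, ]
  st1$p <- 0.2
  expect_equal(bh_fdr(st1)$q, 0.2)

  st$p <- c(1.2, 0.5, 0.5)
  expect_error(bh_fdr(st), "\\[0, 1\\]")
})

test_that("BH q-values are monotone in p, at least p, and at most 1", {
  set.seed(99)
  for (rep in 1:20) {
    m <- sample(1:50, 1)
    st <- tibble::tibble(tissue = "liver", scale = "raw",
                         p = runif(m)^sample(1:3, 1))
    q <- bh_fdr(st)$q
    expect_true(all(q >= st$p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(st$p)]) >= -1e-15))
  }
})

test_that("the effect threshold is the mean species SEM of the family", {
  st <- make_norm(list("TAG 48:0" = rnorm(8) + 10,
                       "TAG 50:1" = rnorm(8) + 10))
  st <- species_stats(st)
  st$sem_fc <- c(0.02, 0.04)
  expect_equal(effect_threshold(st), 0.03)
  st$sem_fc <- c(0.05, 0.05)
  expect_equal(effect_threshold(st), 0.05)
  two_fam <- dplyr::bind_rows(st, dplyr::mutate(st, scale = "class_fraction"))
  expect_error(effect_threshold(two_fam), "single tissue")
})

test_that("volcano categories partition species by the dual p/effect filter", {
  st <- make_norm(list("TAG 48:0" = rnorm(8) + 10))
  st <- species_stats(st)
  grid <- tidyr::expand_grid(p = c(0.01, 0.20), fc = c(1.5, 1.05))
  for (i in seq_len(nrow(grid))) {
    st$p <- grid$p[i]
    st$fc <- grid$fc[i]
    cat_i <- volcano_categorize(st, alpha = 0.05, threshold = 0.1)$category
    expected <- if (grid$p[i] < 0.05 && abs(grid$fc[i] - 1) > 0.1) {
      "SIGNIFICANT_EFFECT"
    } else if (grid$p[i] < 0.05) {
      "SIGNIFICANT_ONLY"
    } else if (abs(grid$fc[i] - 1) > 0.1) {
      "EFFECT_ONLY"
    } else "UNCHANGED"
    expect_equal(cat_i, expected)
  }
})

test_that("every species lands in exactly one volcano category", {
  cfg <- simulation_config(panel = null_panel(300),
                           effects = c(C1 = 2, C2 = 0.5), seed = 8)
  st <- quick_stats(generate_dataset(cfg)$raw, null_panel(300))
  st <- volcano_categorize(st)
  expect_equal(nrow(st), 300)
  expect_true(all(st$category %in% c("UNCHANGED", "EFFECT_ONLY",
                                     "SIGNIFICANT_ONLY", "SIGNIFICANT_EFFECT")))
  expect_equal(sum(table(st$category)), 300)
})

test_that("class summaries report treated totals as percent of control", {
  same <- make_norm(list("TAG 48:0" = rep(2, 8), "TAG 50:1" = rep(1, 8)))
  cs <- class_summary(same, tiny_panel())
  expect_equal(cs$percent_of_control[cs$group_label == "TAG"], 100)
  expect_equal(cs$p_one_sample[cs$group_label == "TAG"], 1)

  up <- make_norm(list("TAG 48:0" = c(1, 1, 1, 1, 1.27, 1.27, 1.27, 1.27)))
  cs <- class_summary(up, tiny_panel())
  expect_equal(cs$percent_of_control[cs$group_label == "TAG"], 127)
})

test_that("class percent recovers a uniform spike within sampling error", {
  panel <- tiny_panel()
  effects <- stats::setNames(
    rep(1.4, sum(panel$species$lipid_class == "TAG")),
    panel$species$canonical_label[panel$species$lipid_class == "TAG"]
  )
  cfg <- tiny_config(effects = effects, matrix_drift = 0, seed = 31)
  norm <- average_duplicates(normalize_to_standard(generate_dataset(cfg)$raw, panel))
  cs <- class_summary(norm, panel)
  # 3 Monte-Carlo SDs of the ratio of two 6-animal means at 10% biological CV
  mc_tol <- 3 * 0.10 * sqrt(2 / 6)
  expect_equal(cs$percent_of_control[cs$group_label == "TAG"], 140,
               tolerance = mc_tol)
})

test_that("carnitine subgroups split into free, acetyl and propionyl-plus", {
  panel <- build_default_panel()
  cfg <- simulation_config(panel = panel, noise_cv = 0, tech_cv = 0,
                           baseline_log_sd = 0, matrix_drift = 0, seed = 1)
  norm <- average_duplicates(normalize_to_standard(generate_dataset(cfg)$raw, panel))
  cs <- class_summary(norm, panel)
  expect_true(all(c("CARNITINE_FREE", "CARNITINE_ACETYL", "CARNITINE_ACYL") %in%
                    cs$group_label))
  expect_equal(cs$n_species[cs$group_label == "CARNITINE_FREE"], 1)
  expect_equal(cs$n_species[cs$group_label == "CARNITINE_ACETYL"], 1)
  expect_equal(cs$n_species[cs$group_label == "CARNITINE_ACYL"], 39)
})

test_that("direction counts use the exact binomial test and drop fc = 1 ties", {
  st <- make_norm(as.list(stats::setNames(
    replicate(10, rnorm(8) + 10, simplify = FALSE),
    paste0("TAG ", 2 * (20:29), ":0")
  )))
  st <- species_stats(st)
  st$p <- 0.01
  st$fc <- c(rep(1.5, 5), rep(0.5, 5))
  st$direction <- ifelse(st$fc > 1, "increased", "decreased")
  st <- volcano_categorize(st, threshold = 0.1)
  dc <- direction_counts(st)
  expect_equal(dc$n_increased, 5)
  expect_equal(dc$n_decreased, 5)
  expect_equal(dc$binomial_p, 1.0)

  st$fc <- c(rep(1.5, 9), 0.5)
  st$direction <- ifelse(st$fc > 1, "increased", "decreased")
  st <- volcano_categorize(st, threshold = 0.1)
  dc <- direction_counts(st)
  expect_equal(dc$binomial_p, 0.021484375)

  # a tied species contributes to neither count
  st$fc[1] <- 1
  st$direction[1] <- NA
  dc <- direction_counts(volcano_categorize(st, threshold = 0.1))
  expect_equal(dc$n_increased + dc$n_decreased, 9)

  empty <- direction_counts(volcano_categorize(st, threshold = 10), "SIGNIFICANT_EFFECT")
  expect_equal(empty$n_increased + empty$n_decreased, 0)
  expect_equal(empty$binomial_p, 1)
})

test_that("the exact binomial test equals brute-force pmf summation for n <= 25", {
  for (n in 1:25) {
    for (k in 0:n) {
      expect_equal(stats::binom.test(k, n, 0.5)$p.value,
                   oracle_binom_p(k, n), tolerance = 1e-12,
                   info = sprintf("k=%d n=%d", k, n))
    }
  }
})

test_that("cross-tissue direction comparison is a Fisher exact test on the 2x2 table", {
  a <- structure(list(tier = "SIGNIFICANT_EFFECT", n_increased = 67,
                      n_decreased = 10, binomial_p = NA), class = "direction_counts")
  b <- structure(list(tier = "SIGNIFICANT_EFFECT", n_increased = 7,
                      n_decreased = 2, binomial_p = NA), class = "direction_counts")
  expect_equal(direction_contrast(a, b),
               stats::fisher.test(matrix(c(67, 10, 7, 2), 2))$p.value)
  z <- structure(list(tier = "x", n_increased = 0, n_decreased = 0,
                      binomial_p = 1), class = "direction_counts")
  expect_equal(direction_contrast(z, z), 1)
})
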
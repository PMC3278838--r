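test_that("f_score matches a direct-formula oracle on random instances", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(4:30, 1)
      y <- c(1L, 1L, 0L, 0L, rbinom(n, 1, 0.5))
      x <- rnorm(length(y), mean = y * runif(1, 0, 3))
      expect_equal(f_score(x, y), oracle_f_score(x, y), tolerance = 1e-9)
    }
  })
  expect_equal(f_score(c(1, 2, 3, 2, 3, 4), c(1, 1, 1, 0, 0, 0)),
               oracle_f_score(c(1, 2, 3, 2, 3, 4), c(1, 1, 1, 0, 0, 0)))
})

test_that("f_score edge cases behave as documented", {
  # identical class means, nonzero variance -> 0
  expect_equal(f_score(c(1, 3, 1, 3), c(1, 1, 0, 0)), 0)
  # strong separation with tiny within-class jitter -> very large
  expect_gt(f_score(c(2, 2.001, 0, 0.001), c(1, 1, 0, 0)), 1e4)
  # constant within classes but separated between -> Inf sentinel
  expect_identical(f_score(c(2, 2, 0, 0), c(1, 1, 0, 0)), Inf)
  expect_error(f_score(1:4, c(1, 1, 1, 1)), "both classes")
  expect_error(f_score(1:3, c(1, 1, 0)), "at least two")
})

test_that("embedded pre-selection recovers planted signal and is stable", {
  sim <- synthesize_planted(pool_size = 30, n_planted = 3, shift = 4,
                            n_per_class = 60, seed = 9)
  norm <- apply_minmax(sim$data, fit_minmax(sim$data))
  top3 <- embedded_preselect(norm, k = 3)
  expect_setequal(top3$feature, sim$design$planted)

  # k = p keeps everything, reordered
  all_p <- embedded_preselect(norm, k = 30)
  expect_setequal(all_p$feature, sim$design$pool)

  # duplicated columns receive identical weights; ties break by name
  dup <- norm
  dup$PROP900 <- dup[[sim$design$planted[1]]]
  r <- embedded_preselect(dup, k = 31)
  w1 <- unname(r$weight[r$feature == sim$design$planted[1]])
  w2 <- unname(r$weight[r$feature == "PROP900"])
  expect_equal(w1, w2, tolerance = 1e-6)
  expect_identical(embedded_preselect(norm, k = 10)$feature,
                   embedded_preselect(norm, k = 10)$feature)
  expect_error(embedded_preselect(dplyr::mutate(norm, label = 1L), k = 2),
               "classes")
})

test_that("cross-validated SVM fitness is calibrated and deterministic", {
  sep <- separable_data(n_per_class = 30, gap = 6, seed = 3)
  fit1 <- svm_cv_fitness(sep, cost = 10, gamma = 0.25, seed = 4)
  expect_gte(fit1, 0.95)
  # chance level on permuted labels
  perm <- sep
  perm$label <- withr::with_seed(8, sample(perm$label))
  fit_null <- svm_cv_fitness(perm, cost = 10, gamma = 0.25, seed = 4)
  expect_lt(abs(fit_null - 0.5), 0.2)
  # determinism contract
  expect_identical(fit1, svm_cv_fitness(sep, cost = 10, gamma = 0.25,
                                        seed = 4))
  expect_error(svm_cv_fitness(sep[c(1:3, 31:33), ], folds = 5), "CV needs")
})

test_that("population initialization respects the configuration", {
  cfg <- ma_config(pool = sprintf("P%03d", 1:60), pop_size = 10,
                   subset_size = 40, seed = 2)
  pop <- init_population(cfg)
  expect_length(pop, 10)
  for (ind in pop) {
    expect_length(ind$subset, 40)
    expect_true(all(ind$subset %in% cfg$pool))
    expect_false(anyDuplicated(ind$subset) > 0)
    expect_true(ind$cost >= 2^-5 && ind$cost <= 2^15)
    expect_true(ind$gamma >= 2^-15 && ind$gamma <= 2^3)
  }
  expect_identical(pop, init_population(cfg))
  # subset_size = pool size forces identical subsets
  cfg_full <- ma_config(pool = sprintf("P%03d", 1:40), pop_size = 4,
                        subset_size = 40, seed = 2)
  subs <- lapply(init_population(cfg_full), `[[`, "subset")
  expect_length(unique(subs), 1)
})

test_that("best-half selection is elitist and stable under ties", {
  mk <- function(f, id) list(subset = id, cost = 1, gamma = 1, fitness = f)
  pop <- list(mk(0.9, "a"), mk(0.5, "b"), mk(0.8, "c"), mk(0.6, "d"))
  kept <- select_best_half(pop)
  expect_equal(sapply(kept, `[[`, "subset"), c("a", "c"))
  ties <- list(mk(0.7, "a"), mk(0.7, "b"), mk(0.7, "c"), mk(0.7, "d"))
  expect_equal(sapply(select_best_half(ties), `[[`, "subset"), c("a", "b"))
  pop10 <- lapply(1:10, function(i) mk(i / 10, as.character(i)))
  expect_length(select_best_half(pop10), 5)
  expect_error(select_best_half(list(mk(NA_real_, "a"), mk(1, "b")))," fitness")
})

test_that("property-pool recombination favors frequent parent properties", {
  cfg <- ma_config(pool = sprintf("P%02d", 1:20), pop_size = 10,
                   subset_size = 5, seed = 1)
  # P01 carried by all five parents, P20 by exactly one
  subsets <- list(c("P01", "P02", "P03", "P04", "P20"),
                  c("P01", "P05", "P06", "P07", "P08"),
                  c("P01", "P09", "P10", "P11", "P12"),
                  c("P01", "P13", "P14", "P15", "P16"),
                  c("P01", "P17", "P18", "P19", "P02"))
  parents <- lapply(subsets, function(s) {
    list(subset = s, cost = 1, gamma = 1, fitness = 0.5)
  })
  hits <- c(common = 0, rare = 0)
  for (s in 1:400) {
    off <- recombine_property_pool(parents, 1, cfg, seed = s)[[1]]
    expect_length(off$subset, 5)
    hits["common"] <- hits["common"] + ("P01" %in% off$subset)
    hits["rare"] <- hits["rare"] + ("P20" %in% off$subset)
  }
  expect_gt(hits[["common"]], hits[["rare"]])
  # identical parents leave no diversity
  same <- lapply(1:2, function(i) list(subset = sprintf("P%02d", 1:5),
                                       cost = 1, gamma = 1, fitness = 0.5))
  off <- recombine_property_pool(same, 3, cfg, seed = 7)
  for (o in off) expect_setequal(o$subset, sprintf("P%02d", 1:5))
  # cannot fill offspring when parents hold too few distinct properties
  cfg_big <- ma_config(pool = sprintf("P%02d", 1:20), pop_size = 10,
                       subset_size = 10, seed = 1)
  expect_error(recombine_property_pool(same, 1, cfg_big, seed = 1),
               "distinct")
})

test_that("the mutation schedule starts at s*m, decays monotonically to 1", {
  expect_equal(mutation_count(0, s = 40, m = 0.2, n_total = 100), 8)
  expect_equal(mutation_count(100, s = 40, m = 0.2, n_total = 100), 1)
  for (pars in list(c(40, 0.2, 100), c(60, 0.3, 50), c(20, 0.4, 30))) {
    nm <- vapply(0:pars[3], mutation_count, integer(1),
                 s = pars[1], m = pars[2], n_total = pars[3])
    expect_true(all(diff(nm) <= 0))
    expect_true(all(nm >= 1))
    expect_equal(nm[1], max(1, round(pars[1] * pars[2])))
    expect_equal(nm[length(nm)], 1)
  }
  expect_error(mutation_count(5, 40, 1.2, 100), "between 0 and 1")
  expect_error(mutation_count(-1, 40, 0.2, 100), "n_g")
})

test_that("mutation preserves cardinality and reproducibility", {
  cfg <- ma_config(pool = sprintf("P%02d", 1:30), pop_size = 4,
                   subset_size = 10, seed = 1)
  ind <- init_population(cfg)[[1]]
  ind$fitness <- 0.7
  same <- mutate_individual(ind, 0, cfg, seed = 5)
  expect_identical(same$subset, ind$subset)
  expect_identical(same$fitness, 0.7)  # subset untouched, fitness kept
  mut <- mutate_individual(ind, 4, cfg, seed = 5)
  expect_length(mut$subset, 10)
  expect_equal(length(setdiff(ind$subset, mut$subset)), 4)
  expect_true(is.na(mut$fitness))
  expect_identical(mut, mutate_individual(ind, 4, cfg, seed = 5))
  # full replacement possible when the pool is large enough
  full <- mutate_individual(ind, 10, cfg, seed = 6)
  expect_length(full$subset, 10)
  # more swaps requested than non-members available: swap what exists
  cfg_small <- ma_config(pool = sprintf("P%02d", 1:12), pop_size = 4,
                         subset_size = 10, seed = 1)
  ind2 <- init_population(cfg_small)[[1]]
  expect_warning(mutate_individual(ind2, 5, cfg_small, seed = 1),
                 "non-member")
})

test_that("local search adopts a strictly better high-F-score feature", {
  sim <- synthesize_planted(pool_size = 12, n_planted = 3, shift = 4,
                            n_per_class = 40, seed = 21)
  data <- apply_minmax(sim$data, fit_minmax(sim$data))
  cfg <- ma_config(pool = sim$design$pool, pop_size = 4, subset_size = 4,
                   cv_folds = 3, seed = 3)
  rankings <- f_score_table(data, cfg$pool)
  # start from a subset that misses every planted feature
  bad_subset <- setdiff(cfg$pool, sim$design$planted)[1:4]
  adopted <- 0
  for (s in 1:10) {
    ind <- list(subset = bad_subset, cost = 8, gamma = 0.25,
                fitness = NA_real_)
    out <- local_search(ind, data, rankings, cfg, fold_seed = s)
    expect_length(out$subset, 4)
    adopted <- adopted + any(sim$design$planted %in% out$subset)
  }
  expect_gte(adopted / 10, 0.9)
})

test_that("local search never accepts a non-improving candidate", {
  sep <- separable_data(n_per_class = 20, p = 6, gap = 6, seed = 2)
  cfg <- ma_config(pool = paste0("f", 1:6), pop_size = 4, subset_size = 2,
                   cv_folds = 4, seed = 1)
  rankings <- f_score_table(sep, cfg$pool)
  # f1 carries all the signal: a subset containing it is hard to improve
  ind <- list(subset = c("f1", "f2"), cost = 10, gamma = 0.25,
              fitness = NA_real_)
  out <- local_search(ind, sep, rankings, cfg, fold_seed = 4)
  base <- svm_cv_fitness(sep, c("f1", "f2"), cost = 10, gamma = 0.25,
                         folds = 4, seed = 4)
  expect_gte(out$fitness, base)
  expect_true("f1" %in% out$subset)
})

test_that("the memetic loop is elitist, cardinality-safe and seeded", {
  sim <- synthesize_planted(pool_size = 25, n_planted = 5,
                            n_per_class = 80, seed = 31)
  data <- apply_minmax(sim$data, fit_minmax(sim$data))
  cfg <- ma_config(pool = sim$design$pool, pop_size = 6, subset_size = 8,
                   generations = 12, cv_folds = 3, patience = 50, seed = 11)
  res <- run_memetic(data, cfg)
  hist <- tidy(res)
  expect_true(all(diff(hist$best) >= 0))
  expect_true(all(vapply(res$history$best_subset, length, integer(1)) == 8))
  expect_true(all(diff(hist$n_mutations[-1]) <= 0))
  expect_length(res$best$subset, 8)
  res2 <- run_memetic(data, cfg)
  expect_identical(res$best, res2$best)
  # the planted features should dominate the selected subset
  expect_gte(length(intersect(res$best$subset, sim$design$planted)), 4)
})

test_that("selection results serialize to JSON", {
  sim <- synthesize_planted(pool_size = 10, n_planted = 2, shift = 4,
                            n_per_class = 20, seed = 2)
  cfg <- ma_config(pool = sim$design$pool, pop_size = 4, subset_size = 3,
                   generations = 2, cv_folds = 3, seed = 1)
  res <- run_memetic(sim$data, cfg)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_selection(res, tmp)
  back <- read_selection(tmp)
  expect_equal(back$subset, res$best$subset)
  expect_equal(back$fitness, res$best$fitness)
})
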
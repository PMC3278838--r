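#' Two-class F-score of a feature
#'
#' The filter statistic used to rank features for the memetic local search:
#' \deqn{F = \frac{(\bar x_+ - \bar x)^2 + (\bar x_- - \bar x)^2}
#'   {s_+^2 + s_-^2}}
#' where \eqn{\bar x}, \eqn{\bar x_+}, \eqn{\bar x_-} are the overall and
#' per-class means and \eqn{s_\pm^2} the unbiased within-class variances.
#' Larger is more discriminative. A zero denominator with a nonzero
#' numerator (constant within each class, different between classes) returns
#' `Inf`, the maximally discriminative sentinel; 0/0 returns 0.
#'
#' @param values Numeric vector of per-sample feature values.
#' @param labels Binary labels (0/1), same length; both classes must be
#'   present with at least two samples each.
#' @return A non-negative number (possibly `Inf`).
#' @export
f_score <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    abort("`labels` must contain both classes (0 and 1).")
  }
  pos <- values[labels == 1L]
  neg <- values[labels == 0L]
  if (length(pos) < 2L || length(neg) < 2L) {
    abort("Each class needs at least two samples for the F-score.")
  }
  num <- (mean(pos) - mean(values))^2 + (mean(neg) - mean(values))^2
  den <- var(pos) + var(neg)
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
}

#' F-scores of every feature column
#'
#' @param data Tibble with a `label` column and numeric feature columns.
#' @param features Feature names to score (default: all feature columns).
#' @return Tibble with columns `feature` and `f_score`, in input order.
#' @export
f_score_table <- function(data, features = NULL) {
  stopifnot("label" %in% names(data))
  features <- features %||% feature_columns(data)
  tibble(feature = features,
         f_score = map_dbl(data[features], f_score, labels = data$label))
}

#' Embedded SVM pre-selection of candidate properties
#'
#' The first feature-optimization stage: a linear-kernel SVM is fitted once
#' on all candidate per-property features and properties are ranked by the
#' absolute value of their primal weight \eqn{w_j = \sum_i \alpha_i y_i
#' x_{ij}}; the top `k` (canonically 186) form the pool the memetic
#' algorithm searches. Ties are broken by feature-name order, so the result
#' is deterministic.
#'
#' @param data Tibble with `label` and numeric feature columns (normalized).
#' @param k Number of properties to keep; at most the number of features.
#' @param cost Linear-SVM cost parameter.
#' @return Tibble of `k` rows with columns `feature`, `weight`,
#'   `abs_weight`, `rank`, ordered by decreasing `abs_weight`.
#' @export
embedded_preselect <- function(data, k = 186L, cost = 1) {
  stopifnot("label" %in% names(data))
  feats <- feature_columns(data)
  k <- as.integer(k)
  if (k < 1L || k > length(feats)) {
    abort("`k` must be between 1 and the number of features.")
  }
  y <- factor(data$label, levels = c(0L, 1L))
  if (length(unique(data$label)) < 2L) {
    abort("Both classes must be present for pre-selection.")
  }
  x <- as.matrix(data[feats])
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- unname(drop(crossprod(fit$coefs, fit$SV)))
  ranked <- tibble(feature = feats, weight = w, abs_weight = abs(w))
  ranked <- arrange(ranked, desc(.data$abs_weight), .data$feature)
  ranked <- mutate(head(ranked, k), rank = row_number())
  ranked
}

# Stratified fold assignment: every class is spread across all folds.
make_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < folds) {
        abort(sprintf("Class %s has %d samples; %d-fold CV needs >= %d.",
                      cl, length(idx), folds, folds))
      }
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_id
}

# Core CV loop on a plain matrix; fold assignment is fixed by the caller.
cv_accuracy <- function(x, y, cost, gamma, fold_id) {
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Cross-validated RBF-SVM accuracy of a feature subset
#'
#' The memetic algorithm's fitness function: mean accuracy of an RBF-kernel
#' SVM over seeded stratified k-fold cross-validation, restricted to the
#' given feature subset. Deterministic for fixed inputs and seed.
#'
#' @param data Tibble with `label` and numeric feature columns.
#' @param subset Feature names to use (default: all feature columns).
#' @param cost,gamma RBF-SVM parameters (both > 0).
#' @param folds Number of CV folds (default 5).
#' @param seed Seed controlling the fold assignment.
#' @return Accuracy in `[0, 1]`.
#' @export
svm_cv_fitness <- function(data, subset = NULL, cost = 1, gamma = 0.1,
                           folds = 5L, seed = 1L) {
  stopifnot("label" %in% names(data), cost > 0, gamma > 0)
  if (length(unique(data$label)) < 2L) {
    abort("Both classes must be present; CV needs labeled 0/1 data.")
  }
  subset <- subset %||% feature_columns(data)
  x <- as.matrix(data[subset])
  y <- factor(data$label, levels = c(0L, 1L))
  fold_id <- make_folds(data$label, folds, seed)
  cv_accuracy(x, y, cost, gamma, fold_id)
}

#' Memetic-algorithm configuration
#'
#' Parameters of the evolutionary feature-subset search. Defaults follow
#' the canonical run: a pool of pre-selected properties (186 in the
#' reference setting), 10 parents, subsets of exactly 40 properties, 100
#' generations, mutation value `m = 0.2` and local-search length 8, with
#' 5-fold cross-validated SVM accuracy as fitness.
#'
#' @param pool Character vector of candidate property names.
#' @param pop_size Population size (even; default 10).
#' @param subset_size Fixed cardinality `s` of every individual (default 40).
#' @param generations Maximum number of generations `N_G` (default 100).
#' @param mutation_value Mutation constant `m` in (0, 1) (default 0.2);
#'   `s * m` mutations are applied per offspring in the first generation.
#' @param local_search_length Maximum count of Add/Delete steps per local
#'   search (default 8).
#' @param cv_folds Cross-validation folds for the fitness (default 5).
#' @param patience Early stop after this many generations without
#'   improvement of the best fitness (default 15).
#' @param cost_range,gamma_range Log-uniform initialization ranges for the
#'   RBF-SVM parameters carried as genes on each individual.
#' @param param_sigma Log-normal sd for mutating `(cost, gamma)`.
#' @param mutation_count_fn Optional override for the mutation schedule,
#'   a function `(n_g, s, m, n_total) -> integer`; default
#'   [mutation_count()].
#' @param seed Seed for the whole run.
#' @return An `ma_config` object.
#' @seealso [run_memetic()]
#' @export
ma_config <- function(pool, pop_size = 10L, subset_size = 40L,
                      generations = 100L, mutation_value = 0.2,
                      local_search_length = 8L, cv_folds = 5L,
                      patience = 15L,
                      cost_range = c(2^-5, 2^15),
                      gamma_range = c(2^-15, 2^3),
                      param_sigma = 0.3,
                      mutation_count_fn = NULL,
                      seed = 1L) {
  pool <- as.character(pool)
  pop_size <- as.integer(pop_size)
  subset_size <- as.integer(subset_size)
  if (pop_size < 2L || pop_size %% 2L != 0L) {
    abort("`pop_size` must be an even integer >= 2.")
  }
  if (subset_size > length(pool) || subset_size < 1L) {
    abort("`subset_size` must be between 1 and the pool size.")
  }
  if (mutation_value <= 0 || mutation_value >= 1) {
    abort("`mutation_value` must lie strictly between 0 and 1.")
  }
  if (local_search_length < 1L) abort("`local_search_length` must be >= 1.")
  structure(
    list(pool = pool, pop_size = pop_size, subset_size = subset_size,
         generations = as.integer(generations),
         mutation_value = mutation_value,
         local_search_length = as.integer(local_search_length),
         cv_folds = as.integer(cv_folds), patience = as.integer(patience),
         cost_range = cost_range, gamma_range = gamma_range,
         param_sigma = param_sigma,
         mutation_count_fn = mutation_count_fn %||% mutation_count,
         seed = as.integer(seed)),
    class = "ma_config")
}

new_individual <- function(subset, cost, gamma, fitness = NA_real_) {
  list(subset = sort(subset), cost = cost, gamma = gamma, fitness = fitness)
}

draw_svm_params <- function(config) {
  list(cost = 2^runif(1, log2(config$cost_range[1]),
                      log2(config$cost_range[2])),
       gamma = 2^runif(1, log2(config$gamma_range[1]),
                       log2(config$gamma_range[2])))
}

#' Initialize a random population of feature subsets
#'
#' Each individual draws `subset_size` properties uniformly without
#' replacement from the pool and log-uniform RBF-SVM parameters from the
#' configured ranges.
#'
#' @param config An [ma_config()].
#' @return List of `pop_size` individuals (each a list with elements
#'   `subset`, `cost`, `gamma`, `fitness`).
#' @export
init_population <- function(config) {
  with_seed(config$seed, {
    map(seq_len(config$pop_size), function(i) {
      p <- draw_svm_params(config)
      new_individual(sample(config$pool, config$subset_size),
                     p$cost, p$gamma)
    })
  })
}

#' Keep the fitter half of a population
#'
#' Stable selection: ties keep the lower-index individual.
#'
#' @param population List of individuals with fitness set.
#' @return List of `length(population) / 2` parents, fittest first.
#' @export
select_best_half <- function(population) {
  fit <- map_dbl(population, "fitness")
  if (anyNA(fit)) abort("All individuals must have an evaluated fitness.")
  keep <- order(-fit, seq_along(fit))[seq_len(length(population) %/% 2L)]
  population[keep]
}

#' Recombine parents through a shared property pool
#'
#' A pool array holds the shuffled multiset of all parents' properties. For
#' each offspring, properties are drawn one at a time; a property is kept
#' the first time it appears for that offspring and returned to the pool
#' otherwise, until `subset_size` distinct properties are held. Properties
#' shared by many fit parents therefore enter offspring with elevated
#' probability. Offspring inherit their SVM parameters from a uniformly
#' chosen parent.
#'
#' @param parents List of individuals.
#' @param n_offspring Number of offspring to create.
#' @param config An [ma_config()].
#' @param seed Seed for the draws.
#' @return List of `n_offspring` individuals with unset fitness.
#' @export
recombine_property_pool <- function(parents, n_offspring, config, seed) {
  pool_multiset <- unlist(map(parents, "subset"))
  s <- config$subset_size
  if (length(unique(pool_multiset)) < s) {
    abort(sprintf(
      "Parents hold %d distinct properties; cannot fill offspring of size %d.",
      length(unique(pool_multiset)), s))
  }
  with_seed(seed, {
    map(seq_len(n_offspring), function(i) {
      # Sequential draws from the shuffled multiset, keeping first
      # occurrences: walking a shuffled bag and skipping repeats.
      held <- head(unique(sample(pool_multiset)), s)
      donor <- parents[[sample.int(length(parents), 1L)]]
      new_individual(held, donor$cost, donor$gamma)
    })
  })
}

#' Mutation schedule: mutations per offspring at generation n_g
#'
#' An exponentially decaying schedule
#' \deqn{N_M(n_G) = \max\{1,\ \mathrm{round}(s\, m\, e^{-\lambda n_G /
#'   N_G})\}, \qquad \lambda = \ln(s\, m),}
#' so that the first generation applies `round(s * m)` mutations (8 for
#' `s = 40`, `m = 0.2`) and the last applies exactly 1: large steps early,
#' fine steps near convergence. Non-increasing in `n_g`.
#'
#' @param n_g Current generation, `0 <= n_g <= n_total`.
#' @param s Offspring size (subset cardinality).
#' @param m Mutation value in (0, 1).
#' @param n_total Total number of generations `N_G`.
#' @return Integer number of mutations, at least 1.
#' @examples
#' mutation_count(0, s = 40, m = 0.2, n_total = 100)   # 8
#' mutation_count(100, s = 40, m = 0.2, n_total = 100) # 1
#' @export
mutation_count <- function(n_g, s, m, n_total) {
  if (m <= 0 || m >= 1) abort("`m` must lie strictly between 0 and 1.")
  if (n_g < 0 || n_g > n_total) abort("`n_g` must be in 0 .. n_total.")
  start <- s * m
  if (start <= 1) return(1L)
  lambda <- log(start)
  max(1L, as.integer(round(start * exp(-lambda * n_g / n_total))))
}

#' Mutate a feature subset
#'
#' Replaces `n_m` uniformly chosen subset members with `n_m` uniformly
#' chosen non-members, preserving cardinality, so properties absent from the
#' first generation can still enter the search later. The SVM parameter
#' genes are perturbed multiplicatively (log-normal, small sigma) and
#' clamped to their configured ranges. If fewer than `n_m` non-members
#' exist, as many as available are swapped, with a warning.
#'
#' @param individual An individual.
#' @param n_m Number of mutations (see [mutation_count()]).
#' @param config An [ma_config()].
#' @param seed Seed.
#' @return The mutated individual, fitness unset.
#' @export
mutate_individual <- function(individual, n_m, config, seed) {
  with_seed(seed, {
    subset <- individual$subset
    if (n_m > 0) {
      non_members <- setdiff(config$pool, subset)
      k <- min(n_m, length(non_members))
      if (k < n_m) {
        warn(sprintf("Only %d non-member properties available; swapping %d.",
                     length(non_members), k))
      }
      if (k > 0) {
        out_feats <- sample(subset, k)
        in_feats <- sample(non_members, k)
        subset <- c(setdiff(subset, out_feats), in_feats)
      }
    }
    clamp <- function(x, r) min(max(x, r[1]), r[2])
    cost <- clamp(individual$cost * exp(rnorm(1, 0, config$param_sigma)),
                  config$cost_range)
    gamma <- clamp(individual$gamma * exp(rnorm(1, 0, config$param_sigma)),
                   config$gamma_range)
    new_individual(subset, cost, gamma,
                   fitness = if (n_m > 0) NA_real_ else individual$fitness)
  })
}

# Order features worst-first (ascending F-score, ties by name).
rank_ascending <- function(features, rankings) {
  sc <- rankings$f_score[match(features, rankings$feature)]
  features[order(sc, features)]
}

#' F-score-guided Add/Delete local search
#'
#' Given an offspring `O`, the selected set `S` and excluded set `E` are
#' ranked by [f_score()]. Each step simultaneously Adds the top-ranked
#' member of `E` and Deletes the bottom-ranked member of `S` (cardinality is
#' preserved), forming a candidate `O_N` whose cross-validated fitness is
#' evaluated; `O_N` replaces `O` only if it is strictly better. The climb
#' stops at the first non-improving step or after `local_search_length`
#' steps.
#'
#' @param individual An individual with evaluated fitness.
#' @param data Tibble with `label` and the pool's feature columns.
#' @param rankings F-score table over the pool ([f_score_table()]).
#' @param config An [ma_config()].
#' @param fold_seed Seed fixing the CV fold assignment.
#' @return The (possibly improved) individual, fitness set; the number of
#'   fitness evaluations spent is attached as attribute `"n_evals"`.
#' @export
local_search <- function(individual, data, rankings, config, fold_seed) {
  x <- as.matrix(data[config$pool])
  y <- factor(data$label, levels = c(0L, 1L))
  fold_id <- make_folds(data$label, config$cv_folds, fold_seed)
  eval_subset <- function(subset) {
    cv_accuracy(x[, subset, drop = FALSE], y,
                individual$cost, individual$gamma, fold_id)
  }
  n_evals <- 0L
  if (is.na(individual$fitness)) {
    individual$fitness <- eval_subset(individual$subset)
    n_evals <- n_evals + 1L
  }
  current <- individual
  for (step in seq_len(config$local_search_length)) {
    S <- rank_ascending(current$subset, rankings)
    E <- rank_ascending(setdiff(config$pool, current$subset), rankings)
    if (length(E) == 0L) break
    add <- E[length(E)]   # highest-ranked excluded feature
    delete <- S[1L]       # lowest-ranked selected feature
    candidate <- sort(c(setdiff(current$subset, delete), add))
    fit <- eval_subset(candidate)
    n_evals <- n_evals + 1L
    if (fit > current$fitness) {
      current$subset <- candidate
      current$fitness <- fit
    } else {
      break
    }
  }
  attr(current, "n_evals") <- n_evals
  current
}

#' Run the memetic feature-subset search
#'
#' The full evolutionary loop: evaluate the population with 5-fold
#' cross-validated RBF-SVM accuracy, keep the best half as parents,
#' recombine them through the property pool, mutate offspring on the
#' exponentially decaying schedule of [mutation_count()], improve each
#' offspring by [local_search()], and replace the worst half. Runs for
#' `generations` generations or until the best fitness has not improved for
#' `patience` generations. The best half is retained unchanged each
#' generation, so the best fitness is non-decreasing.
#'
#' @param data Tibble with `label` and one numeric column per pool property.
#' @param config An [ma_config()].
#' @return A `memetic_result`: list with elements `best` (fittest individual
#'   ever seen), `history` (per-generation tibble: `generation`, `best`,
#'   `mean`, `n_mutations`, `best_subset` list-column), `rankings`
#'   (F-score table), `config`, and `n_evals`.
#' @examples
#' \donttest{
#' sim <- synthesize_planted(pool_size = 20, n_planted = 4,
#'                           n_per_class = 40, seed = 1)
#' cfg <- ma_config(pool = sim$design$pool, pop_size = 4, subset_size = 6,
#'                  generations = 5, cv_folds = 3, seed = 1)
#' res <- run_memetic(sim$data, cfg)
#' glance(res)
#' }
#' @export
run_memetic <- function(data, config) {
  stopifnot(inherits(config, "ma_config"), "label" %in% names(data))
  missing_cols <- setdiff(config$pool, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Data lacks pool columns: %s",
                  paste(head(missing_cols, 5L), collapse = ", ")))
  }
  if (length(unique(data$label)) < 2L) {
    abort("Both classes must be present.")
  }

  x <- as.matrix(data[config$pool])
  y <- factor(data$label, levels = c(0L, 1L))
  fold_seed <- config$seed + 1000003L
  fold_id <- make_folds(data$label, config$cv_folds, fold_seed)
  rankings <- f_score_table(data, config$pool)
  n_evals <- 0L
  evaluate <- function(ind) {
    if (!is.na(ind$fitness)) return(ind)
    ind$fitness <- cv_accuracy(x[, ind$subset, drop = FALSE], y,
                               ind$cost, ind$gamma, fold_id)
    n_evals <<- n_evals + 1L
    ind
  }

  population <- map(init_population(config), evaluate)
  best_of <- function(pop) pop[[which.max(map_dbl(pop, "fitness"))]]
  best_ever <- best_of(population)

  history <- list(record_generation(0L, population, 0L))
  stale <- 0L
  for (g in seq_len(config$generations)) {
    parents <- select_best_half(population)
    offspring <- recombine_property_pool(
      parents, config$pop_size %/% 2L, config,
      seed = config$seed + 7919L * g)
    n_m <- config$mutation_count_fn(g, config$subset_size,
                                    config$mutation_value,
                                    config$generations)
    offspring <- imap(offspring, function(o, i) {
      mutate_individual(o, n_m, config,
                        seed = config$seed + 104729L * g + i)
    })
    offspring <- map(offspring, evaluate)
    offspring <- map(offspring, function(o) {
      improved <- local_search(o, data, rankings, config, fold_seed)
      n_evals <<- n_evals + attr(improved, "n_evals")
      improved
    })
    population <- c(parents, offspring)

    gen_best <- best_of(population)
    improved_now <- gen_best$fitness > best_ever$fitness
    if (improved_now) {
      best_ever <- gen_best
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    history[[length(history) + 1L]] <- record_generation(g, population, n_m)
    if (stale >= config$patience) break
  }

  structure(
    list(best = best_ever, history = bind_rows(history),
         rankings = rankings, config = config, n_evals = n_evals),
    class = "memetic_result")
}

record_generation <- function(g, population, n_m) {
  fit <- map_dbl(population, "fitness")
  top_subset <- population[[which.max(fit)]]$subset
  tibble(generation = g, best = max(fit), mean = mean(fit),
         n_mutations = n_m, best_subset = list(top_subset))
}

#' @export
print.memetic_result <- function(x, ...) {
  cat(sprintf(
    "<memetic_result> %d generations | best 5-fold CV accuracy %.4f | %d properties | %d SVM evaluations\n",
    max(x$history$generation), x$best$fitness,
    length(x$best$subset), x$n_evals))
  invisible(x)
}

#' @describeIn run_memetic Per-generation history as a tibble
#'   (`generation`, `best`, `mean`, `n_mutations`).
#' @param x A `memetic_result`.
#' @param ... Unused.
#' @method tidy memetic_result
#' @export
tidy.memetic_result <- function(x, ...) {
  select(x$history, -"best_subset")
}

#' @describeIn run_memetic One-row summary (best fitness, generations run,
#'   subset size, SVM parameters, evaluations spent).
#' @method glance memetic_result
#' @export
glance.memetic_result <- function(x, ...) {
  tibble(best_fitness = x$best$fitness,
         generations = max(x$history$generation),
         subset_size = length(x$best$subset),
         cost = x$best$cost, gamma = x$best$gamma,
         n_evals = x$n_evals)
}

#' @describeIn run_memetic Fitness trajectory (best and mean per
#'   generation).
#' @param object A `memetic_result`.
#' @method autoplot memetic_result
#' @export
autoplot.memetic_result <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(tidy(object), c("best", "mean"),
                                   names_to = "statistic",
                                   values_to = "fitness")
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$generation, y = .data$fitness,
                               colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "5-fold CV accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save or load a selected feature subset as JSON
#'
#' @param result A `memetic_result`.
#' @param file Path.
#' @return [write_selection()]: `file`, invisibly; [read_selection()]: a
#'   list with `subset`, `cost`, `gamma`, `fitness`.
#' @export
write_selection <- function(result, file) {
  jsonlite::write_json(
    list(subset = result$best$subset, cost = result$best$cost,
         gamma = result$best$gamma, fitness = result$best$fitness,
         seed = result$config$seed),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_selection
#' @export
read_selection <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
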
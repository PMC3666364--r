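# Genetic-algorithm wrapper feature selection.
#
# Individuals are fixed-length bit masks over the feature registry. Fitness
# is the negated sum of per-tissue mean Jaccard indices obtained by running
# the full segmentation pipeline restricted to the masked features on a set
# of training volumes with references; lower is better, with -3 the ideal
# limit (perfect overlap for all three tissues).

#' GA configuration
#'
#' Defaults are conventional wrapper-selection settings: population 50,
#' 60 generations (enough for convergence at this problem size), uniform
#' crossover at rate 0.8, per-bit mutation 1/23, tournament size 3,
#' elitism 1.
#'
#' @param population Even population size.
#' @param generations Number of generations, >= 1.
#' @param crossover_rate,mutation_rate Probabilities in `[0, 1]`.
#' @param tournament Tournament size for selection.
#' @param min_features Minimum number of selected features per individual.
#' @param seed Random seed.
#' @return An object of class `somseg_ga_config`.
#' @export
ga_config <- function(population = 50L, generations = 60L,
                      crossover_rate = 0.8, mutation_rate = 1 / 23,
                      tournament = 3L, min_features = 1L, seed = 1L) {
  population <- as.integer(population)
  if (population < 2L || population %% 2L != 0L)
    stop("population must be even and >= 2")
  if (generations < 1L) stop("generations must be >= 1")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stop("rates must lie in [0, 1]")
  structure(list(population = population,
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament = as.integer(tournament),
                 min_features = as.integer(min_features),
                 seed = as.integer(seed)),
            class = "somseg_ga_config")
}

#' Pipeline fitness of a feature subset
#'
#' Runs the full segmentation pipeline restricted to the masked features on
#' each `(volume, reference)` pair and returns
#' `-(mean J_WM + mean J_GM + mean J_CSF)`; lower is better. A volume on
#' which the pipeline fails is skipped with a warning; if all fail, an
#' error is raised.
#'
#' @param mask Logical vector over `names` (or a character vector of
#'   feature names).
#' @param volumes List of `list(volume = <somseg_volume>,
#'   ref = <somseg_labelmap>)` pairs.
#' @param config A [pipeline_config()]; its `selected_features` is replaced
#'   by the mask.
#' @param names Feature names the mask indexes (default: the canonical 23).
#' @return Scalar fitness (>= -3).
#' @export
feature_fitness <- function(mask, volumes,
                            config = pipeline_config(),
                            names = somseg_feature_names()) {
  if (is.character(mask)) mask <- names %in% resolve_feature_names(mask)
  stopifnot(length(mask) == length(names), length(volumes) > 0L)
  if (!any(mask)) return(0)
  config$selected_features <- names[mask]
  per_vol <- lapply(volumes, function(v) {
    tryCatch({
      res <- segment_volume(v$volume, config)
      score_segmentation(res$segmentation, v$ref)$per_tissue
    }, error = function(e) {
      warning("pipeline failed on a training volume: ", conditionMessage(e))
      NULL
    })
  })
  per_vol <- per_vol[!vapply(per_vol, is.null, logical(1))]
  if (!length(per_vol)) stop("fitness evaluation failed on every volume")
  -sum(rowMeans(do.call(cbind, per_vol)))
}

#' GA feature-subset selection
#'
#' Binary-encoded elitist genetic algorithm: tournament selection, uniform
#' crossover, bit-flip mutation, elitism 1; individuals with fewer than
#' `min_features` bits are repaired by switching on random bits. Fitness
#' values are cached per mask, so the best-fitness trace is non-increasing
#' and re-evaluation is free.
#'
#' @param volumes Training data passed through to `fitness_fn` (for the
#'   default fitness: a list of `list(volume=, ref=)` pairs).
#' @param config A [ga_config()].
#' @param fitness_fn Function `(mask, volumes, ...) -> scalar` to minimize;
#'   defaults to [feature_fitness()].
#' @param names Feature names defining mask length (default: canonical 23).
#' @param ... Passed to `fitness_fn`.
#' @return A list: `mask` (named logical), `features` (selected names),
#'   `fitness` (best value), `trace` (per-generation best fitness,
#'   non-increasing), `evaluations` (number of distinct masks scored).
#' @export
ga_select <- function(volumes, config = ga_config(),
                      fitness_fn = feature_fitness,
                      names = somseg_feature_names(), ...) {
  stopifnot(inherits(config, "somseg_ga_config"))
  nb <- length(names)
  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  score <- function(bits) {
    key <- paste(as.integer(bits), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness_fn(bits, volumes, ...)
    evals <<- evals + 1L
    cache[[key]] <- val
    val
  }
  repair <- function(bits) {
    deficit <- config$min_features - sum(bits)
    if (deficit > 0L)
      bits[sample(which(!bits), deficit)] <- TRUE
    bits
  }
  pop <- lapply(seq_len(config$population), function(i)
    repair(stats::runif(nb) < 0.5))
  fit <- vapply(pop, score, numeric(1))
  trace <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    elite <- which.min(fit)
    pick <- function() {
      cand <- sample.int(config$population, config$tournament, replace = TRUE)
      cand[which.min(fit[cand])]
    }
    children <- vector("list", config$population)
    for (i in seq(1L, config$population, by = 2L)) {
      p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
      if (stats::runif(1) < config$crossover_rate) {
        swap <- stats::runif(nb) < 0.5            # uniform crossover
        tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      }
      flip1 <- stats::runif(nb) < config$mutation_rate
      flip2 <- stats::runif(nb) < config$mutation_rate
      children[[i]] <- repair(xor(p1, flip1))
      children[[i + 1L]] <- repair(xor(p2, flip2))
    }
    children[[1L]] <- pop[[elite]]                # elitism 1
    pop <- children
    fit <- vapply(pop, score, numeric(1))
    trace[g] <- min(fit)
  }
  best <- which.min(fit)
  mask <- stats::setNames(pop[[best]], names)
  list(mask = mask, features = names[mask], fitness = fit[best],
       trace = trace, evaluations = evals)
}
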
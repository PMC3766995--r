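# Strongly typed genetic programming for binary texture grading.
#
# Trees are nested lists. Node shapes:
#   list(kind = "op",    name = <operator>, args = list(...))
#   list(kind = "feat",  name = <feature column name>)
#   list(kind = "const", value = <numeric>)
# Every node has a return type, "bool" or "num". The root is always "bool";
# TRUE maps to gradeIV, FALSE to gradeII. Trees are built well-typed and are
# never repaired at evaluation time.

GP_OPS <- list(
  AND  = list(type = "bool", arg = c("bool", "bool")),
  OR   = list(type = "bool", arg = c("bool", "bool")),
  XOR  = list(type = "bool", arg = c("bool", "bool")),
  NOT  = list(type = "bool", arg = "bool"),
  LT   = list(type = "bool", arg = c("num", "num")),
  LE   = list(type = "bool", arg = c("num", "num")),
  GT   = list(type = "bool", arg = c("num", "num")),
  GE   = list(type = "bool", arg = c("num", "num")),
  ADD  = list(type = "num",  arg = c("num", "num")),
  SUB  = list(type = "num",  arg = c("num", "num")),
  MUL  = list(type = "num",  arg = c("num", "num")),
  PDIV = list(type = "num",  arg = c("num", "num"))
)

# operator families for the change-node-type mutator (arity-compatible swaps)
GP_OP_FAMILY <- list(
  AND = c("OR", "XOR"), OR = c("AND", "XOR"), XOR = c("AND", "OR"),
  LT = c("LE", "GT", "GE"), LE = c("LT", "GT", "GE"),
  GT = c("LT", "LE", "GE"), GE = c("LT", "LE", "GT"),
  ADD = c("SUB", "MUL", "PDIV"), SUB = c("ADD", "MUL", "PDIV"),
  MUL = c("ADD", "SUB", "PDIV"), PDIV = c("ADD", "SUB", "MUL"),
  NOT = character(0)
)

GP_LABELS <- c("gradeII", "gradeIV")

#' Genetic-programming configuration
#'
#' Defaults reproduce one cell of the reference parameter grid: population 70,
#' tournament selection (size 2), subtree crossover with probability 0.9, a
#' 10 percent mutation rate choosing uniformly among four mutators
#' (replace-branch, change-node-type, full-tree shaker, one-point shaker),
#' elitism 1, and depth/length caps on every individual. Evolution stops early
#' once a tree classifies the training set perfectly, since training accuracy
#' is the fitness and cannot improve further.
#'
#' @param max_generations Maximum number of generations (grid: 70 or 100).
#' @param mutation_probability_percent Mutation probability in percent
#'   (grid: 10 or 15).
#' @param population_size Number of trees per generation (grid: 70).
#' @param max_tree_depth Maximum tree depth, root = depth 1 (grid: 8 or 10).
#' @param max_tree_length Maximum node count (grid: 25, 50 or 80).
#' @param tournament_size Tournament size for parent selection.
#' @param crossover_probability Probability of subtree crossover per offspring.
#' @param elitism_count Individuals copied unchanged into the next generation.
#' @param n_folds Cross-validation folds.
#' @param n_runs Independent cross-validation repetitions.
#' @param seed Master seed; all randomness derives from it.
#' @return List of class \code{gp_config}.
#' @export
gp_config <- function(max_generations = 70L,
                      mutation_probability_percent = 10,
                      population_size = 70L,
                      max_tree_depth = 8L,
                      max_tree_length = 25L,
                      tournament_size = 2L,
                      crossover_probability = 0.9,
                      elitism_count = 1L,
                      n_folds = 10L,
                      n_runs = 10L,
                      seed = 1L) {
  cfg <- list(max_generations = as.integer(max_generations),
              mutation_probability_percent = mutation_probability_percent,
              population_size = as.integer(population_size),
              max_tree_depth = as.integer(max_tree_depth),
              max_tree_length = as.integer(max_tree_length),
              tournament_size = as.integer(tournament_size),
              crossover_probability = crossover_probability,
              elitism_count = as.integer(elitism_count),
              n_folds = as.integer(n_folds),
              n_runs = as.integer(n_runs),
              seed = as.integer(seed))
  stopifnot(cfg$max_generations >= 1L, cfg$population_size >= 2L,
            cfg$population_size >= cfg$tournament_size,
            cfg$max_tree_depth >= 2L, cfg$max_tree_length >= 3L,
            cfg$mutation_probability_percent >= 0,
            cfg$mutation_probability_percent <= 100,
            cfg$crossover_probability >= 0, cfg$crossover_probability <= 1,
            cfg$elitism_count >= 0L, cfg$n_folds >= 2L, cfg$n_runs >= 1L)
  class(cfg) <- "gp_config"
  cfg
}

#' The reference parameter grid
#'
#' Cartesian product of the tested settings: maximum generations 70/100,
#' mutation probability 10/15 percent, maximum tree depth 8/10, maximum tree
#' length 25/50/80, population fixed at 70 -- 24 configurations.
#'
#' @return Data frame with one row per configuration.
#' @export
gp_default_grid <- function() {
  expand.grid(max_generations = c(70L, 100L),
              mutation_probability_percent = c(10, 15),
              max_tree_depth = c(8L, 10L),
              max_tree_length = c(25L, 50L, 80L),
              KEEP.OUT.ATTRS = FALSE)
}

# ---- tree structure helpers -------------------------------------------------

node_type <- function(node) {
  switch(node$kind,
         op = GP_OPS[[node$name]]$type,
         feat = "num",
         const = "num")
}

tree_length <- function(node) {
  if (node$kind != "op") return(1L)
  1L + sum(vapply(node$args, tree_length, integer(1L)))
}

tree_depth <- function(node) {
  if (node$kind != "op") return(1L)
  1L + max(vapply(node$args, tree_depth, integer(1L)))
}

# enumerate nodes as list of (path, type, kind, name); path = integer vector
# of argument indices from the root (root path = integer(0))
tree_nodes <- function(node, path = integer(0L)) {
  self <- list(list(path = path, type = node_type(node), kind = node$kind,
                    name = if (node$kind == "const") NA_character_ else node$name))
  if (node$kind != "op") return(self)
  kids <- lapply(seq_along(node$args), function(i) {
    tree_nodes(node$args[[i]], c(path, i))
  })
  c(self, unlist(kids, recursive = FALSE))
}

get_node <- function(node, path) {
  for (i in path) node <- node$args[[i]]
  node
}

set_node <- function(node, path, replacement) {
  if (length(path) == 0L) return(replacement)
  node$args[[path[1L]]] <- set_node(node$args[[path[1L]]], path[-1L],
                                    replacement)
  node
}

# ---- random tree generation (strongly typed, grow method) -------------------

random_const <- function(ranges) {
  j <- sample.int(nrow(ranges), 1L)
  stats::runif(1L, ranges$lo[j], ranges$hi[j])
}

random_terminal <- function(ctx) {
  if (stats::runif(1L) < 0.5) {
    list(kind = "feat", name = ctx$features[sample.int(length(ctx$features), 1L)])
  } else {
    list(kind = "const", value = random_const(ctx$ranges))
  }
}

# grow a random subtree of the requested type within a depth budget
random_tree <- function(type, depth_budget, ctx, p_stop = 0.3) {
  if (type == "num") {
    if (depth_budget <= 1L || stats::runif(1L) < p_stop) {
      return(random_terminal(ctx))
    }
    name <- sample(c("ADD", "SUB", "MUL", "PDIV"), 1L)
  } else {
    # bool nodes need at least depth 2 (comparison over numeric terminals)
    if (depth_budget <= 2L || stats::runif(1L) < p_stop) {
      name <- sample(c("LT", "LE", "GT", "GE"), 1L)
    } else {
      name <- sample(c("AND", "OR", "XOR", "NOT", "LT", "LE", "GT", "GE"), 1L)
    }
  }
  argtypes <- GP_OPS[[name]]$arg
  args <- lapply(argtypes, random_tree, depth_budget = depth_budget - 1L,
                 ctx = ctx, p_stop = p_stop)
  list(kind = "op", name = name, args = args)
}

random_individual <- function(cfg, ctx) {
  for (attempt in 1:100) {
    depth_cap <- sample(2:min(6L, cfg$max_tree_depth), 1L)
    tree <- random_tree("bool", depth_cap, ctx)
    if (tree_length(tree) <= cfg$max_tree_length &&
        tree_depth(tree) <= cfg$max_tree_depth) {
      return(tree)
    }
  }
  # minimal comparison tree always satisfies the limits
  list(kind = "op", name = "LT",
       args = list(list(kind = "feat", name = ctx$features[1L]),
                   list(kind = "const", value = random_const(ctx$ranges))))
}

# ---- evaluation -------------------------------------------------------------

# vectorized evaluation over a feature data frame; returns logical or numeric
# vector of length nrow(X)
eval_node <- function(node, X) {
  if (node$kind == "feat") return(X[[node$name]])
  if (node$kind == "const") return(rep(node$value, nrow(X)))
  a <- eval_node(node$args[[1L]], X)
  switch(node$name,
         NOT = !a,
         {
           b <- eval_node(node$args[[2L]], X)
           switch(node$name,
                  AND = a & b, OR = a | b, XOR = xor(a, b),
                  LT = a < b, LE = a <= b, GT = a > b, GE = a >= b,
                  ADD = a + b, SUB = a - b, MUL = a * b,
                  PDIV = ifelse(abs(b) < 1e-12, 1, a / b))
         })
}

#' Evaluate a GP model on one or more feature vectors
#'
#' Comparison nodes map reals to Booleans, logical nodes combine Booleans,
#' arithmetic nodes combine reals; protected division returns 1 on a zero
#' divisor. The Boolean root maps TRUE to \code{"gradeIV"} and FALSE to
#' \code{"gradeII"}.
#'
#' @param model A \code{gp_model} (from \code{\link{gp_train}}) or a bare
#'   tree list.
#' @param fv Named numeric vector, single-row list, or data frame of feature
#'   columns.
#' @return Character vector of class labels.
#' @export
evaluate_tree <- function(model, fv) {
  tree <- if (inherits(model, "gp_model")) model$tree else model
  if (!is.data.frame(fv)) {
    fv <- as.data.frame(as.list(fv))
  }
  missing <- setdiff(tree_feature_names(tree), names(fv))
  if (length(missing) > 0L) {
    stop("feature vector lacks features used by the model: ",
         paste(missing, collapse = ", "))
  }
  if (any(!vapply(fv[tree_feature_names(tree)],
                  function(col) all(is.finite(col)), logical(1L)))) {
    stop("feature values must be finite")
  }
  out <- eval_node(tree, fv)
  ifelse(out, GP_LABELS[2L], GP_LABELS[1L])
}

tree_feature_names <- function(tree) {
  nodes <- tree_nodes(tree)
  unique(unlist(lapply(nodes, function(n) if (n$kind == "feat") n$name)))
}

# training accuracy of a tree on a prepared dataset
tree_fitness <- function(tree, feats, y_is_iv) {
  pred <- eval_node(tree, feats)
  mean(pred == y_is_iv)
}

# ---- breeding operators -----------------------------------------------------

tournament_pick <- function(fitness, size) {
  cand <- sample.int(length(fitness), size, replace = TRUE)
  cand[which.max(fitness[cand])]
}

crossover_trees <- function(t1, t2) {
  n1 <- tree_nodes(t1)
  i <- sample.int(length(n1), 1L)
  target <- n1[[i]]
  n2 <- tree_nodes(t2)
  compat <- Filter(function(n) n$type == target$type, n2)
  if (length(compat) == 0L) return(t1)
  donor <- compat[[sample.int(length(compat), 1L)]]
  set_node(t1, target$path, get_node(t2, donor$path))
}

mutate_replace_branch <- function(tree, cfg, ctx) {
  nodes <- tree_nodes(tree)
  i <- sample.int(length(nodes), 1L)
  target <- nodes[[i]]
  budget <- max(2L, cfg$max_tree_depth - length(target$path))
  set_node(tree, target$path, random_tree(target$type, budget, ctx))
}

mutate_change_node_type <- function(tree, cfg, ctx) {
  nodes <- tree_nodes(tree)
  swappable <- Filter(function(n) {
    (n$kind == "op" && length(GP_OP_FAMILY[[n$name]]) > 0L) || n$kind == "feat"
  }, nodes)
  if (length(swappable) == 0L) return(tree)
  target <- swappable[[sample.int(length(swappable), 1L)]]
  node <- get_node(tree, target$path)
  if (node$kind == "op") {
    node$name <- sample(GP_OP_FAMILY[[node$name]], 1L)
  } else {
    node$name <- ctx$features[sample.int(length(ctx$features), 1L)]
  }
  set_node(tree, target$path, node)
}

# re-randomize all numeric constants (full tree shaker) or one (one point)
mutate_shake <- function(tree, ctx, all_constants) {
  nodes <- tree_nodes(tree)
  const_paths <- lapply(Filter(function(n) n$kind == "const", nodes),
                        function(n) n$path)
  if (length(const_paths) == 0L) return(tree)
  if (!all_constants) {
    const_paths <- const_paths[sample.int(length(const_paths), 1L)]
  }
  for (p in const_paths) {
    tree <- set_node(tree, p, list(kind = "const",
                                   value = random_const(ctx$ranges)))
  }
  tree
}

mutate_tree <- function(tree, cfg, ctx) {
  switch(sample.int(4L, 1L),
         mutate_replace_branch(tree, cfg, ctx),
         mutate_change_node_type(tree, cfg, ctx),
         mutate_shake(tree, ctx, all_constants = TRUE),
         mutate_shake(tree, ctx, all_constants = FALSE))
}

# ---- training ---------------------------------------------------------------

prepare_gp_data <- function(data) {
  feats <- intersect(feature_names(), names(data))
  if (length(feats) == 0L) {
    feats <- setdiff(names(data), c("sample_id", "label"))
    feats <- feats[vapply(data[feats], is.numeric, logical(1L))]
  }
  if (length(feats) == 0L) stop("no numeric feature columns found")
  if (!"label" %in% names(data)) stop("data must have a 'label' column")
  y <- as.character(data$label)
  if (!all(y %in% GP_LABELS)) {
    stop("labels must be ", paste(GP_LABELS, collapse = " or "))
  }
  X <- data[feats]
  if (!all(vapply(X, function(col) all(is.finite(col)), logical(1L)))) {
    stop("feature values must be finite")
  }
  lo <- vapply(X, min, numeric(1L))
  hi <- vapply(X, max, numeric(1L))
  degenerate <- hi <= lo
  hi[degenerate] <- lo[degenerate] + 1
  list(X = X, y_is_iv = y == GP_LABELS[2L],
       ctx = list(features = feats,
                  ranges = data.frame(lo = lo, hi = hi)))
}

#' Train a genetic-programming classifier
#'
#' Evolves a population of strongly typed Boolean expression trees over the
#' feature columns. Fitness is training-set accuracy. Each generation keeps
#' \code{elitism_count} elites and fills the rest with tournament-selected
#' parents recombined by subtree crossover (probability
#' \code{crossover_probability}) and mutated with probability
#' \code{mutation_probability_percent}/100 by one of four mutators chosen
#' uniformly: replace-branch, change-node-type, full-tree shaker (re-draws all
#' numeric constants) and one-point shaker (re-draws one constant). Offspring
#' that exceed the depth or length limits are rejected and the parent is
#' retained. Numeric constants are drawn uniformly from the per-feature
#' training ranges. The run is fully reproducible from \code{cfg$seed}.
#'
#' @param data Data frame with a \code{label} column (\code{"gradeII"} /
#'   \code{"gradeIV"}) and numeric feature columns (canonically the 15 of
#'   \code{\link{feature_names}}; any other numeric columns are used if none
#'   of the canonical ones are present).
#' @param cfg A \code{\link{gp_config}}.
#' @return Object of class \code{gp_model}: the best-of-run \code{tree}, its
#'   \code{train_accuracy}, \code{depth}, \code{length}, the feature names and
#'   the generation at which it appeared.
#' @export
gp_train <- function(data, cfg = gp_config()) {
  prep <- prepare_gp_data(data)
  if (length(unique(prep$y_is_iv)) < 2L) {
    stop("training set must contain both classes")
  }
  if (min(table(prep$y_is_iv)) < 2L) {
    stop("training set needs at least 2 samples per class")
  }
  set.seed(cfg$seed)
  gp_train_impl(prep, cfg)
}

gp_train_impl <- function(prep, cfg) {
  X <- prep$X
  y <- prep$y_is_iv
  ctx <- prep$ctx
  pop <- replicate(cfg$population_size, random_individual(cfg, ctx),
                   simplify = FALSE)
  fit <- vapply(pop, tree_fitness, numeric(1L), feats = X, y_is_iv = y)
  best_i <- which.max(fit)
  best <- list(tree = pop[[best_i]], fitness = fit[best_i], generation = 0L)

  gen <- 0L
  while (gen < cfg$max_generations && best$fitness < 1) {
    gen <- gen + 1L
    ord <- order(fit, decreasing = TRUE)
    new_pop <- pop[ord[seq_len(cfg$elitism_count)]]
    new_fit <- fit[ord[seq_len(cfg$elitism_count)]]
    while (length(new_pop) < cfg$population_size) {
      p1 <- tournament_pick(fit, cfg$tournament_size)
      child <- pop[[p1]]
      if (stats::runif(1L) < cfg$crossover_probability) {
        p2 <- tournament_pick(fit, cfg$tournament_size)
        child <- crossover_trees(child, pop[[p2]])
      }
      if (stats::runif(1L) < cfg$mutation_probability_percent / 100) {
        child <- mutate_tree(child, cfg, ctx)
      }
      if (tree_depth(child) > cfg$max_tree_depth ||
          tree_length(child) > cfg$max_tree_length) {
        child <- pop[[p1]]   # reject offspring, retain parent
      }
      new_pop[[length(new_pop) + 1L]] <- child
      new_fit <- c(new_fit, tree_fitness(child, X, y))
    }
    pop <- new_pop
    fit <- new_fit
    gi <- which.max(fit)
    if (fit[gi] > best$fitness) {
      best <- list(tree = pop[[gi]], fitness = fit[gi], generation = gen)
    }
  }
  structure(
    list(tree = best$tree,
         train_accuracy = best$fitness,
         depth = tree_depth(best$tree),
         length = tree_length(best$tree),
         features = ctx$features,
         generation = best$generation,
         config = cfg),
    class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat("GP symbolic classifier\n")
  cat(sprintf("  training accuracy: %.4f (found at generation %d)\n",
              x$train_accuracy, x$generation))
  cat(sprintf("  tree depth %d, length %d\n", x$depth, x$length))
  cat("  ", deparse_tree(x$tree), "\n", sep = "")
  invisible(x)
}

#' Human-readable infix rendering of a model tree
#'
#' @param tree A \code{gp_model} or bare tree.
#' @return Single string.
#' @export
deparse_tree <- function(tree) {
  if (inherits(tree, "gp_model")) tree <- tree$tree
  infix <- c(AND = "&", OR = "|", LT = "<", LE = "<=", GT = ">", GE = ">=",
             ADD = "+", SUB = "-", MUL = "*", PDIV = "/")
  rec <- function(node) {
    if (node$kind == "feat") return(node$name)
    if (node$kind == "const") return(sprintf("%.4g", node$value))
    if (node$name == "NOT") return(paste0("!(", rec(node$args[[1L]]), ")"))
    if (node$name == "XOR") {
      return(paste0("xor(", rec(node$args[[1L]]), ", ",
                    rec(node$args[[2L]]), ")"))
    }
    paste0("(", rec(node$args[[1L]]), " ", infix[[node$name]], " ",
           rec(node$args[[2L]]), ")")
  }
  rec(tree)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a GP model to JSON (prefix-notation expression tree)
#'
#' @param model A \code{gp_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "gp_model"))
  obj <- list(tree = tree_to_list(model$tree),
              train_accuracy = model$train_accuracy,
              depth = model$depth, length = model$length,
              features = model$features, generation = model$generation)
  write_json_report(obj, path)
}

#' Read a GP model written by \code{write_model_json}
#'
#' @param path JSON path.
#' @return A \code{gp_model}.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  tree <- list_to_tree(obj$tree)
  structure(
    list(tree = tree,
         train_accuracy = as.numeric(obj$train_accuracy),
         depth = tree_depth(tree), length = tree_length(tree),
         features = unlist(obj$features), generation = obj$generation),
    class = "gp_model")
}

tree_to_list <- function(node) {
  switch(node$kind,
         op = list(op = node$name, args = lapply(node$args, tree_to_list)),
         feat = list(feature = node$name),
         const = list(const = node$value))
}

list_to_tree <- function(x) {
  if (!is.null(x$op)) {
    list(kind = "op", name = x$op, args = lapply(x$args, list_to_tree))
  } else if (!is.null(x$feature)) {
    list(kind = "feat", name = x$feature)
  } else {
    list(kind = "const", value = as.numeric(x$const))
  }
}

# ---- cross-validation and grid search --------------------------------------

# deterministic stratified fold assignment; depends only on labels and seed
stratified_folds <- function(y_is_iv, n_folds) {
  folds <- integer(length(y_is_iv))
  for (cls in c(FALSE, TRUE)) {
    idx <- which(y_is_iv == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Stratified repeated cross-validation of the GP classifier
#'
#' Runs stratified \code{n_folds}-fold cross-validation \code{n_runs} times
#' with seeds derived from \code{cfg$seed}. Fold assignment is re-randomized
#' each run. Within a fold, the model is trained only on the training portion
#' and evaluated on the held-out fold. The headline figure is the accuracy of
#' the best run (mean over its folds), reported alongside the mean and
#' standard deviation across runs. Setting \code{n_folds} equal to the sample
#' count gives leave-one-out validation (singleton folds; stratification is
#' vacuous there).
#'
#' @param data Labeled feature data frame (see \code{\link{gp_train}}).
#' @param cfg A \code{\link{gp_config}}.
#' @return Object of class \code{gp_cv_result}: per-run fold accuracies, fold
#'   assignments, per-run best models, \code{mean_accuracy}, \code{sd_accuracy},
#'   \code{best_run}, \code{best_accuracy}, \code{best_model} and the derived
#'   seeds.
#' @export
cross_validate <- function(data, cfg = gp_config()) {
  prep <- prepare_gp_data(data)
  n <- length(prep$y_is_iv)
  counts <- table(factor(prep$y_is_iv, levels = c(FALSE, TRUE)))
  loo <- cfg$n_folds == n   # leave-one-out: singleton folds, unstratified
  if (!loo && min(counts) < cfg$n_folds) {
    stop("each class needs at least n_folds = ", cfg$n_folds, " samples")
  }
  set.seed(cfg$seed)
  run_seeds <- sample.int(2^31 - 1L, cfg$n_runs * (cfg$n_folds + 1L))
  run_seeds <- matrix(run_seeds, nrow = cfg$n_runs)

  runs <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    set.seed(run_seeds[r, 1L])
    folds <- if (loo) sample.int(n) else
      stratified_folds(prep$y_is_iv, cfg$n_folds)
    fold_acc <- numeric(cfg$n_folds)
    fold_models <- vector("list", cfg$n_folds)
    for (k in seq_len(cfg$n_folds)) {
      tr <- folds != k
      fold_cfg <- cfg
      fold_cfg$seed <- run_seeds[r, k + 1L]
      prep_tr <- list(X = prep$X[tr, , drop = FALSE],
                      y_is_iv = prep$y_is_iv[tr],
                      ctx = list(features = prep$ctx$features,
                                 ranges = feature_ranges(prep$X[tr, , drop = FALSE])))
      set.seed(fold_cfg$seed)
      model <- gp_train_impl(prep_tr, fold_cfg)
      pred <- eval_node(model$tree, prep$X[!tr, , drop = FALSE])
      fold_acc[k] <- mean(pred == prep$y_is_iv[!tr])
      fold_models[[k]] <- model
    }
    best_fold <- which.max(fold_acc)
    runs[[r]] <- list(fold_accuracies = fold_acc,
                      mean_accuracy = mean(fold_acc),
                      folds = folds,
                      best_model = fold_models[[best_fold]],
                      fold_models = fold_models)
  }
  run_means <- vapply(runs, `[[`, numeric(1L), "mean_accuracy")
  best_run <- which.max(run_means)
  structure(
    list(runs = runs,
         run_accuracies = run_means,
         mean_accuracy = mean(run_means),
         sd_accuracy = stats::sd(run_means),
         best_run = best_run,
         best_accuracy = run_means[best_run],
         best_model = runs[[best_run]]$best_model,
         n_runs = cfg$n_runs,
         n_folds = cfg$n_folds,
         seeds = run_seeds[, 1L],
         config = cfg),
    class = "gp_cv_result")
}

feature_ranges <- function(X) {
  lo <- vapply(X, min, numeric(1L))
  hi <- vapply(X, max, numeric(1L))
  degenerate <- hi <= lo
  hi[degenerate] <- lo[degenerate] + 1
  data.frame(lo = lo, hi = hi)
}

#' @export
print.gp_cv_result <- function(x, ...) {
  cat(sprintf(
    "GP cross-validation: %d runs x %d folds\n", x$n_runs, x$n_folds))
  cat(sprintf("  mean accuracy %.4f +/- %.4f (sd across runs)\n",
              x$mean_accuracy, if (is.na(x$sd_accuracy)) 0 else x$sd_accuracy))
  cat(sprintf("  best run %d: accuracy %.4f\n", x$best_run, x$best_accuracy))
  invisible(x)
}

#' Grid search over the reference parameter grid
#'
#' Cross-validates every configuration of the grid (by default the 24-cell
#' reference grid of \code{\link{gp_default_grid}}) and ranks the results by
#' best-run accuracy, non-increasing.
#'
#' @param data Labeled feature data frame.
#' @param grid Data frame of configuration columns overriding
#'   \code{base_cfg}; one row per configuration.
#' @param base_cfg \code{\link{gp_config}} supplying the remaining settings
#'   (folds, runs, seed, ...).
#' @return Object of class \code{gp_grid_result}: \code{table} (ranked
#'   configurations with accuracies) and \code{results} (the
#'   \code{gp_cv_result} objects, in table order).
#' @export
grid_search <- function(data, grid = gp_default_grid(),
                        base_cfg = gp_config()) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) stop("grid must be non-empty")
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_cfg
    for (nm in names(grid)) cfg[[nm]] <- grid[i, nm]
    cfg <- do.call(gp_config, unclass(cfg))
    results[[i]] <- cross_validate(data, cfg)
  }
  best <- vapply(results, `[[`, numeric(1L), "best_accuracy")
  means <- vapply(results, `[[`, numeric(1L), "mean_accuracy")
  ord <- order(best, decreasing = TRUE)
  tab <- cbind(grid[ord, , drop = FALSE],
               best_accuracy = best[ord],
               mean_accuracy = means[ord])
  rownames(tab) <- NULL
  structure(list(table = tab, results = results[ord]),
            class = "gp_grid_result")
}

#' @export
print.gp_grid_result <- function(x, ...) {
  cat("GP grid search over", nrow(x$table), "configurations\n")
  print(utils::head(x$table, 5L))
  invisible(x)
}
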
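# Random-forest prediction of clade membership under an escalating
# label-perturbation null. Each (perturbation level, replicate) run:
# perturb labels -> 75/25 random split -> 100-tree forest -> validation
# accuracy + impurity importances. All randomness derives from a per-run
# seed expanded deterministically from one base seed.

#' Perturb clade labels
#'
#' Independently for each terminal, with probability `p` the label is
#' replaced by a uniform draw over the set of observed clade names; with
#' probability `1 - p` it is kept. Under the default `"inclusive"` variant
#' the draw includes the original label (so the effective change probability
#' is `p * (k - 1) / k` for `k` clades); `"exclusive"` always draws a
#' different label.
#'
#' @param labels Character vector of clade names (>= 2 distinct when p > 0).
#' @param p Perturbation probability in \[0, 1\].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param variant `"inclusive"` (default) or `"exclusive"`.
#' @return Perturbed label vector, names preserved.
#' @export
perturb_labels <- function(labels, p, seed = NULL,
                           variant = c("inclusive", "exclusive")) {
  variant <- match.arg(variant)
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("`p` must be a single probability in [0, 1]")
  nm <- names(labels)
  labels <- as.character(labels)
  out <- labels
  names(out) <- nm
  pool <- sort(unique(labels))
  if (p > 0 && length(pool) < 2L)
    stop("perturbation undefined with a single clade label")
  if (!is.null(seed)) set.seed(seed)
  if (p == 0) return(out)
  hit <- stats::runif(length(labels)) < p
  if (any(hit)) {
    if (variant == "inclusive") {
      out[hit] <- sample(pool, sum(hit), replace = TRUE)
    } else {
      out[hit] <- vapply(labels[hit], function(l)
        sample(setdiff(pool, l), 1L), character(1))
    }
  }
  out
}

#' Run one forest replicate at a perturbation level
#'
#' Perturbs the labels, draws a simple random (unstratified) training set of
#' `floor(train_frac * n)` rows, fits a random forest of `n_trees` trees on
#' the one-hot matrix (remaining hyperparameters at the forest
#' implementation's documented defaults, recorded in the result), and scores
#' plain accuracy on the held-out rows against their perturbed labels,
#' capturing normalized impurity-based importances. Fully reproducible from
#' `seed`.
#'
#' @param X Binary matrix (terminals x encoded columns), or a `cf_encoded`.
#' @param y Clade labels aligned with the rows of `X` (taken from a
#'   `cf_encoded` when omitted).
#' @param p Perturbation level in \[0, 1\].
#' @param seed Integer seed for this run.
#' @param n_trees Number of decision trees (default 100).
#' @param train_frac Training fraction (default 0.75).
#' @param perturb_variant Passed to [perturb_labels()].
#' @return A list of class `cf_run`: `level`, `seed`, `accuracy`,
#'   `importance` (named, sums to 1 when nonzero), `n_train`,
#'   `n_validation`, `hyperparameters`.
#' @export
run_replicate <- function(X, y = NULL, p, seed, n_trees = 100L,
                          train_frac = 0.75,
                          perturb_variant = c("inclusive", "exclusive")) {
  perturb_variant <- match.arg(perturb_variant)
  if (inherits(X, "cf_encoded")) {
    if (is.null(y)) y <- X$labels
    X <- X$X
  }
  y <- as.character(y)
  n <- nrow(X)
  if (length(y) != n) stop("labels must align with the rows of X")
  if (n < 8L) stop("need at least 8 rows")
  if (train_frac <= 0 || train_frac >= 1) stop("`train_frac` in (0, 1)")

  set.seed(seed)
  y_p <- perturb_labels(y, p, seed = NULL, variant = perturb_variant)
  classes <- sort(unique(y_p))
  n_train <- floor(train_frac * n)
  train <- sample.int(n, n_train)
  val <- setdiff(seq_len(n), train)
  missing_classes <- setdiff(classes, y_p[train])
  if (length(missing_classes))
    warning("clade(s) absent from the training split: ",
            paste(missing_classes, collapse = ", "))
  fit <- ranger::ranger(
    x = X[train, , drop = FALSE],
    y = factor(y_p[train], levels = sort(unique(y_p[train]))),
    num.trees = n_trees, importance = "impurity",
    seed = seed, num.threads = 1L)
  pred <- stats::predict(fit, X[val, , drop = FALSE],
                         num.threads = 1L)$predictions
  acc <- mean(as.character(pred) == y_p[val])
  imp <- fit$variable.importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  structure(list(
    level = p, seed = seed, accuracy = acc,
    importance = imp[colnames(X)],
    n_train = n_train, n_validation = n - n_train,
    hyperparameters = list(num.trees = n_trees, mtry = fit$mtry,
                           min.node.size = fit$min.node.size,
                           splitrule = fit$splitrule,
                           replace = TRUE, sample.fraction = 1,
                           importance = "impurity",
                           perturb_variant = perturb_variant)),
    class = "cf_run")
}

# per-run seed: deterministic, documented expansion of one base seed.
# Runs are slotted (level index, replicate index); the base seed occupies
# the high bits so the result stays below 2^31 - 1.
.run_seed <- function(base_seed, level_index, replicate, n_levels,
                      n_replicates) {
  slot <- (level_index - 1L) * n_replicates + (replicate - 1L)
  width <- n_levels * n_replicates
  base <- base_seed %% ((2147483647L - width) %/% width)
  as.integer(base * width + slot + 1L)
}

#' Full label-perturbation sweep
#'
#' Runs [run_replicate()] for every perturbation level and replicate (the
#' default grid is 0 to 1 at 0.01 increments, ten replicates: 1010 forest
#' fits) and fits the accuracy-degradation regression over all replicate
#' points.
#'
#' @inheritParams run_replicate
#' @param levels Perturbation levels in \[0, 1\].
#' @param replicates Replicates per level (default 10).
#' @param base_seed Base seed expanded deterministically into per-run seeds.
#' @return A list of class `cf_sweep`: `runs` (data frame: level, replicate,
#'   seed, accuracy, n_train, n_validation), `importances` (runs x columns
#'   matrix), `regression` (see [fit_accuracy_regression()]; `NULL` if a
#'   single level was swept), `levels`, `replicates`, `base_seed`,
#'   `hyperparameters`.
#' @export
sweep_perturbation <- function(X, y = NULL, levels = seq(0, 1, by = 0.01),
                               replicates = 10L, base_seed = 1L,
                               n_trees = 100L, train_frac = 0.75,
                               perturb_variant = c("inclusive", "exclusive")) {
  perturb_variant <- match.arg(perturb_variant)
  if (!length(levels) || any(levels < 0 | levels > 1))
    stop("`levels` must be nonempty, within [0, 1]")
  if (inherits(X, "cf_encoded")) {
    if (is.null(y)) y <- X$labels
    X <- X$X
  }
  nl <- length(levels); nr <- as.integer(replicates)
  runs <- vector("list", nl * nr)
  imp <- matrix(NA_real_, nl * nr, ncol(X),
                dimnames = list(NULL, colnames(X)))
  tab <- data.frame(level = numeric(nl * nr), replicate = integer(nl * nr),
                    seed = integer(nl * nr), accuracy = numeric(nl * nr),
                    n_train = integer(nl * nr),
                    n_validation = integer(nl * nr))
  k <- 0L
  for (li in seq_len(nl)) {
    for (ri in seq_len(nr)) {
      k <- k + 1L
      sd <- .run_seed(base_seed, li, ri, nl, nr)
      r <- run_replicate(X, y, p = levels[li], seed = sd, n_trees = n_trees,
                         train_frac = train_frac,
                         perturb_variant = perturb_variant)
      runs[[k]] <- r
      imp[k, ] <- r$importance
      tab[k, ] <- list(levels[li], ri, sd, r$accuracy, r$n_train,
                       r$n_validation)
    }
  }
  reg <- if (nl >= 2L) fit_accuracy_regression(tab) else NULL
  structure(list(runs = tab, importances = imp, regression = reg,
                 levels = levels, replicates = nr, base_seed = base_seed,
                 hyperparameters = runs[[1L]]$hyperparameters),
            class = "cf_sweep")
}

#' @export
print.cf_sweep <- function(x, ...) {
  cat("Perturbation sweep: ", length(x$levels), " levels x ", x$replicates,
      " replicates = ", nrow(x$runs), " forest runs\n", sep = "")
  p0 <- x$runs$accuracy[x$runs$level == min(x$levels)]
  cat(sprintf("  mean accuracy at p=%.2f: %.4f\n", min(x$levels), mean(p0)))
  if (!is.null(x$regression))
    cat(sprintf("  accuracy ~ level: slope %.4f, R2 %.4f, p %.3g\n",
                x$regression$slope, x$regression$r_squared,
                x$regression$p_value))
  invisible(x)
}

#' Accuracy-degradation regression
#'
#' Ordinary least squares of validation accuracy on perturbation level over
#' all replicate points (not level means).
#'
#' @param runs A `cf_sweep`, or a data frame with `level` and `accuracy`.
#' @param on_means Fit on per-level mean accuracies instead of replicate
#'   points (default `FALSE`).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value` (two-sided,
#'   for the slope).
#' @export
fit_accuracy_regression <- function(runs, on_means = FALSE) {
  if (inherits(runs, "cf_sweep")) runs <- runs$runs
  stopifnot(all(c("level", "accuracy") %in% names(runs)))
  if (nrow(runs) < 3L) stop("need at least 3 runs")
  if (length(unique(runs$level)) < 2L)
    stop("all runs are at a single perturbation level")
  if (on_means) {
    agg <- stats::aggregate(accuracy ~ level, data = runs, FUN = mean)
    runs <- agg
  }
  if (stats::var(runs$accuracy) == 0)  # constant accuracy: flat fit
    return(list(slope = 0, intercept = runs$accuracy[1L], r_squared = 0,
                p_value = 1))
  fit <- stats::lm(accuracy ~ level, data = runs)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[["level"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients["level", "Pr(>|t|)"]))
}

#' Aggregate feature importances at a perturbation level
#'
#' Averages the per-column impurity importances over the replicates of one
#' level and ranks them in decreasing order (ties broken lexicographically).
#' Columns are value-level one-hot names such as `"CatHF=Pimelodidae"`.
#'
#' @param sweep A `cf_sweep`.
#' @param level A perturbation level present in the sweep.
#' @param top_n Number of top columns to return (default all).
#' @return Data frame with `column` and `mean_importance`, sorted.
#' @export
aggregate_importances <- function(sweep, level, top_n = Inf) {
  stopifnot(inherits(sweep, "cf_sweep"))
  idx <- which(abs(sweep$runs$level - level) < 1e-12)
  if (!length(idx)) stop("level ", level, " is not in the sweep")
  m <- colMeans(sweep$importances[idx, , drop = FALSE])
  ord <- order(-m, names(m))
  out <- data.frame(column = names(m)[ord], mean_importance = unname(m)[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, top_n)
}
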
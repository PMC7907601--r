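#' Replicated k-fold cross-validation of the prediction models
#'
#' One replicate shuffles the lines into k folds (sizes differing by at
#' most one) and rotates the test fold; held-out predictions are pooled
#' over the k folds and the replicate's accuracy is the Pearson
#' correlation between pooled predictions and observed values. Accuracies
#' are summarised by their mean and standard error over all replicates,
#' which are partitioned into \code{sets} replication sets (set-level
#' means also reported).
#'
#' @param y named vector of genotype-level trait values (BLUEs), aligned
#'   with the rows of K.
#' @param K genomic relationship matrix over the same lines.
#' @param sri optional matrix of secondary-trait (index) values, lines x
#'   indices, required by the srir / gs_sri / multigs models.
#' @param model one of "unigs", "srir", "gs_sri", "multigs".
#' @param k folds (default 5, i.e. 80/20 splits).
#' @param replicates total replicates (default 100, as two 50-replicate
#'   sets).
#' @param sets number of replication sets the replicates divide into.
#' @param seed root seed; each replicate derives its own substream.
#' @param include_fixed for gs_sri, add the fixed index part to the
#'   prediction (see \code{\link{predict.gs_covfit}}).
#' @param min_test smallest admissible test fold.
#' @param ... passed to the model fitters (e.g. \code{tol} for multigs).
#' @return object of class \code{gs_cv}: per-replicate accuracies, mean,
#'   SE, set means.
#' @export
kfold_cv <- function(y, K, sri = NULL, model = c("unigs", "srir", "gs_sri", "multigs"),
                     k = 5, replicates = 100, sets = 2, seed = 1,
                     include_fixed = TRUE, min_test = 5, ...) {
  model <- match.arg(model)
  y <- drop(y)
  n <- length(y)
  stopifnot(k >= 2, nrow(K) == n)
  if (model != "unigs") {
    if (is.null(sri)) stop("model ", model, " needs secondary-trait values (sri)")
    sri <- as.matrix(sri)
    stopifnot(nrow(sri) == n)
  }
  if (floor(n / k) < min_test)
    stop("test folds would have fewer than ", min_test,
         " lines; population too small for k = ", k)
  acc <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(derive_seed(seed, paste0("cv_rep", r)))
    fold <- rep(seq_len(k), length.out = n)[sample.int(n)]
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      pred[test] <- predict_heldout(model, y, K, sri, train, test,
                                    include_fixed = include_fixed, ...)
    }
    acc[r] <- stats::cor(pred, y)
  }
  new_gs_cv(acc, sets = sets, model = model, n = n, k = k, seed = seed)
}

## fit on `train`, predict the held-out `test` lines
predict_heldout <- function(model, y, K, sri, train, test,
                            include_fixed = TRUE, ...) {
  switch(model,
    unigs = {
      fit <- reml_single_trait(y[train], K[train, train, drop = FALSE])
      alpha <- gblup_alpha(fit, K[train, train, drop = FALSE], y[train])
      drop(K[test, train, drop = FALSE] %*% alpha)
    },
    srir = {
      fit <- fit_sri_regression(y[train], sri[train, , drop = FALSE])
      predict(fit, sri[test, , drop = FALSE])
    },
    gs_sri = {
      fit <- fit_covariate_gs(y[train], sri[train, , drop = FALSE],
                              K[train, train, drop = FALSE])
      predict(fit, K[test, train, drop = FALSE], sri[test, , drop = FALSE],
              include_fixed = include_fixed)
    },
    multigs = {
      Y <- cbind(primary = y, sri)
      Y[test, 1] <- NA
      idx <- c(train, test)
      fit <- fit_multitrait_gs(Y[idx, , drop = FALSE],
                               K[idx, idx, drop = FALSE], ...)
      fit$gebv[match(test, idx), 1]
    })
}

new_gs_cv <- function(acc, sets = 1, model = "unigs", n = NA, k = NA, seed = NA) {
  set_id <- rep(seq_len(sets), length.out = length(acc) * sets)[seq_along(acc)]
  set_id <- sort(set_id)
  structure(list(accuracies = acc, mean = mean(acc),
                 se = stats::sd(acc) / sqrt(length(acc)),
                 sets = set_id,
                 set_means = tapply(acc, set_id, mean),
                 model = model, n = n, k = k, seed = seed),
            class = "gs_cv")
}

#' @export
print.gs_cv <- function(x, ...) {
  cat(sprintf("Cross-validation accuracy: %s model, %d lines, %d-fold, %d replicates\n",
              x$model, x$n, x$k, length(x$accuracies)))
  cat(sprintf("  mean %.3f (SE %.3f); set means: %s\n", x$mean, x$se,
              paste(sprintf("%.3f", x$set_means), collapse = ", ")))
  invisible(x)
}

#' @export
plot.gs_cv <- function(x, ..., main = NULL) {
  graphics::boxplot(x$accuracies ~ x$sets, xlab = "replication set",
                    ylab = "prediction accuracy (r)",
                    main = main %||% sprintf("%s model", x$model), ...)
  invisible(x)
}

#' Across-environment independent validation
#'
#' Trains a model on one environment's BLUEs (plus that environment's
#' secondary traits where the model uses them) and predicts the lines of
#' another environment from their genotypes plus the test environment's
#' secondary traits -- the "spectra collected, plots not harvested"
#' scenario. Accuracy is the Pearson correlation against the test
#' environment's BLUEs. Lines missing from either environment or from K
#' are dropped to the common set (count recorded).
#'
#' @param y_train named vector of training-environment BLUEs.
#' @param y_test named vector of test-environment BLUEs.
#' @param K genomic relationship matrix containing all lines involved.
#' @param sri_train,sri_test secondary-trait matrices (rownames = lines)
#'   for the training and test environments.
#' @param model one of "unigs", "srir", "gs_sri", "multigs".
#' @param stage label used in error messages when test secondary traits
#'   are missing.
#' @param include_fixed see \code{\link{kfold_cv}}.
#' @param ... passed to the model fitters.
#' @return list of class \code{gs_validation}: accuracy, n_common,
#'   predictions, observed.
#' @export
independent_validation <- function(y_train, y_test, K, sri_train = NULL,
                                   sri_test = NULL,
                                   model = c("unigs", "srir", "gs_sri", "multigs"),
                                   stage = "secondary", include_fixed = TRUE, ...) {
  model <- match.arg(model)
  if (model != "unigs" && is.null(sri_train))
    stop("model ", model, " needs training-environment secondary traits (", stage, ")")
  if (model != "unigs" && is.null(sri_test))
    stop("model ", model, " needs test-environment secondary traits (stage: ",
         stage, ")")
  tr <- intersect(names(y_train), rownames(K))
  te <- intersect(names(y_test), rownames(K))
  if (model != "unigs") {
    if (is.null(colnames(sri_train)))
      colnames(sri_train) <- paste0("SRI", seq_len(ncol(sri_train)))
    if (is.null(colnames(sri_test)))
      colnames(sri_test) <- colnames(sri_train)
    tr <- intersect(tr, rownames(sri_train))
    te <- intersect(te, rownames(sri_test))
  }
  dropped <- (length(y_train) - length(tr)) + (length(y_test) - length(te))
  if (!length(tr) || !length(te))
    stop("no common lines between phenotypes and K")
  yA <- y_train[tr]
  pred <- switch(model,
    unigs = {
      fit <- reml_single_trait(yA, K[tr, tr])
      alpha <- gblup_alpha(fit, K[tr, tr], yA)
      drop(K[te, tr, drop = FALSE] %*% alpha)
    },
    srir = {
      fit <- fit_sri_regression(yA, sri_train[tr, , drop = FALSE])
      predict(fit, sri_test[te, , drop = FALSE])
    },
    gs_sri = {
      fit <- fit_covariate_gs(yA, sri_train[tr, , drop = FALSE], K[tr, tr])
      predict(fit, K[te, tr, drop = FALSE], sri_test[te, , drop = FALSE],
              include_fixed = include_fixed)
    },
    multigs = {
      lines <- union(tr, te)
      S <- matrix(NA_real_, length(lines), 1 + ncol(sri_train),
                  dimnames = list(lines, c("primary", colnames(sri_train))))
      S[tr, 1] <- yA
      S[tr, -1] <- sri_train[tr, , drop = FALSE]
      S[te, -1] <- sri_test[te, , drop = FALSE]
      fit <- fit_multitrait_gs(S, K[lines, lines], ...)
      fit$gebv[te, 1]
    })
  structure(list(accuracy = stats::cor(pred, y_test[te]),
                 n_train = length(tr), n_test = length(te),
                 n_dropped = dropped, model = model,
                 predictions = stats::setNames(pred, te),
                 observed = y_test[te]),
            class = "gs_validation")
}

#' @export
print.gs_validation <- function(x, ...) {
  cat(sprintf("Independent validation (%s): accuracy %.3f (train n=%d, test n=%d%s)\n",
              x$model, x$accuracy, x$n_train, x$n_test,
              if (x$n_dropped) sprintf(", %d lines dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Relative improvement in prediction accuracy
#'
#' Per environment, \eqn{100 (a_{with} - a_{base}) / a_{base}} percent,
#' plus the unweighted mean across environments. Values are reported both
#' raw and rounded to the usual reporting precision (whole percent, one
#' decimal below 10). Environments with non-positive baseline accuracy
#' have undefined improvement and are reported missing.
#'
#' @param base numeric vector of baseline (e.g. univariate) accuracies.
#' @param improved numeric vector of accuracies with secondary traits.
#' @param environments labels (default names of \code{base}).
#' @return data.frame of class \code{gs_improvement}: environment, base,
#'   improved, improvement_pct (raw), improvement (rounded); final row is
#'   the mean across environments.
#' @export
summarize_improvement <- function(base, improved, environments = NULL) {
  stopifnot(length(base) == length(improved))
  environments <- environments %||% names(base) %||%
    paste0("env", seq_along(base))
  raw <- ifelse(base > 0, 100 * (improved - base) / base, NA_real_)
  res <- data.frame(environment = environments, base = base,
                    improved = improved, improvement_pct = raw,
                    improvement = round_report(raw), row.names = NULL)
  mean_raw <- mean(raw, na.rm = TRUE)
  res <- rbind(res, data.frame(environment = "mean", base = NA,
                               improved = NA, improvement_pct = mean_raw,
                               improvement = round_report(mean_raw)))
  class(res) <- c("gs_improvement", class(res))
  res
}

## reporting precision: whole percent, one decimal below 10
round_report <- function(x) {
  ifelse(is.na(x), NA_real_, ifelse(abs(x) < 10, round(x, 1), round(x)))
}

#' @export
print.gs_improvement <- function(x, ...) {
  df <- as.data.frame(x)
  df$improvement <- ifelse(is.na(df$improvement), "-",
                           paste0(df$improvement, "%"))
  print(df[, c("environment", "base", "improved", "improvement")],
        row.names = FALSE)
  invisible(x)
}
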
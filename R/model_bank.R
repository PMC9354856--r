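# The virtual microarray: one weighted elastic-net model per retained
# gene, trained on chemical descriptors plus in vitro log2 fold changes,
# hyperparameters chosen by 5-fold cross-validation over an alpha x
# lambda grid.

#' Fit one weighted elastic-net gene model
#'
#' Minimizes the weighted elastic-net objective
#' `(1/(2*sum(w))) * sum_i w_i (y_i - b0 - x_i . b)^2 +
#'  lambda * (alpha * |b|_1 + (1-alpha)/2 * |b|_2^2)`
#' over an alpha grid and a 100-point log-spaced lambda path (from the
#' data-derived lambda_max down four decades), selecting the pair with
#' minimum weighted cross-validated MSE. The solver is glmnet, so lambda
#' follows the glmnet parameterization: the L1 term is penalized exactly
#' as written, while the quadratic term is additionally divided by the
#' weighted standard deviation of `y` (glmnet fits on the standardized
#' response). Because lambda is chosen by cross-validation over a
#' data-derived path, the two parameterizations index the same model
#' family. Folds are drawn once from the
#' seed and shared across the whole grid. Features are standardized
#' internally; the training means/sds are stored in the model and
#' coefficients are reported on both the standardized and the original
#' scale.
#'
#' @param x Numeric feature matrix (substances x features) with column
#'   names; descriptor columns plus in vitro log2 fold-change columns.
#' @param y In vivo log2 fold change of the target gene.
#' @param weights Per-substance sample weights (default 1).
#' @param invitro_features Character vector naming the columns of `x`
#'   that belong to the in vitro block (for the importance score).
#' @param gene_id Identifier stored in the model.
#' @param alpha_grid Elastic-net mixing values in \[0,1\].
#' @param nlambda Length of the lambda path.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed for the fold draw.
#' @param foldid Optional explicit fold assignment (overrides `seed`).
#' @param lambda_grid Optional fixed (decreasing) lambda sequence that
#'   replaces the data-derived path — mainly for forcing a penalty in
#'   tests and sensitivity checks.
#' @param selection `"cv_1se"` (default): after locating the grid
#'   minimum, move to the largest lambda (same alpha) whose CV MSE is
#'   within one standard error of the minimum — the parsimonious rule
#'   that guards against the over-selection of minimum-CV lasso fits.
#'   `"cv_min"`: take the grid minimum itself.
#' @return A `gene_model`: intercept, sparse named coefficients (`beta`
#'   standardized scale, `beta_original` raw scale), `alpha`, `lambda`,
#'   `cv_mse`, feature standardization, in vitro feature names and a
#'   degeneracy flag.
#' @export
fit_gene_model <- function(x, y, weights = rep(1, length(y)),
                           invitro_features = character(0),
                           gene_id = "gene",
                           alpha_grid = seq(0, 1, by = 0.1),
                           nlambda = 100, cv_folds = 5,
                           seed = 1, foldid = NULL, lambda_grid = NULL,
                           selection = c("cv_1se", "cv_min")) {
  selection <- match.arg(selection)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), length(weights) == length(y))
  if (nrow(x) < cv_folds) {
    stop("need at least ", cv_folds, " substances for ", cv_folds,
         "-fold cross-validation", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in training data",
                                 call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1  # constant features stay constant; coef forced to 0
  xs <- scale(x, center = ctr, scale = scl)

  finish <- function(beta, b0, alpha, lambda, cv_mse, degenerate = FALSE) {
    beta <- stats::setNames(as.numeric(beta), colnames(x))
    beta_orig <- beta / scl
    b0_orig <- b0 - sum(beta_orig * ctr)
    structure(list(gene_id = gene_id, intercept = b0_orig,
                   intercept_std = b0,
                   beta = beta, beta_original = beta_orig,
                   alpha = alpha, lambda = lambda, cv_mse = cv_mse,
                   feature_means = stats::setNames(ctr, colnames(x)),
                   feature_sds = stats::setNames(scl, colnames(x)),
                   invitro_features = invitro_features,
                   degenerate = degenerate),
              class = "gene_model")
  }

  wmean_y <- sum(weights * y) / sum(weights)
  if (stats::var(y) == 0) {
    return(finish(rep(0, ncol(x)), wmean_y, NA_real_, NA_real_, 0,
                  degenerate = TRUE))
  }

  if (is.null(foldid)) {
    foldid <- draw_folds(nrow(x), cv_folds, seed)
  }
  best <- list(mse = Inf)
  for (alpha in alpha_grid) {
    path <- lambda_grid %||% lambda_path(xs, y, weights, alpha, nlambda)
    path <- sort(path, decreasing = TRUE)
    cv_mse <- matrix(NA_real_, cv_folds, length(path))
    cv_w <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      fit <- quiet_glmnet(
        glmnet::glmnet(xs[tr, , drop = FALSE], y[tr],
                       weights = weights[tr], alpha = alpha,
                       lambda = path, standardize = FALSE,
                       thresh = 1e-10))
      pred <- stats::predict(fit, xs[!tr, , drop = FALSE])
      # glmnet may stop the path early; align to the requested grid
      got <- match(signif(fit$lambda, 10), signif(path, 10))
      err <- sweep(pred, 1, y[!tr])^2
      wmse <- colSums(err * weights[!tr]) / sum(weights[!tr])
      cv_mse[f, got] <- wmse
      cv_w[f] <- sum(weights[!tr])
    }
    mean_mse <- colSums(cv_mse * cv_w, na.rm = FALSE) / sum(cv_w)
    ok <- which(!is.na(mean_mse))
    if (length(ok) == 0) next
    j <- ok[which.min(mean_mse[ok])]
    if (mean_mse[j] < best$mse) {
      if (selection == "cv_1se") {
        se <- stats::sd(cv_mse[, j]) / sqrt(cv_folds)
        # largest lambda (sparsest fit) within one SE of the minimum
        j_sel <- min(ok[mean_mse[ok] <= mean_mse[j] + se])
      } else {
        j_sel <- j
      }
      best <- list(mse = mean_mse[j], alpha = alpha,
                   lambda = path[j_sel], cv_mse_sel = mean_mse[j_sel],
                   path = path)
    }
  }
  # tighter tolerance for the reported coefficients than for the CV
  # fold fits, where only the relative ranking of grid points matters
  fit <- quiet_glmnet(
    glmnet::glmnet(xs, y, weights = weights, alpha = best$alpha,
                   lambda = best$path, standardize = FALSE,
                   thresh = 1e-14, maxit = 1e6))
  co <- stats::coef(fit, s = best$lambda)  # lambda lies on the fitted path
  finish(co[-1], co[1], best$alpha, best$lambda, best$cv_mse_sel)
}

# glmnet warns when the last (smallest) lambdas of a path do not reach
# the coordinate-descent tolerance; the partial path it returns is
# aligned to the requested grid, so these warnings are expected noise.
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("Convergence for .*lambda", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Substance-level fold assignment, balanced sizes, drawn once from seed.
draw_folds <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample(rep_len(seq_len(k), n))
}

# lambda_max is the smallest penalty that zeroes every coefficient
# (for alpha = 0 the ridge path uses the alpha = 0.001 convention).
lambda_path <- function(xs, y, w, alpha, nlambda) {
  wn <- w / sum(w)
  r <- y - sum(wn * y)
  lmax <- max(abs(crossprod(xs, wn * r))) / max(alpha, 0.001)
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = nlambda))
}

#' @export
print.gene_model <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat("gene_model '", x$gene_id, "': ", nz, "/", length(x$beta),
      " nonzero coefficients, alpha = ", format(x$alpha),
      ", lambda = ", format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' Predict one gene's in vivo log2 fold change
#' @param object A `gene_model`.
#' @param newx Feature matrix on the original (unstandardized) scale with
#'   the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gene_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)[, names(object$beta), drop = FALSE]
  drop(object$intercept + newx %*% object$beta_original)
}

#' Share of model weight carried by in vitro features
#'
#' The ratio of summed absolute standardized coefficients over the in
#' vitro feature block to the sum over all features; 0 for an all-zero
#' model. Genes with high values are those whose in vivo response the
#' bank predicts mainly from the in vitro transcriptome rather than from
#' chemical structure.
#'
#' @param model A `gene_model`.
#' @return Importance in \[0, 1\].
#' @export
invitro_importance <- function(model) {
  total <- sum(abs(model$beta))
  if (total == 0) return(0)
  sum(abs(model$beta[names(model$beta) %in% model$invitro_features])) / total
}

#' Train the full model bank (virtual microarray)
#'
#' Fits one weighted elastic-net model per retained gene. Every model
#' sees the same feature matrix: all curated/normalized descriptor
#' columns plus the in vitro log2 fold changes of all retained genes
#' (the elastic net performs the per-gene selection). Sample weights for
#' gene g come from the magnitude of g's adjusted in vivo fold change.
#' Training medians of the in vitro features are stored for later
#' imputation of substances lacking in vitro data.
#'
#' @param invivo Adjusted in vivo `fold_change_matrix` (training target).
#' @param invitro Adjusted in vitro `fold_change_matrix`.
#' @param descriptors Curated + normalized `descriptor_table`.
#' @param retained_genes Genes to model (see [filter_genes()]); must be
#'   present in both expression matrices.
#' @param alpha_grid,nlambda,cv_folds Hyperparameter grid, see
#'   [fit_gene_model()].
#' @param seed Bank seed; each gene's folds derive from `seed` plus the
#'   gene's index, so training is reproducible and parallelizable.
#' @param weight_rule Fold thresholds for [assign_weight()].
#' @param selection Hyperparameter selection rule, see [fit_gene_model()].
#' @param verbose Print a progress line per gene.
#' @return A `raid_bank`.
#' @export
train_bank <- function(invivo, invitro, descriptors, retained_genes,
                       alpha_grid = seq(0, 1, by = 0.1), nlambda = 100,
                       cv_folds = 5, seed = 1,
                       weight_rule = c("1.5" = 1.5, "2" = 4),
                       selection = c("cv_1se", "cv_min"),
                       verbose = FALSE) {
  selection <- match.arg(selection)
  subs <- substances(invivo)
  if (!identical(subs, substances(invitro)) ||
      !identical(subs, substances(descriptors))) {
    stop("substance order mismatch between in vivo, in vitro and ",
         "descriptor tables", call. = FALSE)
  }
  if (!all(retained_genes %in% genes(invivo)) ||
      !all(retained_genes %in% genes(invitro))) {
    stop("retained genes missing from expression matrices", call. = FALSE)
  }
  if (!descriptors$normalized) {
    stop("descriptor table must be curated and normalized before ",
         "training (see normalize_descriptors)", call. = FALSE)
  }
  ivt <- invitro$log2_values[, retained_genes, drop = FALSE]
  colnames(ivt) <- paste0("invitro:", retained_genes)
  x <- cbind(descriptors$values, ivt)
  invitro_features <- colnames(ivt)
  medians <- apply(ivt, 2, stats::median)
  names(medians) <- retained_genes
  models <- vector("list", length(retained_genes))
  names(models) <- retained_genes
  for (i in seq_along(retained_genes)) {
    g <- retained_genes[i]
    y <- invivo$log2_values[, g]
    w <- assign_weight(invivo$values[, g], weight_rule)
    models[[g]] <- fit_gene_model(
      x, y, weights = w, invitro_features = invitro_features,
      gene_id = g, alpha_grid = alpha_grid, nlambda = nlambda,
      cv_folds = cv_folds, seed = seed + i, selection = selection)
    if (verbose) {
      message(sprintf("[%d/%d] %s: alpha=%s lambda=%.4g cv_mse=%.4g",
                      i, length(retained_genes), g,
                      format(models[[g]]$alpha), models[[g]]$lambda,
                      models[[g]]$cv_mse))
    }
  }
  structure(list(models = models, training_gene_set = retained_genes,
                 invitro_feature_medians = medians,
                 descriptor_pipeline = descriptor_pipeline(descriptors),
                 random_seed = as.integer(seed)),
            class = "raid_bank")
}

#' @export
print.raid_bank <- function(x, ...) {
  cat("raid_bank: ", length(x$models), " gene models, ",
      length(x$descriptor_pipeline$kept), " descriptors, seed ",
      x$random_seed, "\n", sep = "")
  invisible(x)
}

#' Predict in vivo fold changes for new substances
#'
#' Raw descriptor values are pushed through the bank's stored curation +
#' normalization pipeline (tables already marked normalized are used
#' as-is). In vitro profiles are optional per substance and per gene:
#' any missing cell is imputed with the bank's training median for that
#' gene before the models are applied.
#'
#' @param object A trained `raid_bank`.
#' @param descriptors `descriptor_table` for the substances to predict;
#'   raw tables must contain every descriptor of the fitted pipeline.
#' @param invitro Optional in vitro `fold_change_matrix` (any subset of
#'   substances/genes).
#' @param ... Unused.
#' @return A `fold_change_matrix` with `source = "predicted"` holding
#'   the predicted in vivo fold changes for every bank gene (log2 and
#'   ratio views).
#' @export
predict.raid_bank <- function(object, descriptors, invitro = NULL, ...) {
  if (!descriptors$normalized) {
    descriptors <- apply_descriptor_pipeline(descriptors,
                                             object$descriptor_pipeline)
  } else {
    missing <- setdiff(object$descriptor_pipeline$kept,
                       colnames(descriptors$values))
    if (length(missing) > 0) {
      stop("normalized descriptor table lacks descriptor(s): ",
           paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
    }
  }
  subs <- rownames(descriptors$values)
  gene_set <- object$training_gene_set
  ivt <- matrix(rep(object$invitro_feature_medians[gene_set],
                    each = length(subs)),
                nrow = length(subs),
                dimnames = list(subs, paste0("invitro:", gene_set)))
  if (!is.null(invitro)) {
    common_s <- intersect(subs, substances(invitro))
    common_g <- intersect(gene_set, genes(invitro))
    vals <- invitro$log2_values[common_s, common_g, drop = FALSE]
    idx <- which(!is.na(vals), arr.ind = TRUE)
    ivt[cbind(match(common_s[idx[, 1]], subs),
              match(common_g[idx[, 2]], gene_set))] <- vals[idx]
  }
  x <- cbind(descriptors$values[, object$descriptor_pipeline$kept,
                                drop = FALSE], ivt)
  pred <- sapply(gene_set, function(g) predict(object$models[[g]], x))
  pred <- matrix(pred, nrow = length(subs),
                 dimnames = list(subs, gene_set))
  fold_change_matrix(2^pred, source = "predicted")
}

#' Rank bank genes by in vitro importance
#'
#' @param bank A trained `raid_bank`.
#' @param k Number of genes to return (default 20). If `k` exceeds the
#'   bank size all genes are returned with a warning.
#' @return Data frame `gene`, `importance`, sorted descending by
#'   importance with ties broken by gene id.
#' @export
top_importance_genes <- function(bank, k = 20) {
  imp <- vapply(bank$models, invitro_importance, numeric(1))
  df <- data.frame(gene = names(imp), importance = unname(imp),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$importance, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  if (k > nrow(df)) {
    warning("k = ", k, " exceeds bank size ", nrow(df),
            "; returning all genes")
    k <- nrow(df)
  }
  df[seq_len(k), , drop = FALSE]
}
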
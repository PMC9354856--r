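# Read-across analytics: PCA of expression / descriptor matrices,
# loading-length rankings, principal-component gene sets and their Venn
# partition, normalized-RMSE IVIVE evaluation, projection of external
# substances, biosimilar neighbors, and a minimal PLS-DA.

#' Principal component analysis with a fixed sign convention
#'
#' Column-centered, SVD-based PCA (expression matrices are not scaled;
#' descriptor matrices arrive pre-normalized). To make quadrant
#' assignments reproducible across linear-algebra backends, each loading
#' column is flipped so its largest-magnitude element is positive, with
#' scores flipped accordingly.
#'
#' @param x Numeric matrix, substances as rows, genes (or descriptors)
#'   as columns; or a `fold_change_matrix`, whose log2 view is used.
#' @param scale. Scale columns to unit variance (default `FALSE`).
#' @return A `raid_pca`: `scores`, `loadings`, `explained_variance`,
#'   `center`, `scaled`.
#' @export
fit_pca <- function(x, scale. = FALSE) {
  if (inherits(x, "fold_change_matrix")) x <- x$log2_values
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("PCA needs at least 3 substances", call. = FALSE)
  if (all(apply(x, 2, stats::sd) == 0)) {
    stop("constant matrix: PCA undefined", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(scores = scores, loadings = rot,
                 explained_variance = pc$sdev^2,
                 center = pc$center,
                 scale = if (scale.) pc$scale else NULL,
                 scaled = scale.),
            class = "raid_pca")
}

#' @export
print.raid_pca <- function(x, ...) {
  ev <- x$explained_variance / sum(x$explained_variance)
  cat("raid_pca: ", nrow(x$scores), " substances, ",
      ncol(x$loadings), " components (PC1 ",
      sprintf("%.1f%%", 100 * ev[1]), ", PC2 ",
      sprintf("%.1f%%", 100 * ev[2]), ")\n", sep = "")
  invisible(x)
}

#' Euclidean length of (PC1, PC2) loadings
#'
#' The ranking statistic for influential genes: the hypotenuse of the
#' first two loading coordinates.
#'
#' @param pca A `raid_pca`, or a loadings matrix with >= 2 columns.
#' @return Named nonnegative vector, one length per gene.
#' @export
loading_length <- function(pca) {
  l <- if (inherits(pca, "raid_pca")) pca$loadings else as.matrix(pca)
  stopifnot(ncol(l) >= 2)
  sqrt(l[, 1]^2 + l[, 2]^2)
}

#' Top genes of one loading-plane quadrant
#'
#' Quadrants follow the usual orientation: 1 = (+,+), 2 = (-,+),
#' 3 = (-,-), 4 = (+,-) in the (PC1, PC2) loading plane. Genes in the
#' quadrant are ranked by descending loading length, ties broken by gene
#' id, and truncated to `k`.
#'
#' @param pca A `raid_pca` fitted on expression data.
#' @param quadrant Integer 1-4.
#' @param k Maximum genes returned (default 30).
#' @return Data frame `gene`, `loading_PC1`, `loading_PC2`,
#'   `loading_length` with attribute `quadrant`.
#' @export
quadrant_top_genes <- function(pca, quadrant, k = 30) {
  stopifnot(quadrant %in% 1:4)
  l1 <- pca$loadings[, 1]; l2 <- pca$loadings[, 2]
  inq <- switch(quadrant,
                l1 > 0 & l2 > 0, l1 < 0 & l2 > 0,
                l1 < 0 & l2 < 0, l1 > 0 & l2 < 0)
  len <- loading_length(pca)
  g <- rownames(pca$loadings)[inq]
  g <- g[order(-len[inq], g)]
  g <- utils::head(g, k)
  out <- data.frame(gene = g, loading_PC1 = unname(l1[g]),
                    loading_PC2 = unname(l2[g]),
                    loading_length = unname(len[g]),
                    stringsAsFactors = FALSE)
  attr(out, "quadrant") <- quadrant
  out
}

#' Principal-component-related gene set
#'
#' The union of the top `k` and bottom `k` genes by signed loading on
#' PC1 and on PC2 (at most `4k` genes); the gene universe compared
#' across in vivo, predicted and in vitro data sources.
#'
#' @param pca A `raid_pca`.
#' @param k Genes taken from each extreme (default 30).
#' @return Character vector of gene ids (sorted).
#' @export
pc_related_gene_set <- function(pca, k = 30) {
  sets <- lapply(1:2, function(pc) {
    o <- order(pca$loadings[, pc])
    ids <- rownames(pca$loadings)
    c(utils::head(ids[o], k), utils::tail(ids[o], k))
  })
  sort(unique(unlist(sets)))
}

#' Partition named sets into exclusive Venn regions
#'
#' @param sets Named list of >= 2 character vectors (e.g. the
#'   PC-related gene sets of in vivo, predicted and in vitro data).
#' @return Named integer vector: one count per nonempty membership
#'   pattern, names like `"in_vivo&raid"`; counts sum to the size of the
#'   union.
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  all_patterns <- unlist(lapply(seq_along(sets), function(m) {
    utils::combn(names(sets), m, paste, collapse = "&")
  }))
  counts <- stats::setNames(integer(length(all_patterns)), all_patterns)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Normalized per-gene RMSE of predicted vs in vitro data against in vivo
#'
#' Each source's log2 fold-change matrix is z-normalized over all its
#' entries (source-wise mean 0, sd 1) to remove distributional
#' differences between data sources; then, per gene, the RMSE across
#' substances of (source - in vivo) is computed for the predicted and
#' the in vitro source. Welch's t-test compares the two per-gene RMSE
#' samples. `scope = "invitro_important"` restricts to genes whose model
#' actually uses in vitro features (importance > 0).
#'
#' @param pred Predicted `fold_change_matrix`.
#' @param invivo,invitro Observed matrices (shared substances/genes).
#' @param scope `"all"` or `"invitro_important"`.
#' @param bank Trained `raid_bank`; required for the importance scope.
#' @return An `rmse_comparison`: `per_gene_rmse_raid`,
#'   `per_gene_rmse_invitro`, `gene_scope`, `welch_t`, `welch_p`.
#' @export
qivive_rmse <- function(pred, invivo, invitro,
                        scope = c("all", "invitro_important"),
                        bank = NULL) {
  scope <- match.arg(scope)
  gns <- genes(invivo)
  stopifnot(identical(gns, genes(pred)), identical(gns, genes(invitro)),
            identical(substances(invivo), substances(pred)),
            identical(substances(invivo), substances(invitro)))
  if (scope == "invitro_important") {
    if (is.null(bank) || length(bank$models) == 0) {
      stop("scope 'invitro_important' needs a trained bank", call. = FALSE)
    }
    imp <- vapply(bank$models, invitro_importance, numeric(1))
    gns <- intersect(gns, names(imp)[imp > 0])
  }
  znorm <- function(m) {
    s <- stats::sd(m)
    if (s == 0) s <- 1  # degenerate constant source: center only
    (m - mean(m)) / s
  }
  zvivo <- znorm(invivo$log2_values)[, gns, drop = FALSE]
  zpred <- znorm(pred$log2_values)[, gns, drop = FALSE]
  zvitro <- znorm(invitro$log2_values)[, gns, drop = FALSE]
  rmse <- function(z) sqrt(colMeans((z - zvivo)^2))
  r_raid <- rmse(zpred)
  r_vitro <- rmse(zvitro)
  # identical or both-constant RMSE samples: no evidence of a difference
  wt <- tryCatch(stats::t.test(r_raid, r_vitro, var.equal = FALSE),
                 error = function(e) list(statistic = 0, p.value = 1))
  structure(list(per_gene_rmse_raid = r_raid,
                 per_gene_rmse_invitro = r_vitro,
                 gene_scope = scope,
                 welch_t = unname(wt$statistic),
                 welch_p = unname(wt$p.value)),
            class = "rmse_comparison")
}

#' @export
print.rmse_comparison <- function(x, ...) {
  cat("rmse_comparison [", x$gene_scope, "]: mean RMSE predicted = ",
      sprintf("%.4f", mean(x$per_gene_rmse_raid)), ", in vitro = ",
      sprintf("%.4f", mean(x$per_gene_rmse_invitro)),
      " (Welch p = ", format.pval(x$welch_p), ")\n", sep = "")
  invisible(x)
}

#' Project new substances into a fitted PCA space
#'
#' External substances are projected onto the training loadings (the
#' training geometry, and thus quadrant interpretation, is unchanged):
#' `scores = (x_new - training center) %*% loadings`.
#'
#' @param pca A `raid_pca`.
#' @param newx Matrix (or `fold_change_matrix`) with the same feature
#'   vocabulary as the training matrix.
#' @return Score matrix for the new substances.
#' @export
project_pca <- function(pca, newx) {
  if (inherits(newx, "fold_change_matrix")) newx <- newx$log2_values
  newx <- as.matrix(newx)
  missing <- setdiff(rownames(pca$loadings), colnames(newx))
  if (length(missing) > 0) {
    stop("new matrix lacks feature(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  newx <- newx[, rownames(pca$loadings), drop = FALSE]
  z <- sweep(newx, 2, pca$center)
  if (pca$scaled) z <- sweep(z, 2, pca$scale, `/`)
  z %*% pca$loadings
}

#' Nearest biosimilar substances in the (PC1, PC2) plane
#'
#' Ranks substances by Euclidean distance to the query in the first two
#' principal components — the biological-similarity screen used for
#' read-across. Training scores and any projected external scores are
#' pooled; the query is excluded from its own list.
#'
#' @param pca A `raid_pca`.
#' @param query Substance id present among the pooled scores.
#' @param k Number of neighbors (all if larger than the population).
#' @param external Optional score matrix from [project_pca()].
#' @return Data frame `substance`, `distance`, ascending distance with
#'   ties broken by substance id.
#' @export
biosimilar_neighbors <- function(pca, query, k = 5, external = NULL) {
  sc <- pca$scores[, 1:2, drop = FALSE]
  if (!is.null(external)) sc <- rbind(sc, external[, 1:2, drop = FALSE])
  if (!query %in% rownames(sc)) {
    stop("unknown query substance '", query, "'", call. = FALSE)
  }
  q <- sc[query, ]
  others <- sc[setdiff(rownames(sc), query), , drop = FALSE]
  d <- sqrt((others[, 1] - q[1])^2 + (others[, 2] - q[2])^2)
  o <- order(d, rownames(others))
  o <- utils::head(o, k)
  data.frame(substance = rownames(others)[o], distance = unname(d[o]),
             stringsAsFactors = FALSE)
}

#' Minimal two-component PLS-DA for the toxicity label
#'
#' NIPALS partial least squares on a centered 0/1 response (toxic = 1),
#' classifying by a 0.5 threshold on the predicted response. Substances
#' are split 70/30 with stratification by class; the model is fitted on
#' the 70% and accuracy reported on the held-out 30%.
#'
#' @param x Matrix (or `fold_change_matrix`) of features.
#' @param labels Named vector substance -> `toxic`/`non_toxic` covering
#'   the rows of `x`; both classes must be present.
#' @param n_components Number of PLS components (default 2).
#' @param split_seed Seed for the stratified split.
#' @return List: `scores` (training), `weights`, `accuracy` (held-out),
#'   `train_ids`, `test_ids`, `predicted` (held-out classes).
#' @export
plsda <- function(x, labels, n_components = 2, split_seed = 1) {
  if (inherits(x, "fold_change_matrix")) x <- x$log2_values
  x <- as.matrix(x)
  labels <- labels[rownames(x)]
  y01 <- as.numeric(labels == "toxic")
  if (length(unique(y01)) < 2) {
    stop("PLS-DA needs both toxicity classes", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(split_seed))
  train <- unlist(lapply(split(seq_len(nrow(x)), y01), function(idx) {
    sample(idx, max(1, round(0.7 * length(idx))))
  }))
  test <- setdiff(seq_len(nrow(x)), train)
  fit <- pls1_nipals(x[train, , drop = FALSE], y01[train], n_components)
  yhat <- pls1_predict(fit, x[test, , drop = FALSE])
  predicted <- ifelse(yhat >= 0.5, "toxic", "non_toxic")
  accuracy <- mean(predicted == labels[test])
  list(scores = fit$scores, weights = fit$W, accuracy = accuracy,
       train_ids = rownames(x)[train], test_ids = rownames(x)[test],
       predicted = stats::setNames(predicted, rownames(x)[test]))
}

# PLS1 by NIPALS deflation; first weight vector is proportional to X'y.
pls1_nipals <- function(x, y, ncomp) {
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  xm <- attr(xc, "scaled:center")
  E <- xc; f <- yc
  W <- P <- matrix(0, ncol(x), ncomp,
                   dimnames = list(colnames(x), NULL))
  Tm <- matrix(0, nrow(x), ncomp, dimnames = list(rownames(x), NULL))
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, 1:(a - 1), drop = FALSE]; break }
    w <- w / nw
    t_ <- drop(E %*% w)
    p <- drop(crossprod(E, t_)) / sum(t_^2)
    q[a] <- sum(t_ * f) / sum(t_^2)
    E <- E - tcrossprod(t_, p)
    f <- f - q[a] * t_
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t_
  }
  list(W = W, P = P, q = q, scores = Tm, x_center = xm, y_center = mean(y))
}

pls1_predict <- function(fit, newx) {
  # beta = W (P'W)^-1 q on centered data
  pw <- crossprod(fit$P, fit$W)
  beta <- fit$W %*% solve(pw, fit$q[seq_len(ncol(fit$W))])
  drop(sweep(as.matrix(newx)[, rownames(fit$W), drop = FALSE], 2,
             fit$x_center) %*% beta) + fit$y_center
}

#' Per-class 95% covariance-ellipse parameters in the score plane
#'
#' Emits, for each toxicity class, the mean and 2x2 covariance of the
#' (PC1, PC2) scores plus the ellipse axis lengths/angle at the 95%
#' chi-squared radius — the numeric content of a probability-ellipse
#' overlay.
#'
#' @param pca A `raid_pca`.
#' @param labels Named toxicity labels covering the scored substances.
#' @param level Coverage probability (default 0.95).
#' @return Named list per class: `center`, `cov`, `axes`, `angle_rad`.
#' @export
class_ellipses <- function(pca, labels, level = 0.95) {
  sc <- pca$scores[, 1:2, drop = FALSE]
  labels <- labels[rownames(sc)]
  r2 <- stats::qchisq(level, df = 2)
  lapply(split(as.data.frame(sc), labels), function(d) {
    m <- colMeans(d); S <- stats::cov(d)
    e <- eigen(S, symmetric = TRUE)
    list(center = m, cov = S,
         axes = sqrt(pmax(e$values, 0) * r2),
         angle_rad = atan2(e$vectors[2, 1], e$vectors[1, 1]))
  })
}
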
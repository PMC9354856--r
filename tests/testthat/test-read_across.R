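toy_expr <- function(n = 12, g = 6, seed = 21) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * g), n, g,
              dimnames = list(sprintf("s%02d", 1:n), paste0("g", 1:g)))
  x
}

test_that("PCA reproduces the eigendecomposition of the covariance", {
  x <- matrix(c(2, 4, 1, 6,
                0, 3, 2, 1,
                5, 1, 4, 2), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  pca <- fit_pca(x)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(unname(pca$explained_variance), ev, tolerance = 1e-8)
  # loadings orthonormal, scores self-consistent
  expect_equal(crossprod(pca$loadings), diag(ncol(x)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sweep(x, 2, pca$center) %*% pca$loadings,
               pca$scores, tolerance = 1e-8, ignore_attr = TRUE)
  # variance conservation
  expect_equal(sum(pca$explained_variance),
               sum(apply(x, 2, stats::var)), tolerance = 1e-8)
  # sign convention: dominant element of every loading positive
  for (j in 1:ncol(pca$loadings)) {
    v <- pca$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("collinear data load entirely on the first component", {
  t_ <- seq(-2, 2, length.out = 8)
  x <- cbind(g1 = 2 * t_, g2 = -t_, g3 = 0.5 * t_)
  rownames(x) <- paste0("s", 1:8)
  pca <- fit_pca(x)
  expect_equal(pca$explained_variance[1] / sum(pca$explained_variance), 1,
               tolerance = 1e-12)
  expect_error(fit_pca(matrix(1, 5, 3,
                              dimnames = list(paste0("s", 1:5),
                                              paste0("g", 1:3)))),
               "constant matrix")
})

test_that("loading lengths follow the Pythagorean formula", {
  l <- rbind(gA = c(0.3, 0.4), gB = c(0, 0), gC = c(-0.6, 0.8))
  expect_equal(unname(loading_length(l)), c(0.5, 0, 1.0))
})

test_that("quadrant rankings match a brute-force sort", {
  set.seed(22)
  pca <- fit_pca(toy_expr(n = 30, g = 15))
  l1 <- pca$loadings[, 1]; l2 <- pca$loadings[, 2]
  for (q in 1:4) {
    inq <- switch(q, l1 > 0 & l2 > 0, l1 < 0 & l2 > 0,
                  l1 < 0 & l2 < 0, l1 > 0 & l2 < 0)
    len <- sqrt(l1^2 + l2^2)
    brute <- names(sort(len[inq], decreasing = TRUE))
    got <- quadrant_top_genes(pca, q, k = 30)
    expect_identical(got$gene, brute)
    if (nrow(got) > 0) {
      expect_true(all(sign(got$loading_PC1) == c(1, -1, -1, 1)[q]))
      expect_true(all(sign(got$loading_PC2) == c(1, 1, -1, -1)[q]))
    }
    # truncation at k
    expect_lte(nrow(quadrant_top_genes(pca, q, k = 2)), 2)
  }
})

test_that("PC-related gene sets union the signed loading extremes", {
  pca <- fit_pca(toy_expr(n = 40, g = 25))
  # saturation: k beyond gene count returns everything
  expect_setequal(pc_related_gene_set(pca, k = 30),
                  rownames(pca$loadings))
  k <- 3
  brute <- unique(unlist(lapply(1:2, function(pc) {
    o <- order(pca$loadings[, pc])
    ids <- rownames(pca$loadings)
    c(head(ids[o], k), tail(ids[o], k))
  })))
  expect_setequal(pc_related_gene_set(pca, k = k), brute)
  expect_lte(length(pc_related_gene_set(pca, k = k)), 4 * k)
})

test_that("Venn partition counts equal exhaustive enumeration", {
  A <- paste0("g", 1:10); B <- paste0("g", 6:12); C <- paste0("g", c(1, 11:15))
  sets <- list(in_vivo = A, raid = B, in_vitro = C)
  counts <- venn_partition(sets)
  expect_equal(sum(counts), length(unique(c(A, B, C))))
  universe <- unique(c(A, B, C))
  brute <- table(sapply(universe, function(g) {
    paste(names(sets)[c(g %in% A, g %in% B, g %in% C)], collapse = "&")
  }))
  for (nm in names(brute)) {
    expect_equal(unname(counts[nm]), unname(as.integer(brute[nm])))
  }
  # identical sets collapse into the triple region
  same <- venn_partition(list(a = A, b = A, c = A))
  expect_equal(unname(same["a&b&c"]), length(A))
  expect_equal(sum(same), length(A))
  # disjoint sets populate only singleton regions
  disj <- venn_partition(list(a = paste0("x", 1:3), b = paste0("y", 1:4)))
  expect_equal(unname(disj[c("a", "b", "a&b")]), c(3L, 4L, 0L))
})

test_that("normalized RMSE comparison matches hand computation", {
  subs <- paste0("s", 1:4); gns <- paste0("g", 1:3)
  mk <- function(lv, source) {
    fold_change_matrix(2^matrix(lv, 4, 3, dimnames = list(subs, gns)),
                       source)
  }
  set.seed(23)
  vivo <- matrix(stats::rnorm(12), 4, 3)
  pred <- vivo + matrix(stats::rnorm(12, sd = 0.1), 4, 3)
  vitro <- vivo + matrix(stats::rnorm(12, sd = 1), 4, 3)
  r <- qivive_rmse(mk(pred, "predicted"), mk(vivo, "in_vivo"),
                   mk(vitro, "in_vitro"))
  z <- function(m) (m - mean(m)) / stats::sd(m)
  zv <- z(vivo); zp <- z(pred); zt <- z(vitro)
  expect_equal(unname(r$per_gene_rmse_raid),
               sqrt(colMeans((zp - zv)^2)), tolerance = 1e-12)
  expect_equal(unname(r$per_gene_rmse_invitro),
               sqrt(colMeans((zt - zv)^2)), tolerance = 1e-12)
  tt <- stats::t.test(sqrt(colMeans((zp - zv)^2)),
                      sqrt(colMeans((zt - zv)^2)), var.equal = FALSE)
  expect_equal(r$welch_p, tt$p.value, tolerance = 1e-12)
  # a perfect prediction has zero RMSE everywhere
  r0 <- qivive_rmse(mk(vivo, "predicted"), mk(vivo, "in_vivo"),
                    mk(vitro, "in_vitro"))
  expect_equal(unname(r0$per_gene_rmse_raid), rep(0, 3),
               tolerance = 1e-12)
  # identical comparisons give t = 0, p = 1
  req <- qivive_rmse(mk(vitro, "predicted"), mk(vivo, "in_vivo"),
                     mk(vitro, "in_vitro"))
  expect_equal(req$welch_t, 0)
  expect_equal(req$welch_p, 1)
  # invariance to gene relabeling
  perm <- c(3, 1, 2)
  sub_mk <- function(lv, source) {
    m <- matrix(lv, 4, 3, dimnames = list(subs, gns))[, perm]
    fold_change_matrix(2^m, source)
  }
  rp <- qivive_rmse(sub_mk(pred, "predicted"), sub_mk(vivo, "in_vivo"),
                    sub_mk(vitro, "in_vitro"))
  expect_equal(sort(unname(rp$per_gene_rmse_raid)),
               sort(unname(r$per_gene_rmse_raid)), tolerance = 1e-12)
  expect_equal(rp$welch_p, r$welch_p, tolerance = 1e-12)
  # the importance scope requires a trained bank
  expect_error(qivive_rmse(mk(pred, "predicted"), mk(vivo, "in_vivo"),
                           mk(vitro, "in_vitro"),
                           scope = "invitro_important"),
               "needs a trained bank")
})

test_that("projection extends a fitted PCA without moving training scores", {
  x <- toy_expr(n = 15, g = 5)
  pca <- fit_pca(x)
  # training data project onto their own scores
  expect_equal(project_pca(pca, x), pca$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  # the training mean maps to the origin
  mu <- matrix(pca$center, 1, dimnames = list("mean", names(pca$center)))
  expect_equal(unname(project_pca(pca, mu)[1, ]),
               rep(0, ncol(pca$scores)), tolerance = 1e-10)
  # hand-built two-feature check
  x2 <- cbind(g1 = c(0, 2, 4), g2 = c(1, 3, 5))
  rownames(x2) <- paste0("s", 1:3)
  p2 <- fit_pca(x2)
  new <- matrix(c(10, 20), 1, 2, dimnames = list("sN", c("g1", "g2")))
  expect_equal(project_pca(p2, new),
               (new - matrix(p2$center, 1)) %*% p2$loadings,
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(project_pca(pca, x[, 1:2]), "lacks feature")
})

test_that("biosimilar neighbors rank by score-plane distance", {
  sc <- rbind(q = c(0, 0), dup = c(0, 0), near = c(1, 0),
              far = c(3, 4), veryfar = c(10, 0))
  colnames(sc) <- c("PC1", "PC2")
  pca <- structure(list(scores = sc), class = "raid_pca")
  nb <- biosimilar_neighbors(pca, "q", k = 10)
  expect_identical(nb$substance, c("dup", "near", "far", "veryfar"))
  expect_equal(nb$distance, c(0, 1, 5, 10))
  expect_false("q" %in% nb$substance)
  expect_equal(nrow(biosimilar_neighbors(pca, "q", k = 2)), 2)
  expect_error(biosimilar_neighbors(pca, "nope"), "unknown query")
  # brute-force check on a random 5-point configuration
  set.seed(24)
  sc5 <- matrix(stats::rnorm(10), 5, 2,
                dimnames = list(paste0("s", 1:5), c("PC1", "PC2")))
  pca5 <- structure(list(scores = sc5), class = "raid_pca")
  d <- as.matrix(stats::dist(sc5))["s1", -1]
  expect_identical(biosimilar_neighbors(pca5, "s1", k = 4)$substance,
                   names(sort(d)))
  # externals pool with training scores
  ext <- matrix(c(0.1, 0), 1, 2, dimnames = list("sE", c("PC1", "PC2")))
  nb2 <- biosimilar_neighbors(pca5, "s1", k = 1, external = ext)
  expect_true(nb2$substance %in% c(names(sort(d))[1], "sE"))
})

test_that("PLS-DA separates separable classes and not permuted ones", {
  set.seed(25)
  n <- 60
  cls <- rep(c("toxic", "non_toxic"), each = n / 2)
  x <- matrix(stats::rnorm(n * 8), n, 8,
              dimnames = list(sprintf("s%02d", 1:n), paste0("g", 1:8)))
  x[cls == "toxic", 1:3] <- x[cls == "toxic", 1:3] + 4  # clean separation
  labels <- stats::setNames(cls, rownames(x))
  fit <- plsda(x, labels, split_seed = 5)
  expect_equal(fit$accuracy, 1.0)
  # permuted labels: accuracy near chance (binomial band for the split)
  set.seed(26)
  perm <- stats::setNames(sample(cls), rownames(x))
  fit_perm <- plsda(x, perm, split_seed = 5)
  n_test <- length(fit_perm$test_ids)
  band <- 1.96 * sqrt(0.25 / n_test)
  expect_gte(fit_perm$accuracy, 0.5 - band - 0.15)
  expect_lte(fit_perm$accuracy, 0.5 + band + 0.15)
  expect_error(plsda(x, stats::setNames(rep("toxic", n), rownames(x))),
               "both toxicity classes")
})

test_that("the first PLS weight vector is proportional to X'y", {
  x <- cbind(g1 = c(1, 2, 3, 4), g2 = c(2, 1, 4, 3))
  rownames(x) <- paste0("s", 1:4)
  y <- c(0, 0, 1, 1)
  fit <- raidr:::pls1_nipals(scale(x, scale = FALSE), y - mean(y), 1)
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  w_hand <- drop(crossprod(xc, yc)); w_hand <- w_hand / sqrt(sum(w_hand^2))
  expect_equal(unname(fit$W[, 1]), unname(w_hand), tolerance = 1e-12)
})

test_that("class ellipses summarize per-class score geometry", {
  set.seed(27)
  sc <- matrix(stats::rnorm(40), 20, 2,
               dimnames = list(sprintf("s%02d", 1:20), c("PC1", "PC2")))
  pca <- structure(list(scores = sc), class = "raid_pca")
  labels <- stats::setNames(rep(c("toxic", "non_toxic"), 10),
                            rownames(sc))
  ell <- class_ellipses(pca, labels)
  expect_setequal(names(ell), c("toxic", "non_toxic"))
  tox <- sc[labels == "toxic", ]
  expect_equal(unname(ell$toxic$center), unname(colMeans(tox)),
               tolerance = 1e-10)
  expect_equal(ell$toxic$cov, stats::cov(as.data.frame(tox)),
               tolerance = 1e-10, ignore_attr = TRUE)
})
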
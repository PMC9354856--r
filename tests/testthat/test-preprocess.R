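ctx_vivo <- adjustment_context("in_vivo")
ctx_vitro <- adjustment_context("in_vitro")

test_that("fold change is the ratio of group means with Welch p-values", {
  df <- make_replicate_df("sA", "g1", nrep = 3)
  df$signal <- ifelse(df$group == "treated", 4, 2)
  fc <- compute_fold_change(replicate_table(df, "in_vivo"))
  expect_equal(unname(fc$values["sA", "g1"]), 2)

  df$signal <- 3  # identical groups
  fc <- compute_fold_change(replicate_table(df, "in_vivo"))
  expect_equal(unname(fc$values["sA", "g1"]), 1)
  expect_true(is.na(fc$pvalues["sA", "g1"]))  # degenerate Welch test

  df$signal <- ifelse(df$group == "treated", c(3.1, 2.9, 3.0),
                      c(1.1, 0.9, 1.0))
  fc <- compute_fold_change(replicate_table(df, "in_vivo"))
  expect_equal(unname(fc$values["sA", "g1"]), 3)
  expect_equal(unname(fc$pvalues["sA", "g1"]),
               welch_oracle_p(c(3.1, 2.9, 3.0), c(1.1, 0.9, 1.0)),
               tolerance = 1e-12)
})

test_that("flag summaries count treated Absent calls per cell", {
  df <- make_replicate_df("sA", "g1", nrep = 3)
  df$call[df$group == "treated"] <- c("A", "A", "P")
  fc <- compute_fold_change(replicate_table(df, "in_vivo"))
  expect_equal(unname(fc$flagA["sA", "g1"]), 2)
  expect_false(fc$all_absent["sA", "g1"])
  df$call <- "A"
  fc <- compute_fold_change(replicate_table(df, "in_vivo"))
  expect_true(fc$all_absent["sA", "g1"])
})

test_that("adjustment applies exactly one rule, strongest first", {
  # half rule: flags at threshold, significant p
  expect_equal(adjust_fold_change(1.5, 2, FALSE, 0.02, ctx_vivo), 1.25)
  # half rule via the p band
  expect_equal(adjust_fold_change(1.5, 0, FALSE, 0.07, ctx_vivo), 1.25)
  # quarter rule
  expect_equal(adjust_fold_change(1.4, 0, FALSE, 0.2, ctx_vivo), 1.1)
  # quarter beats half when both fire
  expect_equal(adjust_fold_change(1.4, 3, FALSE, 0.2, ctx_vivo), 1.1)
  # all-Absent beats everything
  expect_equal(adjust_fold_change(2.0, 3, TRUE, 0.001, ctx_vivo), 1.0)
  # clean cell untouched
  expect_equal(adjust_fold_change(3.0, 0, FALSE, 0.01, ctx_vivo), 3.0)
  # down-regulation shrinks in reciprocal space
  expect_equal(adjust_fold_change(0.5, 0, FALSE, 0.2, ctx_vivo),
               1 / (1 + (2 - 1) / 4))
  # NA p-value never triggers a p rule
  expect_equal(adjust_fold_change(1.4, 0, FALSE, NA, ctx_vivo), 1.4)
  # in vitro threshold is 1 Absent call of 2
  expect_equal(adjust_fold_change(1.5, 1, FALSE, 0.01, ctx_vitro), 1.25)
  expect_equal(adjust_fold_change(1.5, 1, FALSE, 0.01, ctx_vivo), 1.5)
  expect_error(adjust_fold_change(-1, 0, FALSE, 0.5, ctx_vivo),
               "finite and > 0")
})

test_that("adjustment is a contraction toward 1 and monotone", {
  set.seed(1)
  F <- c(exp(stats::runif(5000, -3, 3)), seq(0.1, 10, length.out = 5000))
  for (case in list(list(flag = 3, p = 0.02), list(flag = 0, p = 0.07),
                    list(flag = 0, p = 0.5), list(flag = 0, p = 0.01))) {
    Fp <- adjust_fold_change(F, case$flag, FALSE, case$p, ctx_vivo)
    expect_true(all(abs(log2(Fp)) <= abs(log2(F)) + 1e-12))
    # on the same side of 1
    expect_true(all(sign(log2(Fp)) == sign(log2(F)) |
                      abs(log2(F)) < 1e-12))
    # monotone in F for up-regulated values under a fixed rule
    up <- sort(F[F >= 1])
    up_adj <- adjust_fold_change(up, case$flag, FALSE, case$p, ctx_vivo)
    expect_true(all(diff(up_adj) >= -1e-12))
  }
  # equality with the raw value only for the unchanged rule
  Fp <- adjust_fold_change(F, 0, FALSE, 0.01, ctx_vivo)
  expect_equal(Fp, F)
})

test_that("the all-Absent rule needs both sources Absent when paired", {
  v <- matrix(2, 1, 1, dimnames = list("sA", "g1"))
  mk <- function(absent, source) {
    fold_change_matrix(v, source,
                       pvalues = matrix(0.01, 1, 1),
                       flagA = matrix(0L, 1, 1),
                       all_absent = matrix(absent, 1, 1))
  }
  adj <- apply_adjustment(mk(TRUE, "in_vivo"), mk(FALSE, "in_vitro"))
  expect_equal(unname(adj$invivo$values[1, 1]), 2)  # only one source Absent
  adj <- apply_adjustment(mk(TRUE, "in_vivo"), mk(TRUE, "in_vitro"))
  expect_equal(unname(adj$invivo$values[1, 1]), 1)
  expect_equal(unname(adj$invitro$values[1, 1]), 1)
})

test_that("sample weights follow the fold-change magnitude thresholds", {
  expect_equal(assign_weight(4.0), 2)
  expect_equal(assign_weight(1.5), 1.5)
  expect_equal(assign_weight(1.0), 1)
  expect_equal(assign_weight(0.2), 2)  # magnitude 5
  # symmetry under F <-> 1/F on a grid
  F <- exp(stats::runif(2000, -3, 3))
  expect_equal(assign_weight(F), assign_weight(1 / F))
})

test_that("gene filter keeps genes with enough responding substances", {
  set.seed(3)
  n <- 20
  counts <- c(5, 9, 10, 15)
  v <- sapply(counts, function(k) {
    f <- rep(1, n)
    f[seq_len(k)] <- 2  # k substances beyond the 1.5-fold threshold
    f
  })
  dimnames(v) <- list(sprintf("s%02d", 1:n), paste0("g", 1:4))
  fc <- fold_change_matrix(v, "in_vivo")
  expect_identical(filter_genes(fc, min_substances = 10), c("g3", "g4"))
  # all-flat gene is always removed; boundary count retained
  expect_identical(filter_genes(fc, min_substances = 16), character(0))
  # down-regulation counts via magnitude
  v[, 1] <- 1; v[1:12, 1] <- 0.5
  fc <- fold_change_matrix(v, "in_vivo")
  expect_true("g1" %in% filter_genes(fc, min_substances = 10))
})

test_that("descriptor curation drops missing, constant and correlated", {
  set.seed(5)
  n <- 40
  base <- stats::rnorm(n)
  x <- cbind(a = base,
             b = stats::rnorm(n),
             dup_a = base,                                    # r = 1
             c = stats::rnorm(n),
             const = rep(2, n),
             holey = c(NA, stats::rnorm(n - 1)))
  rownames(x) <- sprintf("s%02d", 1:n)
  cur <- curate_descriptors(descriptor_table(x))
  expect_identical(colnames(cur$values), c("a", "b", "c"))
  log <- cur$curation_log
  expect_identical(log$drop_reason[log$descriptor == "holey"], "missing")
  expect_identical(log$drop_reason[log$descriptor == "const"], "constant")
  expect_identical(log$drop_reason[log$descriptor == "dup_a"],
                   "pair_correlation")
  # idempotent
  again <- curate_descriptors(cur)
  expect_identical(colnames(again$values), colnames(cur$values))
  expect_identical(nrow(again$curation_log), nrow(cur$curation_log))
  expect_error(curate_descriptors(descriptor_table(x[1:2, ])),
               "at least 3 substances")
})

test_that("correlation pruning uses the 0.95 bound, left to right", {
  set.seed(6)
  n <- 200
  a <- stats::rnorm(n)
  high <- 0.99 * a + sqrt(1 - 0.99^2) * stats::rnorm(n)  # r ~ 0.99
  mid <- 0.90 * a + sqrt(1 - 0.90^2) * stats::rnorm(n)   # r ~ 0.90
  x <- cbind(a = a, high = high, mid = mid,
             d = stats::rnorm(n), e = stats::rnorm(n))
  rownames(x) <- sprintf("s%03d", 1:n)
  stopifnot(abs(cor(a, high)) > 0.95, abs(cor(a, mid)) < 0.95)
  cur <- curate_descriptors(descriptor_table(x))
  expect_identical(cur$curation_log$descriptor, "high")
  expect_identical(cur$curation_log$drop_reason, "pair_correlation")
  expect_identical(colnames(cur$values), c("a", "mid", "d", "e"))
})

test_that("normalizing transforms are selected per column and reusable", {
  set.seed(8)
  n <- 120
  x <- cbind(gauss = stats::rnorm(n),
             lognorm = exp(stats::rnorm(n)),
             twoval = rep(c(0, 1), n / 2))
  rownames(x) <- sprintf("s%03d", 1:n)
  norm <- normalize_descriptors(curate_descriptors(descriptor_table(x)))
  # every output column standardized
  expect_equal(unname(colMeans(norm$values)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(norm$values, 2, sd)), rep(1, 3),
               tolerance = 1e-8)
  # a normal column keeps a (near-)linear transform
  expect_true(norm$transform_log$gauss$transform %in%
                c("identity", "yeo_johnson"))
  # a lognormal column picks a log-family transform, beating identity on
  # an independently computed Pearson normality statistic
  chosen <- norm$transform_log$lognorm$transform
  expect_true(chosen %in% c("log10", "box_cox", "yeo_johnson"))
  nc <- ceiling(2 * n^(2 / 5))
  stat <- function(z) {
    unname(nortest::pearson.test(scale(z), n.classes = nc)$statistic)
  }
  expect_lt(stat(log10(x[, "lognorm"])), stat(x[, "lognorm"]))
  # stored pipeline reproduces the training output exactly
  pipe <- descriptor_pipeline(norm)
  replay <- apply_descriptor_pipeline(descriptor_table(x), pipe)
  expect_equal(replay$values, norm$values, tolerance = 1e-12)
})

test_that("arcsine and sqrt candidates engage only on legal domains", {
  set.seed(9)
  n <- 80
  x <- cbind(frac = stats::rbeta(n, 0.4, 0.4),   # in [0,1], U-shaped
             counts = stats::rpois(n, 3))        # nonnegative
  rownames(x) <- sprintf("s%03d", 1:n)
  norm <- normalize_descriptors(curate_descriptors(descriptor_table(x)))
  expect_equal(unname(colMeans(norm$values)), c(0, 0), tolerance = 1e-8)
  # negative values exclude box_cox/log10/sqrt/arcsine entirely
  x2 <- cbind(signed = stats::rnorm(n, 0, 2))
  rownames(x2) <- sprintf("s%03d", 1:n)
  norm2 <- normalize_descriptors(curate_descriptors(descriptor_table(x2)))
  expect_true(norm2$transform_log$signed$transform %in%
                c("identity", "yeo_johnson"))
})
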
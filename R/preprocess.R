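# Feature engineering: replicate signals -> reliability-adjusted fold
# changes, sample weights, gene filtering, and descriptor curation /
# normalizing-transform selection.

#' Reliability-adjustment context for a data source
#'
#' Bundles the thresholds of the fold-change shrinkage rules. The Absent
#' (flag A) count threshold is 2-of-3 for in vivo data and 1-of-2 for in
#' vitro data; p-values between 0.05 and 0.1 trigger the half-increment
#' rule and p-values above 0.1 the quarter-increment rule.
#'
#' @param source `"in_vivo"` or `"in_vitro"`.
#' @param flagA_threshold Treated-group Absent-call count at or above
#'   which the half rule fires; defaults 2 (in vivo) / 1 (in vitro).
#' @param p_half_band Closed p-value interval for the half rule.
#' @param p_quarter_threshold p-values strictly above this trigger the
#'   quarter rule.
#' @return An `adjustment_context` list.
#' @export
adjustment_context <- function(source,
                               flagA_threshold = NULL,
                               p_half_band = c(0.05, 0.1),
                               p_quarter_threshold = 0.1) {
  source <- match.arg(source, c("in_vivo", "in_vitro"))
  if (is.null(flagA_threshold)) {
    flagA_threshold <- if (source == "in_vivo") 2L else 1L
  }
  stopifnot(flagA_threshold >= 1, p_half_band[1] < p_half_band[2])
  structure(list(source = source, flagA_threshold = flagA_threshold,
                 p_half_band = p_half_band,
                 p_quarter_threshold = p_quarter_threshold,
                 shrink_half = 0.5, shrink_quarter = 0.25),
            class = "adjustment_context")
}

#' Fold changes, Welch p-values and flag summaries from replicate signals
#'
#' For every (substance, gene) cell the fold change is the treated-group
#' mean signal divided by the control-group mean signal. A per-cell
#' p-value comes from an unequal-variance (Welch) two-sample t-test on the
#' base-2 log signals; when both groups are exactly constant the test is
#' undefined and the p-value is `NA`. The flag summary counts Absent calls
#' among treated replicates; `all_absent` records cells whose calls are
#' Absent in every replicate of both groups (within this source).
#'
#' @param table A `replicate_table`.
#' @return A `fold_change_matrix` with `pvalues`, `flagA` and
#'   `all_absent` populated.
#' @export
compute_fold_change <- function(table) {
  stopifnot(inherits(table, "replicate_table"))
  subs <- unique(table$substance)
  gns <- unique(table$gene)
  dims <- list(subs, gns)
  fc <- matrix(NA_real_, length(subs), length(gns), dimnames = dims)
  pv <- matrix(NA_real_, length(subs), length(gns), dimnames = dims)
  fa <- matrix(NA_integer_, length(subs), length(gns), dimnames = dims)
  aa <- matrix(NA, length(subs), length(gns), dimnames = dims)
  key <- interaction(table$substance, table$gene, drop = TRUE, sep = "\r")
  for (cell in split(seq_len(nrow(table)), key)) {
    rows <- table[cell, ]
    s <- rows$substance[1]; g <- rows$gene[1]
    tr <- rows[rows$group == "treated", ]
    ct <- rows[rows$group == "control", ]
    mc <- mean(ct$signal)
    if (!is.finite(mc) || mc <= 0) {
      stop("non-positive control mean for substance '", s, "', gene '", g,
           "'", call. = FALSE)
    }
    fc[s, g] <- mean(tr$signal) / mc
    pv[s, g] <- welch_p_log2(tr$signal, ct$signal)
    fa[s, g] <- sum(tr$call == "A")
    aa[s, g] <- all(rows$call == "A")
  }
  fold_change_matrix(fc, source = attr(table, "source"),
                     pvalues = pv, flagA = fa, all_absent = aa)
}

# Welch t-test on log2 signals; NA when degenerate (zero variance in both
# groups or < 2 observations per group).
welch_p_log2 <- function(treated, control) {
  x <- log2(treated); y <- log2(control)
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::var(x) == 0 && stats::var(y) == 0) return(NA_real_)
  tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
           error = function(e) NA_real_)
}

#' Shrink a low-reliability fold change toward 1
#'
#' Applies exactly one adjustment rule, the most severe that fires:
#' \enumerate{
#'   \item all detection calls Absent -> fold change set to 1 (no
#'     differentiation);
#'   \item p-value above 0.1 -> the increment above (or below) 1 is
#'     shrunk to one fourth (e.g. 1.4 becomes 1.1);
#'   \item treated-group Absent count at/above the source threshold, or
#'     p-value in \[0.05, 0.1\] -> increment halved (e.g. 1.5 becomes
#'     1.25);
#'   \item otherwise unchanged.
#' }
#' Up-regulation shrinks as `1 + (F - 1) * k`; down-regulation shrinks in
#' reciprocal space, `1 / (1 + (1/F - 1) * k)`, so the rule is symmetric
#' in the sign of the log2 fold change. An `NA` p-value never triggers a
#' p-based rule.
#'
#' @param F Ratio-scale fold change(s), > 0. Vectorized.
#' @param flagA_count Absent calls among treated replicates (recycled).
#' @param all_absent Logical: every call Absent (see
#'   [apply_adjustment()] for the cross-source policy).
#' @param p Per-cell p-value or `NA`.
#' @param ctx An [adjustment_context()].
#' @return Adjusted fold change(s), always between 1 and `F` inclusive.
#' @export
adjust_fold_change <- function(F, flagA_count, all_absent, p, ctx) {
  if (any(!is.finite(F) | F <= 0)) {
    stop("fold change must be finite and > 0", call. = FALSE)
  }
  n <- length(F)
  flagA_count <- rep_len(flagA_count, n)
  all_absent <- rep_len(all_absent, n)
  p <- rep_len(p, n)
  k <- rep_len(1, n)
  half <- (flagA_count >= ctx$flagA_threshold) |
    (!is.na(p) & p >= ctx$p_half_band[1] & p <= ctx$p_half_band[2])
  quarter <- !is.na(p) & p > ctx$p_quarter_threshold
  k[half] <- ctx$shrink_half
  k[quarter] <- ctx$shrink_quarter  # quarter overrides half
  out <- F  # untouched cells keep their value bit-exactly
  i <- which(k < 1)
  out[i] <- ifelse(F[i] >= 1, 1 + (F[i] - 1) * k[i],
                   1 / (1 + (1 / F[i] - 1) * k[i]))
  out[all_absent] <- 1
  out
}

#' Apply the adjustment rules to paired fold-change matrices
#'
#' The set-to-1 rule requires all calls Absent in both the in vivo and in
#' vitro data for the same substance/gene cell (`require_both = TRUE`,
#' the default); each matrix's own flag counts and p-values drive the
#' half/quarter rules.
#'
#' @param invivo,invitro `fold_change_matrix` objects carrying `pvalues`,
#'   `flagA` and `all_absent` (as produced by [compute_fold_change()]).
#'   `invitro` may be `NULL`, in which case the all-Absent rule uses the
#'   single source.
#' @param require_both All-Absent rule needs both sources Absent.
#' @return List with adjusted `invivo` and `invitro` matrices.
#' @export
apply_adjustment <- function(invivo, invitro = NULL, require_both = TRUE) {
  adj_one <- function(fc, joint_absent) {
    ctx <- adjustment_context(fc$source)
    vals <- adjust_fold_change(as.vector(fc$values),
                               as.vector(fc$flagA),
                               as.vector(joint_absent),
                               as.vector(fc$pvalues), ctx)
    out <- fold_change_matrix(
      matrix(vals, nrow(fc$values), dimnames = dimnames(fc$values)),
      source = fc$source, pvalues = fc$pvalues, flagA = fc$flagA,
      all_absent = fc$all_absent)
    out
  }
  if (is.null(invitro)) {
    return(list(invivo = adj_one(invivo, invivo$all_absent),
                invitro = NULL))
  }
  if (!identical(rownames(invivo$values), rownames(invitro$values)) ||
      !identical(colnames(invivo$values), colnames(invitro$values))) {
    stop("in vivo and in vitro matrices must share substance and gene ",
         "order", call. = FALSE)
  }
  joint <- if (require_both) invivo$all_absent & invitro$all_absent
           else NULL
  list(invivo = adj_one(invivo, joint %||% invivo$all_absent),
       invitro = adj_one(invitro, joint %||% invitro$all_absent))
}

#' Training-sample weights from fold-change magnitude
#'
#' Samples showing at least a 1.5-fold change receive weight 1.5 and at
#' least a 4-fold change weight 2; all others weight 1. Magnitude is
#' symmetric in direction: `max(F, 1/F)`.
#'
#' @param F Ratio-scale fold change(s), > 0. Vectorized.
#' @param thresholds Named numeric vector `c(weight = fold_threshold)`
#'   pairs; default `c("1.5" = 1.5, "2" = 4)`.
#' @return Numeric weight(s) in \{1, 1.5, 2\}.
#' @export
assign_weight <- function(F, thresholds = c("1.5" = 1.5, "2" = 4)) {
  if (any(!is.finite(F) | F <= 0)) {
    stop("fold change must be finite and > 0", call. = FALSE)
  }
  m <- pmax(F, 1 / F)
  w <- rep_len(1, length(F))
  names(w) <- names(F)
  for (i in order(thresholds)) {
    w[m >= thresholds[i]] <- as.numeric(names(thresholds)[i])
  }
  w
}

#' Filter genes by differential-expression prevalence
#'
#' A gene is retained iff at least `min_substances` substances show a
#' fold-change magnitude (`max(F, 1/F)`) of `fold_threshold` or more;
#' genes differentially expressed in fewer substances are removed as too
#' rare to model.
#'
#' @param fc An (adjusted) in vivo `fold_change_matrix`.
#' @param min_substances Minimum substance count (default 10).
#' @param fold_threshold Fold-change magnitude cutoff (default 1.5).
#' @return Character vector of retained gene ids, in input order.
#' @export
filter_genes <- function(fc, min_substances = 10, fold_threshold = 1.5) {
  m <- pmax(fc$values, 1 / fc$values)
  counts <- colSums(m >= fold_threshold)
  genes(fc)[counts >= min_substances]
}

#' Curate a raw descriptor table
#'
#' Drops, in order: (1) descriptors with any missing value; (2) constant
#' descriptors; (3) the later member of any descriptor pair whose
#' absolute Pearson correlation exceeds `corr_threshold`, scanning
#' left-to-right and testing each column against all already-retained
#' columns. Every drop is recorded in the curation log. The operation is
#' idempotent.
#'
#' @param table A `descriptor_table` (raw, may contain `NA`).
#' @param corr_threshold Absolute-correlation cutoff (default 0.95).
#' @return Curated `descriptor_table` with an updated `curation_log`.
#' @export
curate_descriptors <- function(table, corr_threshold = 0.95) {
  x <- table$values
  if (nrow(x) < 3) {
    stop("descriptor curation needs at least 3 substances", call. = FALSE)
  }
  log <- table$curation_log
  note <- function(desc, why) {
    rbind(log, data.frame(descriptor = desc, drop_reason = why,
                          stringsAsFactors = FALSE))
  }
  has_na <- colnames(x)[colSums(is.na(x)) > 0]
  for (d in has_na) log <- note(d, "missing")
  x <- x[, setdiff(colnames(x), has_na), drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  const <- colnames(x)[sds == 0]
  for (d in const) log <- note(d, "constant")
  x <- x[, setdiff(colnames(x), const), drop = FALSE]
  kept <- character(0)
  for (d in colnames(x)) {
    if (length(kept) > 0) {
      r <- suppressWarnings(
        abs(stats::cor(x[, d], x[, kept, drop = FALSE])))
      if (any(r > corr_threshold, na.rm = TRUE)) {
        log <- note(d, "pair_correlation")
        next
      }
    }
    kept <- c(kept, d)
  }
  descriptor_table(x[, kept, drop = FALSE], curation_log = log,
                   transform_log = table$transform_log,
                   normalized = table$normalized)
}

# ---- normalizing transforms ----------------------------------------------

yj_transform <- function(x, lambda) {
  pos <- x >= 0
  out <- numeric(length(x))
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log(x[pos] + 1)
  }
  if (abs(lambda - 2) > 1e-10) {
    out[!pos] <- -((-x[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log(-x[!pos] + 1)
  }
  out
}

yj_loglik <- function(x, lambda) {
  z <- yj_transform(x, lambda)
  n <- length(x)
  s2 <- stats::var(z) * (n - 1) / n
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

bc_transform <- function(x, lambda) {
  if (abs(lambda) > 1e-10) (x^lambda - 1) / lambda else log(x)
}

bc_loglik <- function(x, lambda) {
  z <- bc_transform(x, lambda)
  n <- length(x)
  s2 <- stats::var(z) * (n - 1) / n
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

fit_transform <- function(x, transform) {
  lambda <- NULL
  z <- switch(transform,
    identity = x,
    yeo_johnson = {
      opt <- stats::optimize(function(l) yj_loglik(x, l), c(-5, 5),
                             maximum = TRUE)
      lambda <- opt$maximum
      yj_transform(x, lambda)
    },
    box_cox = {
      if (any(x <= 0)) return(NULL)
      opt <- stats::optimize(function(l) bc_loglik(x, l), c(-5, 5),
                             maximum = TRUE)
      lambda <- opt$maximum
      bc_transform(x, lambda)
    },
    log10 = if (any(x <= 0)) return(NULL) else log10(x),
    sqrt = if (any(x < 0)) return(NULL) else sqrt(x),
    arcsine = if (any(x < 0 | x > 1)) return(NULL) else asin(sqrt(x))
  )
  if (is.null(z) || stats::sd(z) == 0) return(NULL)
  list(transform = transform, lambda = lambda,
       center = mean(z), scale = stats::sd(z), z = z)
}

apply_transform <- function(x, tr) {
  z <- switch(tr$transform,
    identity = x,
    yeo_johnson = yj_transform(x, tr$lambda),
    box_cox = bc_transform(x, tr$lambda),
    log10 = log10(x),
    sqrt = sqrt(x),
    arcsine = asin(sqrt(pmin(pmax(x, 0), 1)))
  )
  (z - tr$center) / tr$scale
}

# Pearson chi-squared normality statistic (lower = closer to normal),
# binning ceiling(2 * n^(2/5)), divided by its degrees of freedom
# classes - 1 - (estimated parameters): 2 for standardization plus 1 for
# a fitted transform parameter (Yeo-Johnson / Box-Cox lambda), so
# parameterized transforms are charged for their extra flexibility.
normality_stat <- function(z, n_params = 0) {
  n.classes <- ceiling(2 * length(z)^(2 / 5))
  p <- tryCatch(nortest::pearson.test(z, n.classes = n.classes),
                error = function(e) NULL)
  if (is.null(p)) return(Inf)
  unname(p$statistic) / max(n.classes - 3 - n_params, 1)
}

#' Select and apply the best normalizing transform per descriptor
#'
#' For each descriptor column every applicable candidate transform is
#' fitted: Yeo-Johnson (always), Box-Cox and log10 (strictly positive
#' columns), square root (nonnegative), arcsine (values in \[0,1\]) and
#' identity. The candidate minimizing a Pearson chi-squared
#' goodness-of-fit statistic of the standardized transformed values
#' against the standard normal is chosen, and the column is centered and
#' scaled to mean 0, sd 1. The fitted pipeline (choice, parameters,
#' center, scale) is stored so new substances can be pushed through it
#' unchanged via [apply_descriptor_pipeline()].
#'
#' @param table A curated `descriptor_table`.
#' @return Normalized `descriptor_table` with `transform_log` populated.
#' @export
normalize_descriptors <- function(table) {
  x <- table$values
  candidates <- c("yeo_johnson", "box_cox", "log10", "sqrt", "arcsine",
                  "identity")
  transforms <- list()
  out <- x
  for (d in colnames(x)) {
    fits <- Filter(Negate(is.null),
                   lapply(candidates, function(tr) fit_transform(x[, d], tr)))
    stats_ <- vapply(fits, function(f) {
      normality_stat((f$z - f$center) / f$scale,
                     n_params = as.integer(!is.null(f$lambda)))
    }, numeric(1))
    best <- fits[[which.min(stats_)]]
    transforms[[d]] <- best[c("transform", "lambda", "center", "scale")]
    out[, d] <- (best$z - best$center) / best$scale
  }
  descriptor_table(out, curation_log = table$curation_log,
                   transform_log = transforms, normalized = TRUE)
}

#' Reapply a fitted descriptor pipeline to new substances
#'
#' @param table Raw `descriptor_table` for new substances; must contain
#'   every descriptor the pipeline retained.
#' @param pipeline List with `kept`, `curation_log` and `transforms`, as
#'   stored in a trained bank.
#' @return Normalized `descriptor_table` restricted to the pipeline's
#'   retained descriptors, in pipeline order.
#' @export
apply_descriptor_pipeline <- function(table, pipeline) {
  x <- table$values
  missing <- setdiff(pipeline$kept, colnames(x))
  if (length(missing) > 0) {
    stop("descriptor table lacks descriptor(s) required by the fitted ",
         "pipeline: ", paste(utils::head(missing, 10), collapse = ", "),
         call. = FALSE)
  }
  out <- sapply(pipeline$kept, function(d) {
    apply_transform(x[, d], pipeline$transforms[[d]])
  })
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), pipeline$kept))
  descriptor_table(out, curation_log = pipeline$curation_log,
                   transform_log = pipeline$transforms, normalized = TRUE)
}

#' Extract the reusable pipeline from a normalized descriptor table
#' @param table A curated, normalized `descriptor_table`.
#' @return Pipeline list (`kept`, `curation_log`, `transforms`).
#' @export
descriptor_pipeline <- function(table) {
  stopifnot(table$normalized)
  list(kept = colnames(table$values), curation_log = table$curation_log,
       transforms = table$transform_log)
}
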
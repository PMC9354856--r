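# Shared fixtures. Heavy objects (trained banks) are computed lazily and
# memoized so several test files can reuse them.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# default-condition synthetic study and its preprocessed artifacts
default_study <- function() memo("study", generate_study(sim_config()))

default_prep <- function() memo("prep", {
  study <- default_study()
  adj <- apply_adjustment(compute_fold_change(study$invivo),
                          compute_fold_change(study$invitro))
  desc <- normalize_descriptors(curate_descriptors(study$descriptors))
  list(invivo = adj$invivo, invitro = adj$invitro, descriptors = desc,
       retained = filter_genes(adj$invivo))
})

default_bank <- function() memo("bank", {
  p <- default_prep()
  train_bank(p$invivo, p$invitro, p$descriptors, p$retained, seed = 7)
})

# tiny quick bank over a small study, for serialization/prediction tests
small_study <- function() {
  memo("small_study",
       generate_study(sim_config(n_substances = 30, n_genes = 6,
                                 n_descriptors = 8,
                                 n_invitro_driven_genes = 2,
                                 correlated_descriptor_pairs = 1,
                                 constant_descriptor_count = 1,
                                 seed = 11)))
}

small_bank <- function() memo("small_bank", {
  study <- small_study()
  adj <- apply_adjustment(compute_fold_change(study$invivo),
                          compute_fold_change(study$invitro))
  desc <- normalize_descriptors(curate_descriptors(study$descriptors))
  retained <- filter_genes(adj$invivo, min_substances = 5)
  list(bank = train_bank(adj$invivo, adj$invitro, desc, retained,
                         alpha_grid = c(0.5, 1), nlambda = 40, seed = 11),
       prep = list(invivo = adj$invivo, invitro = adj$invitro,
                   descriptors = desc, retained = retained),
       study = study)
})

# replicate-table TSV writer for reader tests
write_replicate_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# complete replicate data frame: every (substance, gene, group) with
# n reps, flat signals
make_replicate_df <- function(substances, genes, nrep, signal = 100,
                              call = "P") {
  g <- expand.grid(replicate = seq_len(nrep), gene = genes,
                   substance = substances,
                   group = c("control", "treated"),
                   stringsAsFactors = FALSE)
  data.frame(substance = g$substance, gene = g$gene, group = g$group,
             replicate = g$replicate, signal = signal, call = call,
             stringsAsFactors = FALSE)
}

# independently coded Welch t-test on log2 signals (the test oracle)
welch_oracle_p <- function(treated, control) {
  x <- log2(treated); y <- log2(control)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(t), df)
}

# closed-form weighted ridge in the glmnet parameterization: the
# quadratic penalty is lambda / sd_w(y) on the standardized features
ridge_oracle <- function(xs, y, w, lambda) {
  wn <- w / sum(w)
  sy <- sqrt(sum(wn * (y - sum(wn * y))^2))
  xc <- sweep(xs, 2, colSums(xs * wn))
  yc <- y - sum(wn * y)
  unname(drop(solve(crossprod(xc, xc * wn) + (lambda / sy) * diag(ncol(xs)),
                    crossprod(xc, wn * yc))))
}
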
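# Synthetic paired in vivo / in vitro studies with the statistical
# structure the model bank assumes: descriptors drive in vitro responses
# through a sparse linear map, in vivo responses depend on descriptors
# plus (for a designated gene subset) on the in vitro signal, and
# replicate-level signals carry MAS5-style Absent calls enriched at low
# intensities.

#' Configuration for the synthetic study generator
#'
#' Defaults describe a desk-scale study: 80 substances, 20 genes, 30
#' informative descriptors, triplicate in vivo and duplicate in vitro
#' groups, log2-scale effects of sd 1 (about two-fold changes) with
#' measurement noise of sd 0.1, and a 43% toxic fraction matching the
#' class balance of the 115-compound hepatotoxicity panel the workflow
#' targets.
#'
#' @param n_substances,n_genes,n_descriptors Core dimensions.
#' @param n_invitro_driven_genes Genes whose in vivo response depends on
#'   the in vitro signal (nonzero in vitro -> in vivo map).
#' @param descriptor_sparsity Fraction of nonzero descriptor -> gene
#'   effects.
#' @param effect_size_sd SD of nonzero effects (log2 scale).
#' @param noise_sd_invitro,noise_sd_invivo SD of the additive log2 noise
#'   on the true fold changes.
#' @param replicate_noise_sd SD of per-replicate log2 signal noise.
#' @param absent_call_rate Marginal probability of an Absent call,
#'   enriched at low signals.
#' @param toxic_fraction Fraction of substances labeled toxic.
#' @param correlated_descriptor_pairs Planted near-duplicate descriptor
#'   columns (to exercise curation).
#' @param constant_descriptor_count Planted constant columns.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_substances = 80, n_genes = 20, n_descriptors = 30,
                       n_invitro_driven_genes = 8,
                       descriptor_sparsity = 0.1, effect_size_sd = 1,
                       noise_sd_invitro = 0.1, noise_sd_invivo = 0.1,
                       replicate_noise_sd = 0.1, absent_call_rate = 0.1,
                       toxic_fraction = 0.43,
                       correlated_descriptor_pairs = 2,
                       constant_descriptor_count = 1, seed = 7) {
  cfg <- as.list(environment())
  stopifnot(n_substances > 0, n_genes > 0, n_descriptors > 0,
            n_invitro_driven_genes >= 0,
            descriptor_sparsity >= 0, descriptor_sparsity <= 1,
            absent_call_rate >= 0, absent_call_rate <= 1,
            toxic_fraction >= 0, toxic_fraction <= 1)
  if (n_invitro_driven_genes > n_genes) {
    stop("n_invitro_driven_genes cannot exceed n_genes", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic paired study
#'
#' Draws standard-normal descriptors (plus planted duplicate, correlated
#' and constant columns), a sparse descriptor -> in vitro map `A`, a
#' sparse descriptor -> in vivo map `B`, and an in vitro -> in vivo map
#' `C` that is nonzero only for the in-vitro-driven gene set. True log2
#' fold changes are `V = D A + e_vitro` (in vitro) and
#' `Y = D B + V C + e_vivo` (in vivo). Replicate-level signals are built
#' around per-cell lognormal baselines: control replicates
#' `baseline * 2^e`, treated `baseline * 2^(logFC + e)` with replicate
#' noise `e`. Absent calls are drawn at the configured marginal rate with
#' probability decreasing in signal rank, mimicking MAS5 detection
#' behavior. A latent toxicity score (mean absolute in vivo response)
#' thresholded at the configured quantile defines the labels.
#'
#' @param config A [sim_config()].
#' @return List with `invivo` and `invitro` `replicate_table`s,
#'   `descriptors` (raw `descriptor_table`), `labels`, and `truth`
#'   (maps `A`, `B`, `C`, `driven_genes`, true log2 fold-change matrices
#'   `invivo_log2fc` / `invitro_log2fc`, latent scores).
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(config$seed))
  n <- config$n_substances; G <- config$n_genes; P <- config$n_descriptors
  subs <- sprintf("s%03d", seq_len(n))
  gns <- sprintf("g%03d", seq_len(G))
  desc <- sprintf("d%03d", seq_len(P))

  D <- matrix(stats::rnorm(n * P), n, P, dimnames = list(subs, desc))

  # planted curation targets: near-duplicates and constants
  extra <- NULL
  if (config$correlated_descriptor_pairs > 0) {
    src <- seq_len(config$correlated_descriptor_pairs)
    extra <- sapply(src, function(j) D[, j] + stats::rnorm(n, sd = 0.05))
    colnames(extra) <- paste0(desc[src], "_cor")
  }
  if (config$constant_descriptor_count > 0) {
    const <- matrix(1, n, config$constant_descriptor_count,
                    dimnames = list(subs,
                                    sprintf("const%02d",
                                            seq_len(config$constant_descriptor_count))))
    extra <- cbind(extra, const)
  }
  D_full <- cbind(D, extra)

  sparse_map <- function(p, g) {
    m <- matrix(0, p, g)
    nz <- stats::runif(p * g) < config$descriptor_sparsity
    m[nz] <- stats::rnorm(sum(nz), sd = config$effect_size_sd)
    m
  }
  A <- sparse_map(P, G); dimnames(A) <- list(desc, gns)
  B <- sparse_map(P, G); dimnames(B) <- list(desc, gns)
  # guarantee every gene has signal: at least one descriptor effect
  for (j in seq_len(G)) {
    if (all(A[, j] == 0)) A[sample(P, 1), j] <- stats::rnorm(1, sd = config$effect_size_sd)
    if (all(B[, j] == 0)) B[sample(P, 1), j] <- stats::rnorm(1, sd = config$effect_size_sd)
  }
  driven <- sort(sample(gns, config$n_invitro_driven_genes))
  C <- matrix(0, G, G, dimnames = list(gns, gns))
  for (g in driven) {
    C[g, g] <- sample(c(-1, 1), 1) * stats::runif(1, 0.8, 1.2)
  }

  V <- D %*% A + matrix(stats::rnorm(n * G, sd = config$noise_sd_invitro),
                        n, G)
  Y <- D %*% B + V %*% C +
    matrix(stats::rnorm(n * G, sd = config$noise_sd_invivo), n, G)
  dimnames(V) <- dimnames(Y) <- list(subs, gns)

  latent <- rowMeans(abs(Y))
  cutoff <- stats::quantile(latent, 1 - config$toxic_fraction,
                            names = FALSE)
  labels <- stats::setNames(ifelse(latent >= cutoff, "toxic", "non_toxic"),
                            subs)

  invivo <- replicate_records(Y, "in_vivo", 3L, config)
  invitro <- replicate_records(V, "in_vitro", 2L, config)

  list(
    invivo = invivo,
    invitro = invitro,
    descriptors = descriptor_table(D_full),
    labels = labels,
    truth = list(A = A, B = B, C = C, driven_genes = driven,
                 invivo_log2fc = Y, invitro_log2fc = V,
                 latent_score = latent)
  )
}

# Build a replicate_table around per-cell lognormal baselines; Absent
# call probability decreases with the signal's rank so low-intensity
# cells are preferentially flagged.
replicate_records <- function(logfc, source, nrep, config) {
  n <- nrow(logfc); G <- ncol(logfc)
  subs <- rownames(logfc); gns <- colnames(logfc)
  baseline <- matrix(2^stats::rnorm(n * G, mean = 7, sd = 1), n, G)
  grid <- expand.grid(replicate = seq_len(nrep), gene = gns,
                      substance = subs, group = c("control", "treated"),
                      stringsAsFactors = FALSE)
  b <- baseline[cbind(match(grid$substance, subs), match(grid$gene, gns))]
  fc <- logfc[cbind(match(grid$substance, subs), match(grid$gene, gns))]
  eps <- stats::rnorm(nrow(grid), sd = config$replicate_noise_sd)
  signal <- b * 2^(ifelse(grid$group == "treated", fc, 0) + eps)
  call <- rep("P", nrow(grid))
  if (config$absent_call_rate > 0) {
    pct <- rank(log2(signal)) / (nrow(grid) + 1)
    p_absent <- pmin(1, 2 * config$absent_call_rate * (1 - pct))
    absent <- stats::runif(nrow(grid)) < p_absent
    call[absent] <- "A"
    call[!absent & stats::runif(nrow(grid)) < 0.05] <- "M"
  }
  df <- data.frame(substance = grid$substance, gene = grid$gene,
                   group = grid$group, replicate = grid$replicate,
                   signal = signal, call = call,
                   stringsAsFactors = FALSE)
  replicate_table(df, source = source, replicates_per_group = nrep)
}

#' Hand-built worked example exercising every preprocessing branch
#'
#' A 6-substance, 4-gene, 5-descriptor in-memory dataset whose replicate
#' signals were chosen so that, after [compute_fold_change()] and
#' [apply_adjustment()], the in vivo matrix contains:
#' \itemize{
#'   \item `(s1, g1)`: F = 1.5 with 2/3 treated Absent calls -> half
#'     rule -> 1.25;
#'   \item `(s2, g1)`: F = 1.4 with Welch p = 0.274 -> quarter rule ->
#'     1.1;
#'   \item `(s3, g1)`: all calls Absent in vivo and in vitro -> set to 1;
#'   \item `(s4, g1)`: F = 3 with p < 0.05, clean flags -> unchanged
#'     (weight 1.5); `(s5, g1)`: F = 4 (weight 2); `(s6, g1)`: F = 1
#'     (weight 1);
#'   \item `(s6, g2)`: F = 1.5 with Welch p = 0.0586 in the \[0.05, 0.1\]
#'     band -> half rule -> 1.25.
#' }
#' Gene-level differential-expression counts (|FC| >= 1.5 after
#' adjustment) are g1: 2, g2: 3, g3: 3, g4: 1, so
#' `filter_genes(min_substances = 3)` retains exactly g2 and g3. The
#' descriptor table plants one exact duplicate column (`d4 = d1`) and
#' one constant column (`d5`).
#'
#' @return List with `invivo`, `invitro` (`replicate_table`s),
#'   `descriptors`, `labels`, and `expected` (the planted adjusted
#'   values, weights and retained gene set).
#' @export
worked_example_fixture <- function() {
  subs <- paste0("s", 1:6); gns <- paste0("g", 1:4)
  # per-cell recipes: control triple, treated triple, treated calls
  tight <- function(f) list(ct = c(99, 100, 101), tr = f * c(99, 100, 101),
                            calls = c("P", "P", "P"))
  rows <- list()
  add <- function(s, g, ct, tr, ct_calls, tr_calls) {
    rows[[length(rows) + 1]] <<- data.frame(
      substance = s, gene = g,
      group = rep(c("control", "treated"), each = 3),
      replicate = rep(1:3, 2), signal = c(ct, tr),
      call = c(ct_calls, tr_calls), stringsAsFactors = FALSE)
  }
  P3 <- c("P", "P", "P"); A3 <- c("A", "A", "A")
  # g1: the adjustment-rule showcase
  add("s1", "g1", c(100, 100, 100), c(150, 150, 150), P3, c("A", "A", "P"))
  add("s2", "g1", c(80, 120, 100), c(196, 98, 126), P3, P3)  # p = 0.274
  add("s3", "g1", c(100, 100, 100), c(200, 200, 200), A3, A3)
  add("s4", "g1", c(99, 100, 101), 3 * c(99, 100, 101), P3, P3)
  add("s5", "g1", c(99, 100, 101), 4 * c(99, 100, 101), P3, P3)
  add("s6", "g1", c(99, 100, 101), c(99, 100, 101), P3, P3)
  # g2: three clear responders + the p-band cell
  for (s in paste0("s", 1:3)) {
    r <- tight(2); add(s, "g2", r$ct, r$tr, P3, P3)
  }
  add("s4", "g2", c(99, 100, 101), c(99, 100, 101), P3, P3)
  add("s5", "g2", c(99, 100, 101), c(99, 100, 101), P3, P3)
  add("s6", "g2", c(90, 110, 100), c(120, 180, 150), P3, P3)  # p = 0.0586
  # g3: exactly three responders (down-regulation included)
  r <- tight(2); add("s1", "g3", r$ct, r$tr, P3, P3)
  r <- tight(0.5); add("s2", "g3", r$ct, r$tr, P3, P3)
  r <- tight(6); add("s3", "g3", r$ct, r$tr, P3, P3)
  for (s in paste0("s", 4:6)) {
    r <- tight(1); add(s, "g3", r$ct, r$tr, P3, P3)
  }
  # g4: a single responder
  r <- tight(2); add("s1", "g4", r$ct, r$tr, P3, P3)
  for (s in paste0("s", 2:6)) {
    r <- tight(1); add(s, "g4", r$ct, r$tr, P3, P3)
  }
  invivo <- replicate_table(do.call(rbind, rows), source = "in_vivo")

  # in vitro: duplicates, flat fold changes except matched all-Absent cell
  rows <- list()
  add2 <- function(s, g, f, calls) {
    rows[[length(rows) + 1]] <<- data.frame(
      substance = s, gene = g,
      group = rep(c("control", "treated"), each = 2),
      replicate = rep(1:2, 2), signal = c(100, 102, f * c(100, 102)),
      call = calls, stringsAsFactors = FALSE)
  }
  vitro_f <- c(s1 = 1.1, s2 = 1.3, s3 = 0.8, s4 = 1.6, s5 = 0.6, s6 = 1.2)
  for (s in subs) for (g in gns) {
    if (s == "s3" && g == "g1") {
      add2(s, g, 2, c("A", "A", "A", "A"))
    } else {
      # per-substance variation so downstream PCA sees nondegenerate data
      f <- unname(vitro_f[s]) * c(1, 1.05, 1.1, 0.95)[match(g, gns)]
      add2(s, g, f, c("P", "P", "P", "P"))
    }
  }
  invitro <- replicate_table(do.call(rbind, rows), source = "in_vitro")

  desc <- cbind(d1 = c(0.1, 1.2, -0.5, 2.0, -1.1, 0.4),
                d2 = c(1.0, -0.3, 0.8, -1.5, 0.2, 2.1),
                d3 = c(-0.7, 0.5, 1.9, 0.3, -2.0, 1.1),
                d4 = c(0.1, 1.2, -0.5, 2.0, -1.1, 0.4),  # duplicate of d1
                d5 = rep(3, 6))                           # constant
  rownames(desc) <- subs
  labels <- stats::setNames(rep(c("toxic", "non_toxic"), 3), subs)
  list(
    invivo = invivo, invitro = invitro,
    descriptors = descriptor_table(desc), labels = labels,
    expected = list(
      adjusted = c(s1_g1 = 1.25, s2_g1 = 1.1, s3_g1 = 1, s4_g1 = 3,
                   s6_g2 = 1.25),
      weights = c(s4_g1 = 1.5, s5_g1 = 2, s6_g1 = 1),
      retained_genes = c("g2", "g3"),
      min_substances = 3
    )
  )
}

#' Ground-truth feature support for one synthetic gene
#'
#' The features that truly influence a gene's in vivo response in the
#' generator: the descriptors with nonzero direct effect (`B`), and, for
#' in-vitro-driven genes, the gene's own in vitro feature together with
#' the descriptors that drive that in vitro signal (`A`). The latter are
#' included because the in vitro signal is, up to the generator's noise,
#' a linear function of those descriptors, so a fitted model may
#' represent the same dependence through either route; both are correct
#' recoveries of the planted structure.
#'
#' @param truth The `truth` element of [generate_study()] output.
#' @param gene Gene id.
#' @param retained_genes Genes available as in vitro features.
#' @return Character vector of feature names (descriptor ids and
#'   `invitro:<gene>` names).
#' @export
truth_support <- function(truth, gene, retained_genes) {
  sup <- rownames(truth$B)[truth$B[, gene] != 0]
  if (any(truth$C[, gene] != 0)) {
    drivers <- rownames(truth$C)[truth$C[, gene] != 0]
    drivers <- intersect(drivers, retained_genes)
    sup <- union(sup, paste0("invitro:", drivers))
    for (d in drivers) {
      sup <- union(sup, rownames(truth$A)[truth$A[, d] != 0])
    }
  }
  sup
}
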
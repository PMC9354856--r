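# End-to-end orchestration: preprocess -> filter -> train -> predict ->
# PCA / read-across -> RMSE evaluation, with a machine-readable run
# manifest. The command-line wrapper in inst/cli/raid.R is a thin shell
# over these functions.

#' Run the full virtual-microarray workflow
#'
#' Executes the whole pipeline on either a simulated study (when
#' `config$simulate` is a [sim_config()]) or on TSV inputs
#' (`config$invivo`, `config$invitro` replicate tables,
#' `config$descriptors`, optional `config$labels`), writing the standard
#' report bundle to `config$out_dir`:
#' adjusted fold-change matrices, the trained model bank, the predicted
#' in vivo matrix, PCA scores/loadings for the in vivo / predicted /
#' in vitro sources, quadrant gene rankings, the PC-related gene-set
#' Venn counts, the normalized-RMSE comparison, the in vitro importance
#' ranking, and a JSON run manifest. All randomness derives from
#' `config$seed`.
#'
#' @param config List; recognized fields beyond the inputs:
#'   `out_dir` (required), `seed` (default 1), `min_substances` (gene
#'   filter, default 10), `alpha_grid`, `nlambda`, `cv_folds`,
#'   `pca_top_k` (default 30), `quiet`.
#' @return Invisibly, a list with the in-memory results (`bank`,
#'   `predicted`, `pca`, `rmse`, `venn`, ...).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  quiet <- isTRUE(config$quiet)
  say <- function(...) if (!quiet) message("[raidr] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("stage: inputs")
  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      generate_study(config$simulate)
    } else {
      list(
        invivo = read_replicate_table(config$invivo, "in_vivo"),
        invitro = read_replicate_table(config$invitro, "in_vitro"),
        descriptors = read_descriptor_table(config$descriptors),
        labels = if (!is.null(config$labels)) {
          read_toxicity_labels(config$labels)
        }
      )
    }
  })

  say("stage: preprocess")
  prep <- stage("preprocess", {
    fc_vivo <- compute_fold_change(inputs$invivo)
    fc_vitro <- compute_fold_change(inputs$invitro)
    adj <- apply_adjustment(fc_vivo, fc_vitro)
    desc <- normalize_descriptors(curate_descriptors(inputs$descriptors))
    list(invivo = adj$invivo, invitro = adj$invitro, descriptors = desc)
  })
  write_fc_matrix(prep$invivo, file.path(out_dir, "fc_invivo.tsv"))
  write_fc_matrix(prep$invitro, file.path(out_dir, "fc_invitro.tsv"))
  write_descriptor_table(prep$descriptors,
                         file.path(out_dir, "descriptors_normalized.tsv"))

  say("stage: filter")
  retained <- stage("filter", {
    filter_genes(prep$invivo,
                 min_substances = config$min_substances %||% 10)
  })
  if (length(retained) == 0) {
    stop("stage 'filter' failed: no gene passes the differential-",
         "expression filter", call. = FALSE)
  }
  writeLines(retained, file.path(out_dir, "retained_genes.txt"))

  say("stage: train (", length(retained), " genes)")
  bank <- stage("train", {
    train_bank(prep$invivo, prep$invitro, prep$descriptors, retained,
               alpha_grid = config$alpha_grid %||% seq(0, 1, by = 0.1),
               nlambda = config$nlambda %||% 100,
               cv_folds = config$cv_folds %||% 5,
               seed = seed, verbose = !quiet)
  })
  write_model_bank(bank, file.path(out_dir, "bank.raidr.json"))

  say("stage: predict")
  predicted <- stage("predict", {
    predict(bank, prep$descriptors, invitro = prep$invitro)
  })
  write_fc_matrix(predicted, file.path(out_dir, "fc_predicted.tsv"),
                  companions = FALSE)

  say("stage: read-across")
  k <- config$pca_top_k %||% 30
  ra <- stage("read_across", {
    sub <- function(fc) fc_subset(fc, genes = retained)
    mats <- list(in_vivo = sub(prep$invivo), raid = predicted,
                 in_vitro = sub(prep$invitro))
    # a source with no variation (e.g. all-null models on degenerate
    # inputs) cannot be ordinated; it is skipped, not fatal
    usable <- vapply(mats, function(m) {
      any(apply(m$log2_values, 2, stats::sd) > 0)
    }, logical(1))
    pcas <- lapply(mats[usable], fit_pca)
    quadrants <- if (!is.null(pcas$in_vivo)) {
      lapply(c(1, 4), function(q) quadrant_top_genes(pcas$in_vivo, q,
                                                     k = k))
    } else list()
    venn <- if (length(pcas) >= 2) {
      venn_partition(lapply(pcas, pc_related_gene_set, k = k))
    }
    list(pcas = pcas, quadrants = quadrants, venn = venn,
         skipped_sources = names(usable)[!usable])
  })
  for (nm in names(ra$pcas)) {
    p <- ra$pcas[[nm]]
    write_matrix_tsv(p$scores, file.path(out_dir,
                                         paste0("pca_scores_", nm, ".tsv")))
    write_matrix_tsv(p$loadings,
                     file.path(out_dir, paste0("pca_loadings_", nm, ".tsv")))
  }
  for (q in ra$quadrants) {
    utils::write.table(q, file.path(out_dir,
                                    sprintf("quadrant%d_top_genes.tsv",
                                            attr(q, "quadrant"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(ra$venn)) {
    utils::write.table(
      data.frame(region = names(ra$venn), count = as.integer(ra$venn)),
      file.path(out_dir, "venn_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("stage: evaluate")
  rmse <- stage("evaluate", {
    list(all = qivive_rmse(predicted, fc_subset(prep$invivo, retained),
                           fc_subset(prep$invitro, retained),
                           scope = "all"),
         invitro_important = qivive_rmse(
           predicted, fc_subset(prep$invivo, retained),
           fc_subset(prep$invitro, retained),
           scope = "invitro_important", bank = bank))
  })
  rmse_df <- data.frame(
    gene = names(rmse$all$per_gene_rmse_raid),
    rmse_raid = unname(rmse$all$per_gene_rmse_raid),
    rmse_invitro = unname(rmse$all$per_gene_rmse_invitro))
  utils::write.table(rmse_df, file.path(out_dir, "rmse_per_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  imp <- top_importance_genes(bank, k = min(20, length(bank$models)))
  utils::write.table(imp, file.path(out_dir, "invitro_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    command = "run",
    tool = "raidr",
    version = as.character(utils::packageVersion("raidr")),
    seed = seed,
    config = config[setdiff(names(config), "simulate")],
    simulate = if (!is.null(config$simulate)) unclass(config$simulate),
    input_digests = manifest_digests(config),
    n_retained_genes = length(retained),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", digits = NA),
             file.path(out_dir, "manifest.json"))
  say("done: ", out_dir)
  invisible(list(inputs = inputs, preprocessed = prep, retained = retained,
                 bank = bank, predicted = predicted, read_across = ra,
                 rmse = rmse, importance = imp))
}

manifest_digests <- function(config) {
  files <- unlist(config[intersect(names(config),
                                   c("invivo", "invitro", "descriptors",
                                     "labels"))])
  if (length(files) == 0) return(NULL)
  as.list(tools::md5sum(files))
}

#' Subset a fold-change matrix by substances and/or genes
#' @param fc A `fold_change_matrix`.
#' @param genes,substances Ids to keep (default all), in the given order.
#' @return A `fold_change_matrix` restricted to the selection.
#' @export
fc_subset <- function(fc, genes = NULL, substances = NULL) {
  g <- genes %||% colnames(fc$values)
  s <- substances %||% rownames(fc$values)
  sel <- function(m) if (is.null(m)) NULL else m[s, g, drop = FALSE]
  fold_change_matrix(fc$values[s, g, drop = FALSE], source = fc$source,
                     pvalues = sel(fc$pvalues), flagA = sel(fc$flagA),
                     all_absent = sel(fc$all_absent))
}
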
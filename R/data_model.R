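# Core containers: replicate expression tables, fold-change matrices,
# descriptor tables, toxicity labels, and the serialized model bank.
# All interchange files are TSV (UTF-8, "." decimal), substances as rows.

BANK_SCHEMA_VERSION <- "raidr-bank/1"

#' Expected replicates per treatment group for a data source
#'
#' In vivo liver studies carry triplicate treated/control groups; primary
#' hepatocyte (in vitro) studies carry duplicates.
#'
#' @param source `"in_vivo"` or `"in_vitro"`.
#' @return Integer number of replicates per group.
#' @export
default_replicates <- function(source) {
  source <- match.arg(source, c("in_vivo", "in_vitro"))
  if (source == "in_vivo") 3L else 2L
}

#' Read a replicate-level expression table
#'
#' Reads a TSV with columns `substance`, `gene`, `group`, `replicate`,
#' `signal`, `call` holding MAS5-scale expression signals and A/M/P
#' detection calls for treated and solvent-control groups. Validation is
#' strict: every (substance, gene, group) triple must have exactly the
#' expected number of replicates for the data source, signals must be
#' strictly positive numbers, and detection calls must be one of A, M, P.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param source Data source tag, `"in_vivo"` or `"in_vitro"`; sets the
#'   required replicate count (3 in vivo, 2 in vitro) unless
#'   `replicates_per_group` overrides it.
#' @param replicates_per_group Optional replicate-count override.
#' @return A `replicate_table` object: a validated data frame with
#'   attributes `source` and `replicates_per_group`.
#' @export
read_replicate_table <- function(path, source, replicates_per_group = NULL) {
  source <- match.arg(source, c("in_vivo", "in_vitro"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  required <- c("substance", "gene", "group", "replicate", "signal", "call")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("replicate table '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$signal <- strict_numeric(df$signal, "signal", path)
  df$replicate <- as.integer(strict_numeric(df$replicate, "replicate", path))
  replicate_table(df, source = source,
                  replicates_per_group = replicates_per_group)
}

#' Construct a validated replicate table from a data frame
#'
#' @param records Data frame with columns `substance`, `gene`, `group`,
#'   `replicate`, `signal`, `call`.
#' @inheritParams read_replicate_table
#' @return A `replicate_table` object.
#' @export
replicate_table <- function(records, source, replicates_per_group = NULL) {
  source <- match.arg(source, c("in_vivo", "in_vitro"))
  if (is.null(replicates_per_group)) {
    replicates_per_group <- default_replicates(source)
  }
  bad_group <- which(!records$group %in% c("treated", "control"))
  if (length(bad_group) > 0) {
    stop("row ", bad_group[1], ": group must be 'treated' or 'control', got '",
         records$group[bad_group[1]], "'", call. = FALSE)
  }
  bad_call <- which(!records$call %in% c("A", "M", "P"))
  if (length(bad_call) > 0) {
    stop("row ", bad_call[1], ": unknown detection call '",
         records$call[bad_call[1]], "' (expected A, M or P)", call. = FALSE)
  }
  bad_sig <- which(!is.finite(records$signal) | records$signal <= 0)
  if (length(bad_sig) > 0) {
    stop("row ", bad_sig[1], ": signal must be strictly positive, got ",
         records$signal[bad_sig[1]], call. = FALSE)
  }
  counts <- table(records$substance, records$gene, records$group)
  off <- which(counts != replicates_per_group, arr.ind = TRUE)
  if (nrow(off) > 0) {
    i <- off[1, ]
    stop("substance '", dimnames(counts)[[1]][i[1]], "', gene '",
         dimnames(counts)[[2]][i[2]], "', group '",
         dimnames(counts)[[3]][i[3]], "': found ",
         counts[i[1], i[2], i[3]], " replicate(s), expected ",
         replicates_per_group, call. = FALSE)
  }
  structure(records, class = c("replicate_table", "data.frame"),
            source = source, replicates_per_group = replicates_per_group)
}

# Convert character cells to numeric, refusing silent coercion.
strict_numeric <- function(x, what, path = "<in-memory>") {
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y) & !is.na(x) & x != "NA")
  if (length(bad) > 0) {
    stop("non-numeric value '", x[bad[1]], "' in column '", what,
         "' of '", path, "' (row ", bad[1], ")", call. = FALSE)
  }
  y
}

#' Construct a fold-change matrix
#'
#' Holds substance-by-gene fold changes on the ratio scale with a derived
#' base-2 logarithmic view, tagged by data source, plus optional per-cell
#' Welch p-values, treated-group Absent-call counts, and all-Absent flags.
#'
#' @param values Numeric matrix of ratio-scale fold changes
#'   (treated mean / control mean), strictly positive, with substance row
#'   names and gene column names.
#' @param source `"in_vivo"`, `"in_vitro"` or `"predicted"`.
#' @param pvalues Optional matrix of per-cell p-values (same shape).
#' @param flagA Optional matrix of treated-group Absent-call counts.
#' @param all_absent Optional logical matrix: all calls (treated and
#'   control) Absent for the cell within this source.
#' @return A `fold_change_matrix` object.
#' @export
fold_change_matrix <- function(values, source,
                               pvalues = NULL, flagA = NULL,
                               all_absent = NULL) {
  source <- match.arg(source, c("in_vivo", "in_vitro", "predicted"))
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values <= 0)) {
    bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)[1, ]
    stop("fold change must be finite and > 0; offending cell: substance '",
         rownames(values)[bad[1]], "', gene '", colnames(values)[bad[2]],
         "'", call. = FALSE)
  }
  for (m in list(pvalues, flagA, all_absent)) {
    if (!is.null(m) && !identical(dim(m), dim(values))) {
      stop("optional matrix shape does not match fold-change matrix",
           call. = FALSE)
    }
  }
  structure(list(values = values, log2_values = log2(values),
                 source = source, pvalues = pvalues, flagA = flagA,
                 all_absent = all_absent),
            class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat("fold_change_matrix [", x$source, "]: ", nrow(x$values),
      " substances x ", ncol(x$values), " genes\n", sep = "")
  invisible(x)
}

#' @export
dim.fold_change_matrix <- function(x) dim(x$values)

#' Substance identifiers of a container
#' @param x A `fold_change_matrix` or `descriptor_table`.
#' @return Character vector of substance ids in storage order.
#' @export
substances <- function(x) {
  if (inherits(x, "fold_change_matrix")) rownames(x$values)
  else if (inherits(x, "descriptor_table")) rownames(x$values)
  else stop("no substance axis for class ", paste(class(x), collapse = "/"))
}

#' Gene identifiers of a fold-change matrix
#' @param x A `fold_change_matrix`.
#' @return Character vector of gene ids in storage order.
#' @export
genes <- function(x) colnames(x$values)

#' Write / read a fold-change matrix as TSV
#'
#' The ratio-scale values are written substances-as-rows with the first
#' column `substance_id`. Optional p-value and flag matrices are written
#' alongside as `<path>.pvalues` / `<path>.flagA` companions when present.
#'
#' @param fc A `fold_change_matrix`.
#' @param path Output TSV path.
#' @param companions Write companion p-value/flag files when present.
#' @export
write_fc_matrix <- function(fc, path, companions = TRUE) {
  write_matrix_tsv(fc$values, path)
  if (companions && !is.null(fc$pvalues)) {
    write_matrix_tsv(fc$pvalues, paste0(path, ".pvalues"))
  }
  if (companions && !is.null(fc$flagA)) {
    write_matrix_tsv(fc$flagA, paste0(path, ".flagA"))
  }
  invisible(NULL)
}

#' @rdname write_fc_matrix
#' @param source Data source tag for the matrix read back.
#' @export
read_fc_matrix <- function(path, source) {
  vals <- read_matrix_tsv(path)
  pv <- if (file.exists(paste0(path, ".pvalues"))) {
    read_matrix_tsv(paste0(path, ".pvalues"))
  }
  fl <- if (file.exists(paste0(path, ".flagA"))) {
    read_matrix_tsv(paste0(path, ".flagA"))
  }
  fold_change_matrix(vals, source = source, pvalues = pv, flagA = fl)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(substance_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "substance_id") {
    stop("matrix TSV '", path, "' must have 'substance_id' as first column",
         call. = FALSE)
  }
  ids <- df[[1]]
  m <- sapply(names(df)[-1],
              function(cn) strict_numeric(df[[cn]], cn, path))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(ids, names(df)[-1]))
  m
}

#' Construct a chemical descriptor table
#'
#' @param values Numeric matrix, substances as rows, descriptors as
#'   columns. Missing values are permitted before curation only.
#' @param curation_log Data frame of dropped descriptors with columns
#'   `descriptor` and `drop_reason` (`pair_correlation`, `constant`,
#'   `missing`).
#' @param transform_log Named list of fitted per-descriptor normalizing
#'   transforms (see [normalize_descriptors()]).
#' @param normalized Logical: columns centered/scaled by a fitted pipeline.
#' @return A `descriptor_table` object.
#' @export
descriptor_table <- function(values, curation_log = empty_curation_log(),
                             transform_log = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("descriptor table needs substance row names and descriptor ",
         "column names", call. = FALSE)
  }
  structure(list(values = values, curation_log = curation_log,
                 transform_log = transform_log, normalized = normalized),
            class = "descriptor_table")
}

empty_curation_log <- function() {
  data.frame(descriptor = character(0), drop_reason = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("descriptor_table: ", nrow(x$values), " substances x ",
      ncol(x$values), " descriptors",
      if (x$normalized) " (normalized)" else "", "\n", sep = "")
  invisible(x)
}

#' Read / write a descriptor table as TSV
#'
#' @param path TSV path; first column `substance_id`, remaining columns
#'   numeric descriptors. Empty cells or `NA` are read as missing values
#'   (legal only before curation); any other non-numeric cell is an error.
#' @return A `descriptor_table`.
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (names(df)[1] != "substance_id") {
    stop("descriptor TSV '", path, "' must have 'substance_id' as first ",
         "column", call. = FALSE)
  }
  ids <- df[[1]]
  m <- sapply(names(df)[-1], function(cn) strict_numeric(df[[cn]], cn, path))
  m <- matrix(m, nrow = nrow(df), dimnames = list(ids, names(df)[-1]))
  descriptor_table(m)
}

#' @rdname read_descriptor_table
#' @param table A `descriptor_table`.
#' @export
write_descriptor_table <- function(table, path) {
  write_matrix_tsv(table$values, path)
}

#' Read toxicity class labels
#'
#' Reads a TSV with columns `substance_id` and `tox_class`
#' (`toxic`/`non_toxic`). If `expression_substances` is given, every
#' labeled substance must appear in it.
#'
#' @param path TSV path.
#' @param expression_substances Optional character vector of substance ids
#'   present in the expression data.
#' @return Named character vector substance_id -> class.
#' @export
read_toxicity_labels <- function(path, expression_substances = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (cn in c("substance_id", "tox_class")) {
    if (!cn %in% names(df)) {
      stop("label table '", path, "' missing column '", cn, "'",
           call. = FALSE)
    }
  }
  toxicity_labels(stats::setNames(df$tox_class, df$substance_id),
                  expression_substances)
}

#' @rdname read_toxicity_labels
#' @param labels Named character vector substance_id -> class.
#' @export
toxicity_labels <- function(labels, expression_substances = NULL) {
  bad <- which(!labels %in% c("toxic", "non_toxic"))
  if (length(bad) > 0) {
    stop("unknown toxicity class '", labels[bad[1]], "' for substance '",
         names(labels)[bad[1]], "'", call. = FALSE)
  }
  if (!is.null(expression_substances)) {
    orphan <- setdiff(names(labels), expression_substances)
    if (length(orphan) > 0) {
      stop("labeled substance(s) absent from expression data: ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    }
  }
  labels
}

#' Serialize a model bank to a schema-versioned text document
#'
#' The bank is written as human-diffable JSON at full double precision
#' (at least 15 significant digits), so `read_model_bank(write_model_bank(b))`
#' reproduces every coefficient, hyperparameter, median and log bit-exactly
#' at the serialized precision. A `schema_version` field is checked on read.
#'
#' @param bank A `raid_bank` (see [train_bank()]).
#' @param path Output path.
#' @export
write_model_bank <- function(bank, path) {
  doc <- list(
    schema_version = BANK_SCHEMA_VERSION,
    random_seed = bank$random_seed,
    training_gene_set = as.list(bank$training_gene_set),
    invitro_feature_medians = as.list(bank$invitro_feature_medians),
    descriptor_pipeline = serialize_pipeline(bank$descriptor_pipeline),
    models = lapply(bank$models, serialize_gene_model)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, path)
  invisible(NULL)
}

#' @rdname write_model_bank
#' @return `read_model_bank` returns a `raid_bank`.
#' @export
read_model_bank <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path), simplifyVector = FALSE)
  if (!identical(doc$schema_version, BANK_SCHEMA_VERSION)) {
    stop("unsupported model-bank schema_version '", doc$schema_version,
         "' (this build reads '", BANK_SCHEMA_VERSION, "')", call. = FALSE)
  }
  models <- lapply(doc$models, deserialize_gene_model)
  names(models) <- vapply(models, function(m) m$gene_id, character(1))
  structure(list(
    models = models,
    training_gene_set = as.character(unlist(doc$training_gene_set)),
    invitro_feature_medians = unlist_named_numeric(doc$invitro_feature_medians),
    descriptor_pipeline = deserialize_pipeline(doc$descriptor_pipeline),
    random_seed = as.integer(doc$random_seed %||% NA_integer_)
  ), class = "raid_bank")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unlist_named_numeric <- function(x) {
  if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
}

serialize_gene_model <- function(m) {
  list(gene_id = m$gene_id, intercept = m$intercept,
       beta = as.list(m$beta), beta_original = as.list(m$beta_original),
       alpha = m$alpha, lambda = m$lambda, cv_mse = m$cv_mse,
       feature_means = as.list(m$feature_means),
       feature_sds = as.list(m$feature_sds),
       invitro_features = as.list(m$invitro_features),
       degenerate = m$degenerate)
}

deserialize_gene_model <- function(d) {
  structure(list(
    gene_id = d$gene_id,
    intercept = as.numeric(d$intercept),
    beta = unlist_named_numeric(d$beta),
    beta_original = unlist_named_numeric(d$beta_original),
    alpha = as.numeric(d$alpha), lambda = as.numeric(d$lambda),
    cv_mse = as.numeric(d$cv_mse),
    feature_means = unlist_named_numeric(d$feature_means),
    feature_sds = unlist_named_numeric(d$feature_sds),
    invitro_features = as.character(unlist(d$invitro_features)),
    degenerate = isTRUE(d$degenerate)
  ), class = "gene_model")
}

serialize_pipeline <- function(p) {
  if (is.null(p)) return(NULL)
  list(kept = as.list(p$kept),
       curation_log = lapply(seq_len(nrow(p$curation_log)), function(i) {
         as.list(p$curation_log[i, , drop = FALSE])
       }),
       transforms = lapply(p$transforms, function(tr) {
         list(transform = tr$transform, lambda = tr$lambda,
              center = tr$center, scale = tr$scale)
       }))
}

deserialize_pipeline <- function(d) {
  if (is.null(d)) return(NULL)
  cl <- if (length(d$curation_log) == 0) empty_curation_log() else {
    do.call(rbind, lapply(d$curation_log, function(r) {
      data.frame(descriptor = r$descriptor, drop_reason = r$drop_reason,
                 stringsAsFactors = FALSE)
    }))
  }
  transforms <- lapply(d$transforms, function(tr) {
    list(transform = tr$transform,
         lambda = if (is.null(tr$lambda)) NULL else as.numeric(tr$lambda),
         center = as.numeric(tr$center), scale = as.numeric(tr$scale))
  })
  names(transforms) <- names(d$transforms)
  list(kept = as.character(unlist(d$kept)), curation_log = cl,
       transforms = transforms)
}
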
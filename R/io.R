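#' Read an interaction TSV
#'
#' Expected shape: one record per line with at least three tab-separated
#' columns — drug SMILES, protein sequence, numeric label or affinity.
#' Malformed rows (wrong column count, empty sequence, non-numeric third
#' column) are skipped with per-line diagnostics, or abort the read under
#' `strict = TRUE`.
#'
#' @param path File path.
#' @param has_header Skip a header line.
#' @param strict Abort on the first malformed row instead of skipping.
#' @return Data frame with `drug`, `protein`, `label` (numeric) and
#'   attribute `"skipped"` (line numbers of skipped rows).
#' @export
read_interactions <- function(path, has_header = FALSE, strict = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  lines <- readLines(path, warn = FALSE)
  first <- if (has_header) 2L else 1L
  if (length(lines) < first) stop("no data rows")
  rows <- seq(first, length(lines))
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad_msg <- function(i, why) sprintf("line %d: %s", rows[i], why)
  ok <- logical(length(rows))
  drug <- protein <- character(length(rows))
  label <- numeric(length(rows))
  skipped <- integer(0)
  for (i in seq_along(rows)) {
    f <- parts[[i]]
    why <- NULL
    if (length(f) < 3L) {
      why <- sprintf("expected >= 3 tab-separated columns, got %d", length(f))
    } else if (!nzchar(f[1L]) || !nzchar(f[2L])) {
      why <- "empty SMILES or protein sequence"
    } else {
      v <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(v)) why <- sprintf("non-numeric label '%s'", f[3L])
    }
    if (is.null(why)) {
      ok[i] <- TRUE
      drug[i] <- f[1L]; protein[i] <- f[2L]
      label[i] <- as.numeric(f[3L])
    } else {
      if (strict) stop(bad_msg(i, why))
      warning(bad_msg(i, why), call. = FALSE)
      skipped <- c(skipped, rows[i])
    }
  }
  if (!any(ok)) stop("zero valid rows")
  out <- data.frame(drug = drug[ok], protein = protein[ok],
                    label = label[ok], stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Write interaction records as TSV
#'
#' @param records Data frame with `drug`, `protein`, `label` (extra columns
#'   are written too).
#' @param path Output path.
#' @param header Write a header line.
#' @export
write_interactions <- function(records, path, header = FALSE) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Save or load a model checkpoint
#'
#' A checkpoint directory holds everything needed to reproduce predictions
#' from the artifact alone: the weights (`weights.rds`), the model
#' configuration (`model_config.yaml`), and both vocabulary JSONs.
#'
#' @param model A `dpi_model` or `dpi_fit`.
#' @param dir Checkpoint directory (created if missing).
#' @rdname checkpoint
#' @export
save_checkpoint <- function(model, dir) {
  if (inherits(model, "dpi_fit")) model <- model$model
  stopifnot(inherits(model, "dpi_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  yaml::write_yaml(unclass(model$config), file.path(dir, "model_config.yaml"))
  write_vocabulary(model$drug_vocab, file.path(dir, "drug_vocab.json"))
  write_vocabulary(model$protein_vocab, file.path(dir, "protein_vocab.json"))
  invisible(dir)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg <- do.call(model_config, yaml::read_yaml(file.path(dir, "model_config.yaml")))
  model <- structure(
    list(params = readRDS(file.path(dir, "weights.rds")),
         config = cfg,
         drug_vocab = read_vocabulary(file.path(dir, "drug_vocab.json")),
         protein_vocab = read_vocabulary(file.path(dir, "protein_vocab.json"))),
    class = "dpi_model")
  model
}

#' Score drug-protein pairs
#'
#' Deterministic scoring at the posterior mean. For binary models the
#' positive-class probability and thresholded class are appended; for
#' multiclass, per-class probabilities and the argmax class.
#'
#' @param model A `dpi_model` or `dpi_fit`.
#' @param records Data frame with `drug` and `protein` columns (a `label`
#'   column, if present, is carried through).
#' @param batch_size Scoring batch size.
#' @return The input data frame with score columns appended.
#' @export
predict_interactions <- function(model, records, batch_size = 256L) {
  if (inherits(model, "dpi_fit")) model <- model$model
  stopifnot(inherits(model, "dpi_model"),
            all(c("drug", "protein") %in% names(records)))
  recs <- records
  if (is.null(recs$label)) recs$label <- 0
  ds <- prepare_dataset(recs, model$drug_vocab, model$protein_vocab,
                        model$config)
  probs <- predict_dataset(model, ds, batch_size)
  out <- records
  if (model$config$n_classes == 2L) {
    out$prob <- probs[, 2L]
    out$pred <- as.integer(probs[, 2L] >= 0.5)
  } else {
    colnames(probs) <- paste0("prob_", seq_len(ncol(probs)) - 1L)
    out <- cbind(out, probs)
    out$pred <- max.col(probs, ties.method = "first") - 1L
  }
  out
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a run bit-for-bit given the same
#' data file: resolved configurations, seeds, vocabulary hashes, dataset
#' path and row count, and the package version.
#'
#' @param path Output JSON path.
#' @param model_cfg,train_cfg Resolved configurations.
#' @param data_path,n_rows Dataset provenance.
#' @param model The model (for vocabulary hashes).
#' @export
write_manifest <- function(path, model_cfg, train_cfg, data_path, n_rows,
                           model) {
  vhash <- function(v) {
    sum(v$char_to_index * seq_along(v$char_to_index)) + v$unk_index
  }
  obj <- list(
    package_version = as.character(utils::packageVersion("dpivae")),
    model_config = unclass(model_cfg),
    train_config = unclass(train_cfg),
    data = list(path = data_path, n_rows = n_rows),
    vocab_hash = list(drug = vhash(model$drug_vocab),
                      protein = vhash(model$protein_vocab))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the per-epoch training log as CSV
#'
#' @param fit A `dpi_fit`.
#' @param path Output CSV path.
#' @export
write_training_log <- function(fit, path) {
  utils::write.csv(format(fit$history, digits = 10), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
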
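# Reading/writing variant score tables, label harmonization and the
# labelled/unlabelled and validation/test partitions.

.MISSING_TOKENS <- c("", "NA", ".", "NaN")

#' Read a variant score table
#'
#' Reads a CSV/TSV of missense variants (one row per variant) with a
#' `variant_id` column, a clinical assertion `label` column, optionally a
#' `gene` column, and one numeric column per requested predictor score.
#' Empty cells, `NA`, `.` and `NaN` are treated as missing. Parsing is
#' strict: a non-numeric token in a score column is a row-level error,
#' and out-of-range scores (e.g. SIFT outside \[0, 1\]) are rejected.
#' Labels outside the recognized assertion vocabulary are mapped to
#' `unknown` with a warning.
#'
#' @param path Path to the table.
#' @param features Canonical feature names to extract (default all eight).
#' @param dialect `"csv"` or `"tsv"`.
#' @param aliases Optional named character vector mapping file column
#'   names to canonical names, e.g. `c(SIFT_score = "sift")`, for
#'   VEP-style exports.
#' @return A [VariantDataset-class] (labels not yet harmonized).
#' @seealso [harmonizeLabels()], [writeVariantTable()]
#' @export
readVariantTable <- function(path, features = sanfilippoFeatures(),
                             dialect = c("csv", "tsv"), aliases = NULL) {
  dialect <- match.arg(dialect)
  .check_features(features)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  if (!is.null(aliases)) {
    hit <- match(names(df), names(aliases))
    names(df)[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  }
  required <- c("variant_id", "label", features)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  scores <- matrix(NA_real_, n, length(features),
                   dimnames = list(NULL, features))
  for (f in features) {
    raw <- trimws(df[[f]])
    miss <- raw %in% .MISSING_TOKENS
    val <- suppressWarnings(as.numeric(raw[!miss]))
    bad <- which(is.na(val))
    if (length(bad)) {
      rows <- which(!miss)[bad]
      stop(sprintf("unparseable value '%s' for feature '%s' at line %d",
                   raw[!miss][bad[1]], f, rows[1] + 1L), call. = FALSE)
    }
    scores[!miss, f] <- val
  }
  rng <- featureRanges(features)
  for (f in features) {
    v <- scores[, f]
    bad <- which(!is.na(v) & (v < rng["min", f] | v > rng["max", f]))
    if (length(bad)) {
      stop(sprintf("feature '%s' out of range [%g, %g] at line %d (value %g)",
                   f, rng["min", f], rng["max", f], bad[1] + 1L, v[bad[1]]),
           call. = FALSE)
    }
  }
  lab <- .normalize_label(df$label)
  unk <- attr(lab, "unrecognized") & !tolower(trimws(df$label)) %in% "unknown"
  attr(lab, "unrecognized") <- NULL
  if (any(unk)) {
    warning(sprintf("%d label(s) outside the assertion vocabulary mapped to 'unknown' (e.g. '%s')",
                    sum(unk), df$label[which(unk)[1]]), call. = FALSE)
  }
  gene <- if ("gene" %in% names(df)) df$gene else NA_character_
  variantDataset(scores, variantId = df$variant_id, gene = gene, label = lab)
}

#' Write a variant score table
#'
#' Inverse of [readVariantTable()]: writes `variant_id`, `gene`, `label`
#' and one column per feature; missing scores become empty cells.
#' Numeric values are written at full precision so a write/read cycle
#' round-trips the dataset.
#'
#' @param ds A [VariantDataset-class].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(ds, path, dialect = c("csv", "tsv")) {
  stopifnot(is(ds, "VariantDataset"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  sc <- ds@scores
  out <- data.frame(variant_id = ds@variantId, gene = ds@gene,
                    label = ds@label, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (f in colnames(sc)) {
    col <- vapply(sc[, f], function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE)
    }, character(1))
    out[[f]] <- col
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Harmonize clinical assertion labels into binary classes
#'
#' Maps `benign`/`likely_benign` to class 0, `pathogenic`/
#' `likely_pathogenic` to class 1, and `VUS`/`unknown` to unlabelled
#' (`NA`), following the usual collapsing of five-tier clinical
#' assertions for binary classifier training.
#'
#' @param ds A [VariantDataset-class].
#' @return The dataset with its class vector filled in.
#' @export
harmonizeLabels <- function(ds) {
  stopifnot(is(ds, "VariantDataset"))
  y <- rep(NA_integer_, nrow(ds@scores))
  y[ds@label %in% c("benign", "likely_benign")] <- 0L
  y[ds@label %in% c("pathogenic", "likely_pathogenic")] <- 1L
  ds@yClass <- y
  ds@harmonized <- TRUE
  ds
}

#' Split a dataset into unlabelled and labelled parts
#'
#' The unlabelled part (VUS/unknown assertions) is the training pool of
#' the unsupervised model; the labelled part is held out for validation
#' and testing. Row order is preserved within each part and the two
#' parts partition the input.
#'
#' @param ds A harmonized [VariantDataset-class].
#' @return A list with elements `unlabelled` and `labelled`.
#' @export
splitByLabelStatus <- function(ds) {
  stopifnot(is(ds, "VariantDataset"))
  if (!ds@harmonized) ds <- harmonizeLabels(ds)
  unl <- which(is.na(ds@yClass))
  lab <- which(!is.na(ds@yClass))
  if (!length(unl)) {
    warning("no unlabelled variants: unsupervised training is impossible on this table",
            call. = FALSE)
  }
  list(unlabelled = ds[unl], labelled = ds[lab])
}

#' Stratified validation/test partition of labelled variants
#'
#' Splits labelled variants into a validation set and a test set of
#' near-equal size, sampling benign and pathogenic variants with equal
#' probability into each set (each class is split as evenly as
#' possible). When a class has an odd count the extra record goes to the
#' validation set first, alternating for subsequent odd classes so the
#' total sizes differ by at most one.
#'
#' @param labelled A harmonized [VariantDataset-class] containing both
#'   classes.
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return A list with elements `validation` and `test`.
#' @export
partitionValidationTest <- function(labelled, seed = 1L) {
  stopifnot(is(labelled, "VariantDataset"))
  if (!labelled@harmonized) labelled <- harmonizeLabels(labelled)
  y <- labelled@yClass
  if (anyNA(y)) stop("partition requires fully labelled input", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("stratified partition requires both classes present", call. = FALSE)
  }
  set.seed(as.integer(seed))
  val_idx <- integer(0)
  extra_to_validation <- TRUE
  for (cls in c(0L, 1L)) {
    ids <- which(y == cls)
    ids <- ids[sample.int(length(ids))]
    n_c <- length(ids)
    n_val <- n_c %/% 2L
    if (n_c %% 2L == 1L) {
      if (extra_to_validation) n_val <- n_val + 1L
      extra_to_validation <- !extra_to_validation
    }
    val_idx <- c(val_idx, ids[seq_len(n_val)])
  }
  val_idx <- sort(val_idx)
  test_idx <- setdiff(seq_along(y), val_idx)
  list(validation = labelled[val_idx], test = labelled[test_idx])
}

#' Write per-variant predictions to CSV
#'
#' Writes `variant_id`, per-class mean posterior-predictive
#' probabilities, the final label and the tie flag. Probabilities are
#' written at full precision (round-trips at well over 6 significant
#' digits).
#'
#' @param ds The classified [VariantDataset-class].
#' @param result The aligned [ClassificationResult-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(ds, result, path) {
  stopifnot(is(ds, "VariantDataset"), is(result, "ClassificationResult"))
  if (nrow(ds@scores) != length(result@label)) {
    stop("result is not aligned with the dataset (row count mismatch)",
         call. = FALSE)
  }
  out <- data.frame(
    variant_id = ds@variantId,
    prob_benign = format(1 - result@probPathogenic, digits = 15, scientific = FALSE),
    prob_pathogenic = format(result@probPathogenic, digits = 15, scientific = FALSE),
    label = result@label,
    tie = result@tie,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
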
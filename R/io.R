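#' Read a spatial dataset from a delimited text file
#'
#' Reads a TSV/CSV table with a header row holding, at minimum, two
#' coordinate columns, a ground-truth column, and a predicted-cluster
#' column. Column names are resolved through `column_map`, so files with
#' arbitrary headers can be ingested without renaming.
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named character vector mapping the roles
#'   `x`, `y`, `truth`, `pred` (and optionally `spot_id`) to column names in
#'   the file. Roles omitted from the map fall back to their own name.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A validated [spatial_dataset()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("x\ty\ttruth\tpred",
#'              "0\t0\tA\t1", "1\t0\tA\t1", "0\t1\tB\t2", "1\t1\tB\t2"), tf)
#' d <- read_spatial_table(tf)
#' d$n
#' @export
read_spatial_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  roles <- c(x = "x", y = "y", truth = "truth", pred = "pred",
             spot_id = "spot_id")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(roles))
    if (length(bad)) {
      stop("unknown column_map roles: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    roles[names(column_map)] <- column_map
  }
  for (role in c("x", "y", "truth", "pred")) {
    if (!roles[[role]] %in% names(tab)) {
      stop("configuration error: required column '", roles[[role]],
           "' (role ", role, ") not found in ", path, call. = FALSE)
    }
  }
  parse_num <- function(col, role) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("parse error: non-numeric value '", tab[[col]][bad[1]],
           "' in column '", col, "' (role ", role, ") at data row ", bad[1],
           call. = FALSE)
    }
    v
  }
  coords <- cbind(parse_num(roles[["x"]], "x"), parse_num(roles[["y"]], "y"))
  ids <- if (roles[["spot_id"]] %in% names(tab)) {
    tab[[roles[["spot_id"]]]]
  } else NULL
  spatial_dataset(coords,
                  true_labels = tab[[roles[["truth"]]]],
                  pred_labels = tab[[roles[["pred"]]]],
                  spot_ids = ids)
}

#' Write a spatial dataset to a delimited text file
#'
#' Inverse of [read_spatial_table()]: writes `spot_id, x, y, truth, pred`
#' with the original label names, so a read-back reproduces coordinates,
#' labels, and identifiers exactly.
#'
#' @param dataset A [spatial_dataset()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_spatial_table <- function(dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "spatial_dataset"))
  tab <- data.frame(
    spot_id = dataset$spot_ids,
    x = dataset$coords[, 1],
    y = dataset$coords[, 2],
    truth = dataset$true_levels[dataset$true_codes],
    pred = dataset$pred_levels[dataset$pred_codes],
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach an expression matrix to a spatial dataset
#'
#' Reads a spots x genes expression matrix, either as a dense delimited
#' table (first column = spot identifiers when non-numeric) or as a sparse
#' MatrixMarket triplet with a sidecar file of row identifiers (one per
#' line). Rows are reordered to match `dataset$spot_ids`.
#'
#' @param path Path to the expression file.
#' @param dataset The [spatial_dataset()] to attach to.
#' @param format `"auto"` (default; `.mtx` extension selects MatrixMarket),
#'   `"dense"`, or `"mtx"`.
#' @param row_ids_path Sidecar text file of row identifiers, required for
#'   MTX input; optional for dense input without an id column.
#' @return The dataset with `$expression` attached.
#' @export
read_expression <- function(path, dataset, format = c("auto", "dense", "mtx"),
                            row_ids_path = NULL) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "mtx") {
    if (is.null(row_ids_path)) {
      stop("MTX expression input requires `row_ids_path` (one spot id per line)",
           call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    ids <- readLines(row_ids_path)
  } else {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
    first_num <- suppressWarnings(as.numeric(tab[[1]]))
    if (anyNA(first_num)) {  # first column holds identifiers
      ids <- as.character(tab[[1]])
      m <- as.matrix(tab[, -1, drop = FALSE])
    } else {
      ids <- if (is.null(row_ids_path)) dataset$spot_ids else
        readLines(row_ids_path)
      m <- as.matrix(tab)
    }
  }
  if (nrow(m) != dataset$n) {
    stop("expression matrix has ", nrow(m), " rows but the dataset has ",
         dataset$n, " spots", call. = FALSE)
  }
  if (length(ids) != nrow(m)) {
    stop("row identifier count (", length(ids),
         ") does not match expression rows (", nrow(m), ")", call. = FALSE)
  }
  ord <- match(dataset$spot_ids, ids)
  if (anyNA(ord)) {
    stop("expression row identifiers do not cover all spot_ids (first missing: ",
         dataset$spot_ids[which(is.na(ord))[1]], ")", call. = FALSE)
  }
  m <- m[ord, , drop = FALSE]
  if (any(m < 0)) stop("expression entries must be nonnegative", call. = FALSE)
  spatial_dataset(dataset$coords,
                  true_labels = dataset$true_levels[dataset$true_codes],
                  pred_labels = dataset$pred_levels[dataset$pred_codes],
                  expression = m,
                  spot_ids = dataset$spot_ids)
}

#' Read a per-class-pair severity cost table
#'
#' Reads a small CSV with columns `true_class, pred_class, cost` giving the
#' severity cost of predicting `pred_class` for a spot whose truth is
#' `true_class` (classes named in the ground-truth alphabet). Concordant
#' pairs left out of the table default to cost 1.
#'
#' @param path CSV file path.
#' @return A data frame with character `true_class`, `pred_class`, and
#'   numeric positive `cost`.
#' @export
read_cost_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  need <- c("true_class", "pred_class", "cost")
  if (!all(need %in% names(tab))) {
    stop("cost table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$true_class <- as.character(tab$true_class)
  tab$pred_class <- as.character(tab$pred_class)
  tab$cost <- as.numeric(tab$cost)
  if (any(!is.finite(tab$cost)) || any(tab$cost <= 0)) {
    stop("costs must be positive finite numbers", call. = FALSE)
  }
  tab
}

#' Assemble an evaluation report
#'
#' @param score Discrepancy score in `[0, 2]`.
#' @param terms Named or unnamed numeric vector of the three MMD terms
#'   (within-truth, within-clustering, cross); must satisfy
#'   `score = terms[1] + terms[2] - terms[3]` up to 1e-9.
#' @param config Resolved configuration list echoed into the report.
#' @param benchmarks Optional named numeric vector of benchmark metric
#'   scores.
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(score, terms, config = list(),
                              benchmarks = NULL) {
  stopifnot(is.numeric(score), length(score) == 1L, is.finite(score))
  stopifnot(is.numeric(terms), length(terms) == 3L)
  if (abs(score - (terms[1] + terms[2] - terms[3])) > 1e-9) {
    stop("score must equal terms[1] + terms[2] - terms[3]", call. = FALSE)
  }
  structure(list(
    score = unname(score),
    terms = list(within_truth = unname(terms[1]),
                 within_clustering = unname(terms[2]),
                 cross = unname(terms[3])),
    config = config,
    benchmarks = if (is.null(benchmarks)) NULL else as.list(benchmarks)
  ), class = "evaluation_report")
}

#' Write an evaluation report as JSON
#'
#' @param report An [evaluation_report()].
#' @param path Output path; the parent directory must be writable.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  ok <- tryCatch({
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("I/O error writing report to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Read back a JSON evaluation report
#'
#' @param path Path written by [write_report()].
#' @return An `evaluation_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  evaluation_report(score = as.numeric(x$score),
                    terms = as.numeric(c(x$terms$within_truth,
                                         x$terms$within_clustering,
                                         x$terms$cross)),
                    config = x$config,
                    benchmarks = x$benchmarks)
}
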
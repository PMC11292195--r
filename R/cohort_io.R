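# Canonical survival endpoint labels accepted throughout the package.
ENDPOINT_LABELS <- c("OS", "LRFS", "MFS", "DSS")

#' Validate an abundance matrix
#'
#' An abundance matrix is a plain numeric matrix of log2-normalised
#' intensities with proteins as rows and samples as columns; missing
#' measurements are `NA`. Row and column names must be present and unique,
#' and every non-missing value must be finite.
#'
#' @param x numeric matrix, proteins x samples.
#' @return `x`, invisibly, after validation.
#' @export
validate_abundance <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance matrix must be a numeric matrix (proteins x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance matrix must have protein row names and sample column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate protein identifiers in abundance matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers in abundance matrix")
  if (any(!is.finite(x) & !is.na(x)))
    stop("abundance values must be finite where not missing")
  invisible(x)
}

#' Read a protein abundance matrix from TSV
#'
#' Dialect: tab-separated, first column the protein symbol, remaining
#' columns one per sample. Missing values are encoded as empty cells or
#' `NA`. Values are log2-normalised intensities.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (proteins x samples) with `NA` for missing cells.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("abundance file must have a protein column plus >=1 sample column: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate protein identifiers in ", path)
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        stop(sprintf("non-numeric abundance cell at row %d, column '%s' in %s",
                     bad[1L], names(vals)[j], path))
      v <- vn
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  validate_abundance(m)
  m
}

#' Write an abundance matrix as TSV
#'
#' Inverse of [read_abundance()]; `NA` cells are written as `NA`.
#'
#' @param x abundance matrix.
#' @param path output path.
#' @export
write_abundance <- function(x, path) {
  validate_abundance(x)
  df <- data.frame(protein = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Comma- or tab-separated table with one row per sample. Required column:
#' `sample_id`. Recognised clinical columns: `subtype`, `grade` (2, 3 or
#' NA), `site`, `depth`, `margins`, `sex`, `performance_status`,
#' `preop_treatment`, `tumor_size` (mm), `age` (years). Survival endpoints
#' are supplied as paired columns `<label>_time` (months) and
#' `<label>_event` (0/1 or TRUE/FALSE) where `<label>` is one of
#' OS, LRFS, MFS, DSS; any other endpoint label is rejected.
#'
#' @param path path to a CSV/TSV file.
#' @return data.frame with a `sample_id` column; event columns coerced to
#'   logical, times numeric.
#' @export
read_clinical <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = TRUE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("clinical table must contain a sample_id column: ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table: ", path)
  time_cols <- grep("_time$", names(df), value = TRUE)
  for (tc in time_cols) {
    lab <- sub("_time$", "", tc)
    if (!lab %in% ENDPOINT_LABELS)
      stop("unknown survival endpoint label '", lab, "' (allowed: ",
           paste(ENDPOINT_LABELS, collapse = ", "), ")")
    ec <- paste0(lab, "_event")
    if (!ec %in% names(df))
      stop("endpoint ", lab, " has a time column but no ", ec, " column")
    tv <- as.numeric(df[[tc]])
    if (any(tv < 0, na.rm = TRUE))
      stop("negative time in column ", tc)
    df[[tc]] <- tv
    df[[ec]] <- as.logical(df[[ec]])
  }
  df
}

#' Write a clinical table
#' @param df clinical data.frame as returned by [read_clinical()].
#' @param path output path (CSV).
#' @export
write_clinical <- function(df, path) {
  out <- df
  ev <- grep("_event$", names(out), value = TRUE)
  for (e in ev) out[[e]] <- as.integer(out[[e]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 60))
    nm <- parts[1L]
    if (nm %in% names(sets)) stop("duplicate gene-set name in GMT: ", nm)
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set in GMT: ", nm)
    sets[[nm]] <- structure(genes, description = parts[2L])
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors (optional `description`
#'   attributes).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- ""
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read cell-track tables
#'
#' CSV dialect of common Fiji tracking-plugin exports: columns `TRACK_ID`,
#' `FRAME`, `POSITION_T` (minutes), `POSITION_X`, `POSITION_Y` (micrometres),
#' and optionally `CONDITION` / `CELL_LINE`. Secondary header rows (rows
#' whose FRAME value is not numeric, as written by some exporters) are
#' skipped. Rows are sorted by frame within track.
#'
#' @param path path to a CSV file.
#' @return data.frame with columns `track_id`, `frame`, `t`, `x`, `y`
#'   (plus `condition`, `cell_line` when present).
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = TRUE,
                        stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "FRAME", "POSITION_T", "POSITION_X", "POSITION_Y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track table missing columns: ", paste(miss, collapse = ", "))
  suppressWarnings(fr <- as.numeric(df$FRAME))
  df <- df[!is.na(fr), , drop = FALSE]   # drop exporter sub-header rows
  out <- data.frame(
    track_id = as.character(df$TRACK_ID),
    frame = as.integer(as.numeric(df$FRAME)),
    t = as.numeric(df$POSITION_T),
    x = as.numeric(df$POSITION_X),
    y = as.numeric(df$POSITION_Y),
    stringsAsFactors = FALSE
  )
  if ("CONDITION" %in% names(df)) out$condition <- as.character(df$CONDITION)
  if ("CELL_LINE" %in% names(df)) out$cell_line <- as.character(df$CELL_LINE)
  if (any(!is.finite(out$x)) || any(!is.finite(out$y)))
    stop("non-finite track positions in ", path)
  if (any(out$t < 0)) stop("negative POSITION_T in ", path)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  dup <- stats::aggregate(frame ~ track_id, out, function(f) anyDuplicated(f) > 0L)
  if (any(dup$frame))
    stop("duplicate frames within track(s): ",
         paste(dup$track_id[dup$frame], collapse = ", "))
  out
}

#' Write a track table in the input CSV dialect
#' @param tracks data.frame as returned by [read_tracks()].
#' @param path output path.
#' @export
write_tracks <- function(tracks, path) {
  out <- data.frame(TRACK_ID = tracks$track_id, FRAME = tracks$frame,
                    POSITION_T = tracks$t, POSITION_X = tracks$x,
                    POSITION_Y = tracks$y, stringsAsFactors = FALSE)
  if (!is.null(tracks$condition)) out$CONDITION <- tracks$condition
  if (!is.null(tracks$cell_line)) out$CELL_LINE <- tracks$cell_line
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a set of result tables plus a JSON run summary
#'
#' Each element of `report` that is a data.frame is written as a TSV named
#' after it (rows ordered as given, columns as given); scalar/list elements
#' are collected into `run_summary.json`. Output is deterministic: files
#' and JSON keys are written in sorted name order.
#'
#' @param report named list of data.frames and scalars.
#' @param dir output directory (created if needed).
#' @return character vector of files written.
#' @export
write_results <- function(report, dir) {
  if (is.null(names(report)) || any(!nzchar(names(report))))
    stop("report elements must be named")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  summ <- list()
  for (nm in sort(names(report))) {
    x <- report[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, f)
    } else {
      summ[[nm]] <- x
    }
  }
  if (length(summ)) {
    f <- file.path(dir, "run_summary.json")
    jsonlite::write_json(summ[sort(names(summ))], f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  written
}
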
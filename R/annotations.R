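# Matrisome / integrin-adhesome catalogs and proteome filtering.

MATRISOME_DIVISIONS <- c("core_matrisome", "matrisome_associated", "adhesome")
CORE_CATEGORIES <- c("collagens", "glycoproteins", "proteoglycans")

#' Load a matrisome/adhesome annotation catalog
#'
#' Reads a delimited catalog with header columns `gene`, `division`,
#' `category` (an optional `aliases` column is carried through but not
#' used for matching). Divisions are `core_matrisome`,
#' `matrisome_associated` and `adhesome`. A gene listed under both a
#' matrisome division and the adhesome is resolved by precedence
#' matrisome > adhesome: the matrisome record is kept and the adhesome
#' membership is retained as the logical `in_adhesome` flag, so the
#' divisions partition the catalog while adhesome composition breakdowns
#' remain possible.
#'
#' @param path path to a CSV/TSV catalog.
#' @return object of class `annotation_db`: a data.frame with columns
#'   `gene`, `division`, `category`, `in_adhesome`, plus attribute
#'   `source_version` (the file name).
#' @export
load_annotation_db <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("gene", "division", "category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation catalog missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("annotation catalog is empty: ", path)
    db <- data.frame(gene = character(0), division = character(0),
                     category = character(0), in_adhesome = logical(0),
                     stringsAsFactors = FALSE)
    return(structure(db, class = c("annotation_db", "data.frame"),
                     source_version = basename(path)))
  }
  bad <- setdiff(unique(df$division), MATRISOME_DIVISIONS)
  if (length(bad))
    stop("unknown division(s): ", paste(bad, collapse = ", "))
  core_bad <- df$division == "core_matrisome" & !df$category %in% CORE_CATEGORIES
  if (any(core_bad))
    stop("core_matrisome records must have category in {",
         paste(CORE_CATEGORIES, collapse = ", "), "}: ",
         paste(unique(df$gene[core_bad]), collapse = ", "))
  # precedence resolution: matrisome divisions beat adhesome for dual genes
  adhes_genes <- unique(df$gene[df$division == "adhesome"])
  keep <- !duplicated(df[c("gene", "division")])
  df <- df[keep, , drop = FALSE]
  split_by_gene <- split(seq_len(nrow(df)), df$gene)
  rows <- vapply(split_by_gene, function(ix) {
    if (length(ix) == 1L) return(ix)
    mat <- ix[df$division[ix] != "adhesome"]
    if (length(mat) > 1L)
      stop("gene '", df$gene[ix[1L]],
           "' listed under two matrisome divisions; catalog is inconsistent")
    if (length(mat) == 1L) mat else ix[1L]
  }, integer(1))
  dual <- vapply(split_by_gene, length, integer(1)) > 1L
  if (any(dual))
    warning(sum(dual), " gene(s) in both matrisome and adhesome catalogs; ",
            "matrisome division retained, adhesome membership kept as flag")
  db <- df[rows, c("gene", "division", "category"), drop = FALSE]
  db$in_adhesome <- db$gene %in% adhes_genes
  db <- db[order(db$gene), , drop = FALSE]
  rownames(db) <- NULL
  message("loaded annotation catalog: ", nrow(db), " genes")
  structure(db, class = c("annotation_db", "data.frame"),
            source_version = basename(path))
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db:", nrow(x), "genes (",
      paste(sprintf("%s=%d", names(table(x$division)), table(x$division)),
            collapse = ", "),
      "); source:", attr(x, "source_version"), "\n")
  invisible(x)
}

#' Filter an abundance matrix to annotated proteins
#'
#' Keeps exactly the rows whose symbol appears in the catalog, preserving
#' the input row order and the full sample set.
#'
#' @param matrix abundance matrix (proteins x samples).
#' @param db an `annotation_db`.
#' @param ignore_case match symbols case-insensitively (default FALSE:
#'   exact, case-sensitive, no alias expansion).
#' @return the filtered abundance matrix.
#' @export
filter_matrix <- function(matrix, db, ignore_case = FALSE) {
  validate_abundance(matrix)
  ids <- rownames(matrix)
  cat_genes <- db$gene
  hit <- if (ignore_case) toupper(ids) %in% toupper(cat_genes) else ids %in% cat_genes
  if (!any(hit))
    warning("no overlap between matrix proteins and annotation catalog")
  matrix[hit, , drop = FALSE]
}

#' Catalog coverage of a proteome matrix
#'
#' For each division (and each division/category pair) reports how many
#' catalog genes were detected in the matrix and the detected fraction.
#'
#' @inheritParams filter_matrix
#' @return list with data.frames `by_division` and `by_category`
#'   (columns `n_detected`, `n_catalog`, `fraction`) and scalar
#'   `n_detected_total`.
#' @export
coverage_stats <- function(matrix, db, ignore_case = FALSE) {
  validate_abundance(matrix)
  ids <- rownames(matrix)
  if (ignore_case) ids <- toupper(ids)
  gene_in <- function(g) (if (ignore_case) toupper(g) else g) %in% ids
  db2 <- db[!duplicated(db$gene), , drop = FALSE]
  det <- gene_in(db2$gene)
  agg <- function(keys) {
    sp <- split(det, keys, drop = TRUE)
    out <- data.frame(
      n_detected = vapply(sp, sum, integer(1)),
      n_catalog = vapply(sp, length, integer(1))
    )
    out$fraction <- ifelse(out$n_catalog > 0, out$n_detected / out$n_catalog, NA_real_)
    out <- cbind(group = names(sp), out)
    rownames(out) <- NULL
    out
  }
  list(
    by_division = agg(db2$division),
    by_category = agg(paste(db2$division, db2$category, sep = "/")),
    n_detected_total = sum(det)
  )
}
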
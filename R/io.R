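#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV file with one header row and one identifier column into a
#' [GeneExpression-class] object in the canonical samples-by-genes
#' orientation. A JSON sidecar (`<path>.json`), when present, restores the
#' domain, units, applied transforms and tissue labels written by
#' [writeExpression()].
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param orientation `"samples_in_rows"` or `"genes_in_rows"`; the latter is
#'   transposed on read.
#' @param domain cohort domain, overridden by the sidecar if one exists.
#' @param units expression units, overridden by the sidecar.
#' @return a [GeneExpression-class] object.
#' @details Duplicate identifiers and non-numeric cells are hard errors that
#'   name the offending row or column; missing values are rejected rather
#'   than imputed.
#' @export
readExpression <- function(path,
                           orientation = c("samples_in_rows",
                                           "genes_in_rows"),
                           domain = c("source", "target"),
                           units = "unknown") {
  orientation <- match.arg(orientation)
  domain <- match.arg(domain)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed file (need id column + data): ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  numdf <- df[, -1, drop = FALSE]
  nonnum <- !vapply(numdf, is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric values in column(s): ",
         paste(colnames(numdf)[nonnum], collapse = ", "))
  m <- as.matrix(numdf)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicated identifier(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (orientation == "genes_in_rows") m <- t(m)

  tissue <- NULL
  transforms <- character()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$domain)) domain <- meta$domain
    if (!is.null(meta$units)) units <- meta$units
    if (!is.null(meta$transforms)) transforms <- as.character(meta$transforms)
    if (!is.null(meta$tissue))
      tissue <- as.character(meta$tissue)[match(rownames(m),
                                                names(meta$tissue))]
    if (!is.null(meta$tissue) && is.null(names(meta$tissue)) &&
        length(meta$tissue) == nrow(m))
      tissue <- as.character(meta$tissue)
  }
  geneExpression(m, domain = domain, tissue = tissue, units = units,
                 transforms = transforms)
}

#' Write an expression matrix with a JSON provenance sidecar
#'
#' Writes samples in rows, genes in columns, a header row and an `sample_id`
#' identifier column, plus `<path>.json` recording domain, units, applied
#' transforms and tissue labels so that [readExpression()] round-trips.
#'
#' @param x a [GeneExpression-class] object.
#' @param path output file path (`.csv` for comma-separated).
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  stopifnot(methods::is(x, "GeneExpression"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- exprValues(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  meta <- list(domain = domainOf(x), units = S4Vectors::metadata(x)$units,
               transforms = transformsOf(x))
  ti <- tissueOf(x)
  if (!is.null(ti)) meta$tissue <- as.list(setNames(ti, sampleIds(x)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Filter lowly expressed target genes and log-transform
#'
#' Removes genes that are not expressed (value below `exprThreshold`) in at
#' least `fraction` of the target samples, then transforms the survivors
#' elementwise to `log2(value + 0.1)`. Applies only to the raw
#' (FPKM-like) target cohort; the source cohort is assumed already
#' platform-normalized and is never filtered this way.
#'
#' @param x a target-domain [GeneExpression-class] in raw FPKM-like units.
#' @param exprThreshold expression below this counts as "not expressed"
#'   (strict `<`); default 1.
#' @param fraction minimum fraction of samples that must be unexpressed for
#'   removal (`>=`, i.e. "at least"); default 0.9.
#' @return the filtered, log2-transformed [GeneExpression-class].
#' @export
filterTargetGenes <- function(x, exprThreshold = 1.0, fraction = 0.9) {
  stopifnot(methods::is(x, "GeneExpression"))
  if ("log2" %in% transformsOf(x))
    stop("input is already log-transformed; refusing to filter/transform twice")
  v <- exprValues(x)
  unexpressed <- colMeans(v < exprThreshold)
  keep <- unexpressed < fraction
  if (!any(keep)) stop("no genes survive the expression filter")
  v <- log2(v[, keep, drop = FALSE] + 0.1)
  geneExpression(v, domain = domainOf(x), tissue = tissueOf(x),
                 units = "log2",
                 transforms = c(transformsOf(x), "expression_filter", "log2"))
}

#' Restrict two cohorts to their shared genes
#'
#' Intersects the gene sets of a source and a target cohort and returns both
#' restricted to the shared genes in identical lexicographically sorted
#' order, so downstream matrices are column-aligned.
#'
#' @param source,target [GeneExpression-class] objects.
#' @return a list with elements `source` and `target`.
#' @export
intersectGenes <- function(source, target) {
  stopifnot(methods::is(source, "GeneExpression"),
            methods::is(target, "GeneExpression"))
  shared <- sort(intersect(geneIds(source), geneIds(target)))
  if (!length(shared)) stop("no genes shared between the two cohorts")
  list(source = source[shared, ], target = target[shared, ])
}

#' Recategorize clinical drug responses to sensitive/resistant
#'
#' Maps RECIST-style clinical drug response categories to a binary label:
#' complete and partial response become `"sensitive"`; stable disease and
#' (clinically) progressive disease become `"resistant"`. Matching is
#' tolerant of case, surrounding whitespace and `_`/`-` separators.
#'
#' @param rawLabels character vector of clinical response categories.
#' @return character vector in `{"sensitive", "resistant"}`, preserving
#'   names.
#' @export
encodeCdr <- function(rawLabels) {
  norm <- tolower(trimws(gsub("[_-]+", " ", as.character(rawLabels))))
  norm <- gsub("\\s+", " ", norm)
  map <- c("complete response" = "sensitive",
           "partial response" = "sensitive",
           "stable disease" = "resistant",
           "progressive disease" = "resistant",
           "clinically progressive disease" = "resistant")
  out <- unname(map[norm])
  if (anyNA(out))
    stop("unrecognized clinical response label(s): ",
         paste(unique(rawLabels[is.na(out)]), collapse = ", "))
  names(out) <- names(rawLabels)
  out
}
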
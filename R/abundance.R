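#' Validate an abundance table
#'
#' An abundance table is a plain numeric matrix of nonnegative counts or
#' relative abundances with samples in rows and taxa in columns, both
#' dimensions carrying unique identifiers as dimnames.
#'
#' @param x numeric matrix, samples x taxa.
#' @return `x`, invisibly, after validation.
#' @export
validate_abundance <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance table must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance table must have sample (row) and taxon (column) identifiers")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x) || any(!is.finite(x)))
    stop("abundance table contains missing or non-finite values")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("abundance table needs at least 2 samples and 2 taxa")
  invisible(x)
}

#' Read an abundance table from a delimited file
#'
#' Reads a TSV/CSV (or JSON BIOM, if the biomformat package is available)
#' table of counts or relative abundances. Orientation is always explicit:
#' silent transposition is a classic source of error in microbiome work, so
#' no auto-guessing is attempted.
#'
#' @param path file path. Extension `.csv` selects comma separation,
#'   `.biom` the BIOM format; anything else is read as tab-separated.
#' @param orientation `"samples-in-rows"` or `"taxa-in-rows"`. The returned
#'   matrix is always samples x taxa.
#' @param sep optional field separator overriding the extension heuristic.
#' @return numeric matrix, samples x taxa (see [validate_abundance()]).
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples-in-rows", "taxa-in-rows"),
                                 sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples in BIOM
    m <- t(m)
    validate_abundance(m)
    return(m)
  }
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop(sprintf("non-numeric value in column '%s', row '%s'",
                   colnames(df)[j], rownames(df)[bad]))
    }
  }
  m <- as.matrix(df)
  if (orientation == "taxa-in-rows") m <- t(m)
  validate_abundance(m)
  m
}

#' Write an abundance table to a delimited file
#'
#' @param x abundance matrix, samples x taxa.
#' @param path output path; `.csv` selects comma separation.
#' @param orientation orientation to write in.
#' @export
write_abundance_table <- function(x, path,
                                  orientation = c("samples-in-rows", "taxa-in-rows")) {
  orientation <- match.arg(orientation)
  validate_abundance(x)
  out <- if (orientation == "taxa-in-rows") t(x) else x
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  colnames(df)[1] <- if (orientation == "taxa-in-rows") "taxon_id" else "sample_id"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' First column (or a column named `sample_id`) is taken as the sample
#' identifier. Dichotomous columns passed to the mediation machinery must be
#' coded 0/1.
#'
#' @param path TSV/CSV file path.
#' @param sep optional separator override.
#' @return data.frame with sample identifiers as row names.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  idcol <- if ("sample_id" %in% colnames(df)) "sample_id" else colnames(df)[1]
  if (anyDuplicated(df[[idcol]]))
    stop("duplicate sample identifiers in metadata")
  rownames(df) <- df[[idcol]]
  df[[idcol]] <- NULL
  df
}

#' Align an abundance table and metadata by sample identifier
#'
#' Intersects the two sample sets; order is never assumed. Dropped samples
#' are reported via a message.
#'
#' @param x abundance matrix, samples x taxa.
#' @param meta metadata data.frame with sample identifiers as row names.
#' @return list with elements `abundance` and `metadata`, row-aligned.
#' @export
align_samples <- function(x, meta) {
  common <- intersect(rownames(x), rownames(meta))
  if (length(common) < 2)
    stop("fewer than 2 samples shared between abundance table and metadata")
  dropped <- setdiff(union(rownames(x), rownames(meta)), common)
  if (length(dropped))
    message("dropping ", length(dropped), " unmatched sample(s): ",
            paste(utils::head(dropped, 10), collapse = ", "))
  list(abundance = x[common, , drop = FALSE],
       metadata = meta[common, , drop = FALSE])
}
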
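#' Read an abundance matrix from TSV
#'
#' Reads a tab-separated table with one identifier column followed by numeric
#' abundance columns. Empty cells and the sentinels `NA`, `ND` become missing
#' values; any other non-numeric cell is a parse error naming its row and
#' column. By default rows are metabolites and columns samples; pass
#' `orientation = "samples"` for transposed input.
#'
#' @param path file path.
#' @param orientation `"metabolites"` (rows are metabolites, the default) or
#'   `"samples"` (rows are samples; the matrix is transposed on read).
#' @param log_scale logical flag stored on the returned matrix.
#' @return an [ion_matrix].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, orientation = c("metabolites", "samples"),
                        log_scale = FALSE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (ncol(raw) < 2L)
    stop("matrix file needs an id column plus at least one value column: ", path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate id '", ids[duplicated(ids)][1L], "' in ", path)
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- .parse_numeric_cells(vals, ids)
  rownames(num) <- ids
  if (orientation == "samples") num <- t(num)
  ion_matrix(num, log_scale = log_scale)
}

# shared numeric-cell parser: "" / NA / ND -> missing, otherwise must parse
.parse_numeric_cells <- function(vals, row_ids) {
  miss <- vals == "" | vals == "NA" | vals == "ND" | is.na(vals)
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !miss, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("malformed numeric cell '", vals[bad[1L, 1L], bad[1L, 2L]],
         "' at row '", row_ids[bad[1L, 1L]], "', column '",
         colnames(vals)[bad[1L, 2L]], "'")
  }
  num[miss] <- NA_real_
  num
}

#' Write an abundance matrix to TSV
#'
#' Inverse of [read_matrix()]: metabolites as rows, missing values as empty
#' cells, full double precision so a write/read round trip is bit-identical.
#'
#' @param x an [ion_matrix].
#' @param path file path.
#' @export
write_matrix <- function(x, path) {
  m <- format(.values(x), digits = 17, trim = TRUE)
  m[is.na(.values(x))] <- ""
  df <- data.frame(metabolite_id = rownames(x), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MetaboLights metabolite assignment file (MAF)
#'
#' Parses the tab-separated MAF dialect used by MetaboLights studies:
#' metabolite identification columns (e.g. `database_identifier`,
#' `metabolite_identification`, `smallmolecule_abundance_*`) followed by one
#' abundance column per sample. Abundance cells that do not parse as numbers
#' (including `ND`) become missing values.
#'
#' @param path file path to the MAF.
#' @return a list with elements `matrix` (an [ion_matrix]) and `annotation`
#'   (data.frame with columns `metabolite_id`, `name`, `superpathway`,
#'   `subpathway`, `hmdb_id`, `pubchem_id`).
#' @export
read_maf <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (!"metabolite_identification" %in% names(raw))
    stop("not a metabolite assignment file: mandatory header ",
         "'metabolite_identification' missing in ", path)
  id_cols <- c("database_identifier", "chemical_formula", "smiles", "inchi",
               "metabolite_identification", "mass_to_charge", "fragmentation",
               "modifications", "charge", "retention_time", "taxid", "species",
               "database", "database_version", "reliability", "uri",
               "search_engine", "search_engine_score",
               "smallmolecule_abundance_sub",
               "smallmolecule_abundance_stdev_sub",
               "smallmolecule_abundance_std_error_sub",
               "superpathway", "subpathway", "hmdb_id", "pubchem_id")
  sample_cols <- setdiff(names(raw), id_cols)
  if (!length(sample_cols))
    stop("MAF has no per-sample abundance columns: ", path)
  name <- raw$metabolite_identification
  db <- if ("database_identifier" %in% names(raw)) raw$database_identifier else ""
  ids <- ifelse(is.na(db) | db == "", name, db)
  if (anyDuplicated(ids))
    stop("duplicate metabolite id '", ids[duplicated(ids)][1L], "' in ", path)
  vals <- as.matrix(raw[, sample_cols, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  rownames(num) <- ids
  grab <- function(col) {
    v <- if (col %in% names(raw)) raw[[col]] else rep("", nrow(raw))
    v[is.na(v)] <- ""
    v
  }
  hmdb <- grab("hmdb_id")
  no_hmdb <- hmdb == "" & grepl("^HMDB", ids)
  hmdb[no_hmdb] <- ids[no_hmdb]
  sup <- grab("superpathway")
  sup[sup == ""] <- "unknown"
  ann <- data.frame(metabolite_id = ids, name = name,
                    superpathway = sup, subpathway = grab("subpathway"),
                    hmdb_id = hmdb, pubchem_id = grab("pubchem_id"),
                    stringsAsFactors = FALSE)
  list(matrix = ion_matrix(num), annotation = ann)
}

#' Read the sample, trait or annotation tables
#'
#' Thin typed readers for the package's TSV formats. `read_samples()`
#' validates the table with [validate_samples()]; `read_traits()` checks
#' subject uniqueness and coerces trait columns to numeric.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_samples <- function(path) {
  meta <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE, na.strings = NULL)
  for (col in c("subject_id", "group", "timepoint"))
    if (col %in% names(meta)) meta[[col]][is.na(meta[[col]])] <- ""
  validate_samples(meta)
  meta
}

#' @rdname read_samples
#' @export
read_traits <- function(path) {
  tr <- utils::read.delim(path, check.names = FALSE)
  if (!"subject_id" %in% names(tr))
    stop("traits table lacks a subject_id column")
  if (anyDuplicated(tr$subject_id))
    stop("duplicate subject_id in traits table")
  for (col in setdiff(names(tr), "subject_id")) {
    tr[[col]] <- as.numeric(tr[[col]])
    if (any(is.infinite(tr[[col]])))
      stop("non-finite value in trait '", col, "'")
  }
  tr
}

#' Write a result table to TSV
#'
#' Deterministic serialization for all result tables: fixed column order (as
#' given), no quoting, full double precision, missing values as `NA`.
#'
#' @param records data.frame with a stable column schema.
#' @param path file path.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- format(out[[col]], digits = 17, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
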
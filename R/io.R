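# TSV schemas: matrices are written with row ids in a first column named
# `id`; tables are plain header + rows. All readers validate headers.

#' Write a numeric matrix as TSV (row ids in column `id`)
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table::data.table(id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(as.matrix(m)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a numeric matrix from TSV written by [write_matrix_tsv()]
#' @param path input path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (names(dt)[1] != "id") stop("malformed matrix TSV (expect first column 'id'): ", path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a TSV table, checking required columns
#' @param path input path.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
read_table_tsv <- function(path, required = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!is.null(required) && !all(required %in% names(df)))
    stop("TSV ", path, " is missing column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  df
}

#' Read a sample sheet TSV
#' @param path TSV with sample_id, family_id, age, sex, center, smoking, logTG.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  read_table_tsv(path, c("sample_id", "age", "sex", "center", "smoking"))
}

#' Write a simulated study to a directory of TSV files
#'
#' Files: `pre_betas.tsv`, `post_betas.tsv`, `sample_sheet.tsv`,
#' `kinship.tsv`, `probe_annotation.tsv`, `planted_modules.tsv`.
#'
#' @param study a `cometh_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "cometh_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(study$pre_betas, file.path(dir, "pre_betas.tsv"))
  write_matrix_tsv(study$post_betas, file.path(dir, "post_betas.tsv"))
  write_table_tsv(study$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_matrix_tsv(study$kinship, file.path(dir, "kinship.tsv"))
  write_table_tsv(study$probe_annotation, file.path(dir, "probe_annotation.tsv"))
  write_table_tsv(study$planted_modules, file.path(dir, "planted_modules.tsv"))
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#' @param dir directory path.
#' @return a `cometh_study` (without config).
#' @export
read_study <- function(dir) {
  structure(list(
    pre_betas = read_matrix_tsv(file.path(dir, "pre_betas.tsv")),
    post_betas = read_matrix_tsv(file.path(dir, "post_betas.tsv")),
    sample_sheet = read_sample_sheet(file.path(dir, "sample_sheet.tsv")),
    kinship = read_matrix_tsv(file.path(dir, "kinship.tsv")),
    probe_annotation = read_table_tsv(file.path(dir, "probe_annotation.tsv"),
                                      c("probe_id", "gene")),
    planted_modules = if (file.exists(file.path(dir, "planted_modules.tsv")))
      read_table_tsv(file.path(dir, "planted_modules.tsv"), c("probe_id", "module"))
    else NULL
  ), class = "cometh_study")
}
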
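# Plain-text readers/writers for every intermediate the pipeline exchanges,
# in the schemas the generators emit.

#' Write / read an expression dataset as TSV
#'
#' Genes in rows, samples in columns, first column `gene`. Subtype labels,
#' when present, travel in `# subtype:<sample>=<label>` header comments so a
#' round trip preserves ground truth.
#'
#' @param x An [expr_dataset()].
#' @param path Output file.
#' @return `path`, invisibly (writer); an [expr_dataset()] (reader).
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_dataset"))
  header <- c(
    paste0("# dataset_id=", x$dataset_id),
    if (!is.null(x$subtypes)) {
      paste0("# subtype:", names(x$subtypes), "=", x$subtypes)
    }
  )
  writeLines(header, path)
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  dataset_id <- sub("^# dataset_id=", "", grep("^# dataset_id=", meta, value = TRUE))
  sub_lines <- grep("^# subtype:", meta, value = TRUE)
  subtypes <- NULL
  if (length(sub_lines) > 0) {
    kv <- strsplit(sub("^# subtype:", "", sub_lines), "=", fixed = TRUE)
    subtypes <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene
  expr_dataset(if (length(dataset_id)) dataset_id else "unknown",
               values, subtypes)
}

#' Write / read a long viability plate as CSV
#'
#' Columns: `cell_line`, `drug`, `concentration_M`, `replicate`, `signal`,
#' `control_signal`, `blank_signal`.
#'
#' @param plate Plate tibble as from [simulate_dose_response()].
#' @param path Output file.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_plate_csv <- function(plate, path) {
  readr::write_csv(as_tibble(plate), path)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a dose matrix as long CSV
#'
#' Columns: `rowdrug_conc_M`, `coldrug_conc_M`, `inhibition_pct`, with the
#' identities in `# key=value` header comments.
#'
#' @param m A [dose_matrix()].
#' @param path Output file.
#' @return `path`, invisibly (writer); a [dose_matrix()] (reader).
#' @export
write_dose_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "dose_matrix"))
  writeLines(c(
    paste0("# cell_line=", m$cell_line),
    paste0("# drug_row=", m$drug_row),
    paste0("# drug_col=", m$drug_col)
  ), path)
  df <- data.frame(
    rowdrug_conc_M = rep(m$row_concs, times = length(m$col_concs)),
    coldrug_conc_M = rep(m$col_concs, each = length(m$row_concs)),
    inhibition_pct = as.vector(m$inhibition)
  )
  suppressWarnings(utils::write.table(df, path, sep = ",", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_dose_matrix_csv
#' @export
read_dose_matrix_csv <- function(path) {
  meta <- grep("^#", readLines(path), value = TRUE)
  get <- function(key) sub(paste0("^# ", key, "="), "",
                           grep(paste0("^# ", key, "="), meta, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#")
  row_concs <- sort(unique(df$rowdrug_conc_M))
  col_concs <- sort(unique(df$coldrug_conc_M))
  inh <- matrix(NA_real_, length(row_concs), length(col_concs))
  inh[cbind(match(df$rowdrug_conc_M, row_concs),
            match(df$coldrug_conc_M, col_concs))] <- df$inhibition_pct
  dose_matrix(inh, row_concs, col_concs,
              drug_row = get("drug_row"), drug_col = get("drug_col"),
              cell_line = get("cell_line"))
}

#' Write a run manifest
#'
#' Serializes the seed and full configuration as `# key=value` lines so any
#' stage can be replayed from its inputs.
#'
#' @param config A [sim_config()] or [pipeline_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  flat <- unlist(config)
  writeLines(c(
    paste0("# basalscreen manifest, package ",
           as.character(utils::packageVersion("basalscreen"))),
    paste0(names(flat), "=", vapply(flat, format, ""))
  ), path)
  invisible(path)
}
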
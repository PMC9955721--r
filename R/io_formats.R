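# Reader/writer for the competition-style ASCII PSD feature dialect:
# one PSD sample per line, 96 whitespace-separated numeric fields, plus an
# optional 97th field carrying the task-label code.  No header line.

N_PSD_FEATURES <- 96L

#' Read an ASCII PSD feature file
#'
#' Parses the whitespace-separated ASCII dialect used for precomputed PSD
#' features (BCI competition III dataset V style): 96 numeric fields per row,
#' plus a 97th label field when `label_column_present`. Any run of whitespace
#' is accepted as a separator. Row order is preserved.
#'
#' @param path Path to the file.
#' @param label_column_present Logical; does each row end with a task-label code?
#' @param label_map Named integer vector mapping canonical class names to the
#'   file's label codes (default [default_label_map()], historically 2/3/7).
#' @param subject_id,session_id Identifiers attached to the result.
#' @return A [psd_feature_matrix()]; `labels` is `NULL` when no label column.
#' @export
read_psd_ascii <- function(path, label_column_present = TRUE,
                           label_map = default_label_map(),
                           subject_id = NA_character_, session_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  want <- N_PSD_FEATURES + as.integer(label_column_present)
  if (length(lines) == 0) {
    m <- psd_feature_matrix(matrix(numeric(0), 0, N_PSD_FEATURES),
                            labels = if (label_column_present) character(0),
                            subject_id = subject_id, session_id = session_id)
    attr(m, "label_map") <- label_map
    return(m)
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  widths <- lengths(toks)
  if (any(widths != want)) {
    i <- which(widths != want)[1]
    stop("format error at row ", i, ": expected ", want,
         " fields, found ", widths[i])
  }
  flat <- unlist(toks, use.names = FALSE)
  num <- suppressWarnings(as.numeric(flat))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1]
    stop("parse error at row ", ceiling(bad / want), ", field ",
         (bad - 1) %% want + 1, ": non-numeric value '", flat[bad], "'")
  }
  mat <- matrix(num, ncol = want, byrow = TRUE)
  labels <- NULL
  if (label_column_present) {
    codes <- as.integer(mat[, want])
    mat <- mat[, seq_len(N_PSD_FEATURES), drop = FALSE]
    idx <- match(codes, label_map)
    if (anyNA(idx)) {
      stop("unknown task-label code(s): ",
           paste(unique(codes[is.na(idx)]), collapse = ", "),
           " (label_map covers ", paste(label_map, collapse = ", "), ")")
    }
    labels <- names(label_map)[idx]
  }
  m <- psd_feature_matrix(mat, labels, subject_id = subject_id,
                          session_id = session_id)
  attr(m, "label_map") <- label_map
  m
}

#' Write an ASCII PSD feature file
#'
#' Inverse of [read_psd_ascii()]: one line per PSD sample, 96 fields (plus the
#' label code when `with_labels`), single-space separated, no header. Numeric
#' fields are formatted with `%.10g`, which makes
#' `read_psd_ascii(write_psd_ascii(m))` the identity on values to ~10
#' significant digits.
#'
#' @param m A [psd_feature_matrix()].
#' @param path Output path.
#' @param with_labels Logical; append the label code column (requires labels).
#' @param label_map Named integer vector, canonical class name -> file code.
#' @return `path`, invisibly.
#' @export
write_psd_ascii <- function(m, path, with_labels = !is.null(m$labels),
                            label_map = default_label_map()) {
  stopifnot(inherits(m, "psd_feature_matrix"))
  if (with_labels && is.null(m$labels)) stop("matrix has no labels to write")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  if (nrow(m$values) == 0) return(invisible(path))
  txt <- apply(m$values, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  if (with_labels) {
    codes <- label_map[m$labels]
    if (anyNA(codes)) stop("labels not covered by label_map")
    txt <- paste(txt, codes)
  }
  writeLines(txt, con)
  invisible(path)
}
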
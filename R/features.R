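#' Build a deep-spectrum feature set
#'
#' A feature set is a tibble with one row per scalogram: label columns
#' `subject`, `group` (`"tinnitus"`/`"control"`), `session` (`"S1"`/`"S2"`),
#' and feature columns `f0001`, `f0002`, ... holding the pooled
#' deep-spectrum vector of that scalogram (1280 values for the default
#' backbone).
#'
#' @param x Numeric matrix (rows = instances) or list of equal-length
#'   numeric vectors.
#' @param subject,group,session Label vectors recycled to the number of rows.
#' @return A tibble of class `feature_set`.
#' @export
#' @examples
#' fs <- feature_set(matrix(rnorm(8), 2), subject = c("s1", "s2"),
#'                   group = "tinnitus", session = "S1")
#' feature_matrix(fs)
feature_set <- function(x, subject, group, session) {
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1L) {
      abort(sprintf("ragged feature vectors: lengths %s.",
                    paste(unique(lens), collapse = ", ")))
    }
    x <- do.call(rbind, x)
  }
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("features must be numeric.")
  d <- ncol(x)
  colnames(x) <- sprintf("f%04d", seq_len(d))
  out <- tibble(
    subject = as.character(rep_len(subject, nrow(x))),
    group = as.character(rep_len(group, nrow(x))),
    session = as.character(rep_len(session, nrow(x))))
  out <- dplyr::bind_cols(out, as_tibble(x))
  class(out) <- c("feature_set", class(out))
  out
}

#' @rdname feature_set
#' @param features A feature set tibble.
#' @export
feature_cols <- function(features) {
  grep("^f[0-9]{4,}$", names(features), value = TRUE)
}

#' @rdname feature_set
#' @export
feature_matrix <- function(features) {
  as.matrix(features[feature_cols(features)])
}

#' Write/read a feature table as CSV
#'
#' Columns `subject`, `group`, `session`, then `f0001`..`fNNNN`. The CSV
#' round-trips losslessly at double precision.
#'
#' @param features A [feature_set()] tibble (may have zero rows, in which
#'   case only the header is written).
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` a `feature_set` tibble.
#' @export
write_feature_table <- function(features, path) {
  need <- c("subject", "group", "session")
  if (!all(need %in% names(features))) {
    abort("feature table needs columns subject, group, session.")
  }
  readr::write_csv(features[c(need, feature_cols(features))], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          subject = readr::col_character(),
                          group = readr::col_character(),
                          session = readr::col_character(),
                          .default = readr::col_double()))
  class(df) <- c("feature_set", class(df))
  df
}
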
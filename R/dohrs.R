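dohrs_columns <- c("locus_id", "m", "n",
                   "fixed_s", "poly_one_s", "poly_both_s",
                   "fixed_r", "poly_one_r", "poly_both_r")

#' Assemble a DOHRS dataset
#'
#' A DOHRS dataset holds, per locus, the two sample sizes and the six
#' observed counts: fixed differences between the two species' samples,
#' sites polymorphic in exactly one sample, and sites polymorphic in both
#' samples, each for silent and replacement sites.
#'
#' @param df Data frame with columns
#'   `locus_id m n fixed_s poly_one_s poly_both_s fixed_r poly_one_r poly_both_r`.
#' @param provenance Optional free-text note carried along with the data.
#' @return A validated object of class `c("dohrs_dataset", "data.frame")`.
#' @export
dohrs_dataset <- function(df, provenance = "") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  validate_dohrs(df)
  df <- df[, dohrs_columns]
  df$locus_id <- as.character(df$locus_id)
  for (col in dohrs_columns[-1]) df[[col]] <- as.integer(df[[col]])
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("dohrs_dataset", "data.frame")
  df
}

#' Validate a DOHRS data frame
#'
#' Checks the structural invariants of a DOHRS dataset: all required
#' columns present, at least one locus, unique locus ids, integer
#' non-negative counts, sample sizes >= 1, and no "polymorphic in both
#' samples" counts when a sample holds a single sequence.
#'
#' @param df Data frame to check.
#' @return Invisibly `TRUE`; otherwise an error naming the row and field.
#' @export
validate_dohrs <- function(df) {
  missing_cols <- setdiff(dohrs_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("dataset must contain at least one locus", call. = FALSE)
  dup <- duplicated(df$locus_id)
  if (any(dup)) {
    stop(sprintf("row %d: duplicate locus_id '%s'", which(dup)[1],
                 df$locus_id[which(dup)[1]]), call. = FALSE)
  }
  count_cols <- dohrs_columns[-1]
  for (col in count_cols) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != round(v))) {
      bad <- which(!is.numeric(v) | !is.finite(v) | v != round(v))[1]
      stop(sprintf("row %d, field %s: not a non-negative integer", bad, col),
           call. = FALSE)
    }
    lo <- if (col %in% c("m", "n")) 1 else 0
    if (any(v < lo)) {
      stop(sprintf("row %d, field %s: value %s below %d",
                   which(v < lo)[1], col, v[which(v < lo)[1]], lo),
           call. = FALSE)
    }
  }
  single <- pmin(df$m, df$n) == 1
  for (col in c("poly_both_s", "poly_both_r")) {
    bad <- single & df[[col]] > 0
    if (any(bad)) {
      stop(sprintf(
        "row %d, field %s: a sample of one sequence cannot be polymorphic",
        which(bad)[1], col), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a DOHRS dataset from a tab-separated file
#'
#' Expects a header row with the canonical column names; `#`-prefixed lines
#' are ignored.  The dataset is validated on read.
#'
#' @param path Path to the TSV file.
#' @return A [dohrs_dataset()].
#' @export
read_dohrs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  dohrs_dataset(df, provenance = paste0("read from ", path))
}

#' Write a DOHRS dataset to a tab-separated file
#'
#' Deterministic column and row order; two writes of the same dataset are
#' byte-identical.
#'
#' @param dataset A [dohrs_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dohrs <- function(dataset, path) {
  if (!inherits(dataset, "dohrs_dataset")) dataset <- dohrs_dataset(dataset)
  validate_dohrs(dataset)
  utils::write.table(as.data.frame(dataset)[, dohrs_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
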
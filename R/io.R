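#' Read a gene-by-time log2-ratio table
#'
#' Parses a TSV with a `gene_id` column followed by time-point columns
#' headed `t<minutes>` (e.g., `t0`, `t5`, ...). Cells are log2 ratios;
#' `NA` marks missing measurements, which flag the gene as incomplete (such
#' genes are excluded from model fitting).
#'
#' @param path Path to the TSV file.
#' @return List of class `"timecourse_table"`: `values` (gene-by-time
#'   matrix of log2 ratios, rownames = gene ids), `time` (minutes), and
#'   `complete` (logical per gene).
#' @export
read_timecourse_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || names(tab)[1L] != "gene_id")
    stop("malformed header in ", path,
         ": expected 'gene_id' then time columns 't<min>'")
  tcols <- names(tab)[-1L]
  if (!all(grepl("^t[0-9]+(\\.[0-9]+)?$", tcols)))
    stop("malformed time headers in ", path, ": ",
         paste(tcols[!grepl("^t[0-9]+(\\.[0-9]+)?$", tcols)],
               collapse = ", "))
  time <- as.numeric(sub("^t", "", tcols))
  check_time_grid(time)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))
    stop("non-numeric values in ", path, ", column(s): ",
         paste(tcols[bad], collapse = ", "))
  }
  rownames(vals) <- ids
  structure(list(values = vals, time = time,
                 complete = !apply(is.na(vals), 1L, any)),
            class = "timecourse_table")
}

#' @export
print.timecourse_table <- function(x, ...) {
  cat(sprintf("Time-course table: %d genes x %d time points (%g-%g min); %d complete\n",
              nrow(x$values), length(x$time), min(x$time), max(x$time),
              sum(x$complete)))
  invisible(x)
}

check_overwrite <- function(path, overwrite) {
  if (file.exists(path) && !overwrite)
    stop("file exists and overwrite = FALSE: ", path)
  invisible(path)
}

format_num_df <- function(df, digits = 6) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}

write_tsv <- function(df, path, overwrite) {
  check_overwrite(path, overwrite)
  write.table(format_num_df(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a gene-by-time log2-ratio table
#'
#' @param values Gene-by-time matrix of log2 ratios (rownames = gene ids).
#' @param time Time grid (min) matching the columns.
#' @param path Output path.
#' @param overwrite Overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_timecourse_table <- function(values, time, path, overwrite = FALSE) {
  stopifnot(is.matrix(values), length(time) == ncol(values))
  df <- data.frame(gene_id = rownames(values) %||%
                     sprintf("g%04d", seq_len(nrow(values))),
                   values, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", paste0("t", time))
  write_tsv(df, path, overwrite)
}

#' Write the per-gene fit table
#'
#' @param fits A `"decay_fit_table"` from [fit_decay_models()].
#' @inheritParams write_timecourse_table
#' @return The path, invisibly.
#' @export
write_fit_table <- function(fits, path, overwrite = FALSE) {
  write_tsv(as.data.frame(fits), path, overwrite)
}

#' Write the per-gene profile-statistics table
#'
#' @param stats Data frame from [profile_stats()].
#' @inheritParams write_timecourse_table
#' @return The path, invisibly.
#' @export
write_stats_table <- function(stats, path, overwrite = FALSE) {
  write_tsv(stats, path, overwrite)
}

#' Write the per-cluster labels table
#'
#' @param labels Data frame of cluster labels (strategy, direction,
#'   return-to-baseline, dependence).
#' @inheritParams write_timecourse_table
#' @return The path, invisibly.
#' @export
write_labels_table <- function(labels, path, overwrite = FALSE) {
  write_tsv(labels, path, overwrite)
}

#' Write the generator ground-truth table
#'
#' @param truth Truth data frame from [simulate_cohort()].
#' @inheritParams write_timecourse_table
#' @return The path, invisibly.
#' @export
write_truth_table <- function(truth, path, overwrite = FALSE) {
  write_tsv(truth, path, overwrite)
}

#' Read a plain gene-id list
#'
#' One gene id per line; blank lines and duplicates are dropped.
#'
#' @param path Path to the text file.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}
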
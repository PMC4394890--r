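# Readers for the pipeline's tabular formats. All TSV inputs are UTF-8,
# tab-separated, "#"-comment lines ignored, header mandatory.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("format error in ", what, " ", sQuote(basename(path)),
         ": missing column(s) ", paste(miss, collapse = ", "))
  }
  df
}

#' Read a regulation table
#'
#' Reads a TSV of regulation edges (columns `regulator`, `target`,
#' `regulator_type`; optional `target_type` and `evidence`) into a
#' deduplicated [regulatory_set()]. Row order is irrelevant.
#'
#' @param path path to a tab-separated file with a header.
#' @param evidence_label "predicted" or "validated", applied to every edge;
#'   `NULL` (default) keeps the file's `evidence` column, falling back to
#'   "predicted" if the column is absent.
#' @return A `regulatory_set`.
#' @export
read_regulation_table <- function(path, evidence_label = NULL) {
  df <- read_tsv_checked(path, c("regulator", "target", "regulator_type"),
                         "regulation table")
  bad <- !df$regulator_type %in% c("TF", "miRNA")
  if (any(bad)) {
    i <- which(bad)[1]
    stop("format error in ", sQuote(basename(path)), " line ", i + 1L,
         ": unknown regulator_type ", sQuote(df$regulator_type[i]))
  }
  if (!is.null(evidence_label)) {
    evidence_label <- match.arg(evidence_label, c("predicted", "validated"))
    df$evidence <- rep(evidence_label, nrow(df))
  } else if (!"evidence" %in% names(df)) {
    df$evidence <- rep("predicted", nrow(df))
  }
  if (!"target_type" %in% names(df)) {
    df$target_type <- rep(NA_character_, nrow(df))
  }
  out <- new_regulatory_set(df)
  ffl_log("read_regulation_table: %d rows in, %d edges kept", nrow(df), nrow(out))
  out
}

#' Write a regulatory set as a regulation TSV
#'
#' @param reg a `regulatory_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regulation_table <- function(reg, path) {
  stopifnot(inherits(reg, "regulatory_set"))
  utils::write.table(as.data.frame(reg), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a symbol list
#'
#' One symbol per line; blank and "#"-comment lines are skipped; duplicates
#' collapse. Used for the curated disease-gene, disease-miRNA and TF catalogs.
#'
#' @param path path to a plain-text file.
#' @return Character vector of unique symbols.
#' @export
read_symbol_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a differential-expression table
#'
#' TSV with columns `gene`, `p_value`, `direction` ("up"/"down").
#'
#' @param path path to the table.
#' @return data.frame with the three validated columns.
#' @export
read_de_table <- function(path) {
  df <- read_tsv_checked(path, c("gene", "p_value", "direction"), "DE table")
  df$p_value <- as.numeric(df$p_value)
  bad <- is.na(df$p_value) | df$p_value < 0 | df$p_value > 1
  if (any(bad)) {
    stop("format error in DE table ", sQuote(basename(path)), " row ",
         which(bad)[1], ": p_value outside [0, 1]")
  }
  bad_d <- !df$direction %in% c("up", "down")
  if (any(bad_d)) {
    stop("format error in DE table ", sQuote(basename(path)), " row ",
         which(bad_d)[1], ": direction must be 'up' or 'down'")
  }
  df[, c("gene", "p_value", "direction")]
}

#' Read a TFBS record table
#'
#' TSV with columns `tf`, `target`, `zscore` holding scored TF-binding-site
#' predictions; Z-scores must be finite.
#'
#' @param path path to the table.
#' @return data.frame with columns tf, target, zscore.
#' @export
read_tfbs_table <- function(path) {
  df <- read_tsv_checked(path, c("tf", "target", "zscore"), "TFBS table")
  df$zscore <- as.numeric(df$zscore)
  if (any(!is.finite(df$zscore))) {
    stop("format error in TFBS table ", sQuote(basename(path)), " row ",
         which(!is.finite(df$zscore))[1], ": non-finite zscore")
  }
  df[, c("tf", "target", "zscore")]
}

#' Read a GMT-style gene-set collection
#'
#' Each line is a set name, a description, then one or more member symbols,
#' all tab-separated. Duplicate members within a line collapse.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors (set name -> member symbols).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("format error in GMT file ", sQuote(basename(path)), " line ",
         which(short)[1], ": fewer than 3 tab-separated fields")
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}
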
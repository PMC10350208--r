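#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated rearrangement table following the AIRR (MiAIRR)
#' Rearrangement column convention and returns it as a repertoire
#' `data.frame`. The file must carry at least `sequence_id`, `v_call`,
#' `j_call` and `junction` columns; `duplicate_count` defaults to 1 when
#' absent and `junction_length` is computed from `junction` when absent.
#' Row order is preserved.
#'
#' @param path Path to a tab-separated rearrangement file with a header row.
#' @param subject Subject label attached to every row. If the file carries a
#'   `subject` column it is overridden only when `subject` is non-`NULL`.
#' @param population Population label attached to every row (e.g. `"pop2"`).
#'   If `NULL`, the file must carry a `population` column.
#'
#' @return A `data.frame` with columns `sequence_id`, `v_call`, `j_call`,
#'   `junction`, `junction_length`, `duplicate_count`, `v_mutation_count`
#'   (`NA` when absent from the file), `population` and `subject`.
#'
#' @seealso [validate_repertoire()], [write_airr_table()]
#' @export
read_airr_table <- function(path, subject = NULL, population = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character",
                          check.names = FALSE)
  required <- c("sequence_id", "v_call", "j_call", "junction")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("malformed AIRR table (", path, "): missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("empty repertoire: ", path, " contains no rearrangement rows",
         call. = FALSE)
  }
  out <- data.frame(
    sequence_id = as.character(df$sequence_id),
    v_call = as.character(df$v_call),
    j_call = as.character(df$j_call),
    junction = toupper(as.character(df$junction)),
    stringsAsFactors = FALSE
  )
  out$junction_length <- if ("junction_length" %in% names(df)) {
    jl <- suppressWarnings(as.integer(df$junction_length))
    ifelse(is.na(jl), nchar(out$junction), jl)
  } else {
    nchar(out$junction)
  }
  out$duplicate_count <- if ("duplicate_count" %in% names(df)) {
    dc <- suppressWarnings(as.integer(df$duplicate_count))
    ifelse(is.na(dc), 1L, dc)
  } else {
    rep(1L, nrow(out))
  }
  out$v_mutation_count <- if ("v_mutation_count" %in% names(df)) {
    suppressWarnings(as.integer(df$v_mutation_count))
  } else {
    rep(NA_integer_, nrow(out))
  }
  out$population <- if (!is.null(population)) {
    rep(as.character(population), nrow(out))
  } else if ("population" %in% names(df)) {
    as.character(df$population)
  } else {
    stop("no population label: supply `population` or include a population ",
         "column in ", path, call. = FALSE)
  }
  out$subject <- if (!is.null(subject)) {
    rep(as.character(subject), nrow(out))
  } else if ("subject" %in% names(df)) {
    as.character(df$subject)
  } else {
    rep("subject1", nrow(out))
  }
  out
}

#' Normalize a V or J gene call to the gene level
#'
#' Upstream aligners report calls such as `"IGHV3-23*04, IGHV3-23D*01"`:
#' possibly several comma-separated candidates, each with an allele suffix.
#' Clonal assignment matches V and J at the gene level, so this keeps the
#' first listed call (aligners list the best match first) and strips the
#' allele suffix (everything from `"*"` onward) and surrounding whitespace.
#' The operation is idempotent and vectorized.
#'
#' @param call Character vector of raw gene annotation strings.
#' @return Character vector of gene-level labels, e.g. `"IGHV3-23"`.
#' @examples
#' normalize_gene_call("IGHV1-69*01")
#' normalize_gene_call("IGHV3-23*04, IGHV3-23D*01")
#' @export
normalize_gene_call <- function(call) {
  if (any(is.na(call)) || any(!nzchar(trimws(call)))) {
    stop("invalid gene call: empty or missing annotation string",
         call. = FALSE)
  }
  first <- vapply(strsplit(as.character(call), ",", fixed = TRUE),
                  `[`, character(1L), 1L)
  gene <- sub("\\*.*$", "", first)
  trimws(gene)
}

#' Validate a repertoire and drop malformed rearrangements
#'
#' Applies the structural filters that remain after upstream quality
#' filtering and alignment: rearrangements are dropped when the junction is
#' empty or contains characters outside A/C/G/T (ambiguity characters such
#' as N are rejected, not wildcarded, so that homology is exact), when the
#' stored `junction_length` disagrees with the junction or is not positive,
#' or when a gene call is empty. Retained row order is preserved and the
#' operation is idempotent.
#'
#' @param rep Repertoire `data.frame` as returned by [read_airr_table()].
#' @return The cleaned repertoire with an attribute `rejections`, a named
#'   integer vector counting rows dropped per reason
#'   (`non_acgt`, `bad_length`, `bad_gene_call`).
#' @export
validate_repertoire <- function(rep) {
  stopifnot(is.data.frame(rep))
  junction <- as.character(rep$junction)
  non_acgt <- is.na(junction) | !grepl("^[ACGT]+$", junction)
  bad_length <- !non_acgt &
    (is.na(rep$junction_length) | rep$junction_length <= 0L |
       rep$junction_length != nchar(junction))
  bad_call <- !non_acgt & !bad_length &
    (is.na(rep$v_call) | !nzchar(trimws(rep$v_call)) |
       is.na(rep$j_call) | !nzchar(trimws(rep$j_call)))
  keep <- !(non_acgt | bad_length | bad_call)
  report <- c(non_acgt = sum(non_acgt),
              bad_length = sum(bad_length),
              bad_gene_call = sum(bad_call))
  if (!any(keep)) {
    stop("empty repertoire: all ", nrow(rep),
         " rearrangements were rejected during validation", call. = FALSE)
  }
  out <- rep[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- report
  out
}

#' Write a derived table as TSV
#'
#' Writes any of the pipeline's derived tables (lineages, clone sizes,
#' overlap, connectivity, links, SHM summaries) as a tab-separated file with
#' a header, deterministic column order and preserved row order. Integers
#' and labels round-trip bit-exactly; fractions round-trip at R's full
#' printed precision (15 significant digits).
#'
#' @param records A `data.frame`. May have zero rows, in which case a
#'   header-only file is written.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_airr_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- tryCatch({
    utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write table to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read back a derived TSV table
#'
#' Counterpart of [write_airr_table()]: reads a tab-separated derived table
#' with automatic column typing, such that `read_derived_table(write_airr_table(x))`
#' reproduces `x` for the pipeline's table types.
#'
#' @param path Path to a TSV written by [write_airr_table()].
#' @return A `data.frame`.
#' @export
read_derived_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "",
                    check.names = FALSE)
}
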
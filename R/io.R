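# Plain-text and FASTA input/output for codeword lists, the flat key:value
# run configuration, and JSON run summaries.

#' Read a codeword list from plain text or FASTA
#'
#' Plain text holds one sequence per line; blank lines and lines starting
#' with `#` are ignored. FASTA is parsed with Biostrings. Format `"auto"`
#' sniffs FASTA from a leading `>`.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"text"`, `"fasta"`.
#' @return character vector of uppercase codewords (input order preserved).
#' @export
read_codewords <- function(path, format = c("auto", "text", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[!grepl("^\\s*(#|$)", first)]
    format <- if (length(first) && startsWith(first[1L], ">")) "fasta" else "text"
  }
  if (format == "fasta") {
    words <- unname(as.character(Biostrings::readDNAStringSet(path)))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    words <- lines[!grepl("^(#|$)", lines)]
  }
  as_codewords(words)
}

#' Write a codeword list as plain text or FASTA
#'
#' Plain text writes one sequence per line (optionally the digit form under
#' the T=0, C=1, G=2, A=3 mapping). FASTA records are named
#' `cw_0001 ... cw_NNNN` and wrapped at 60 columns.
#'
#' @param x a `code_set` or character vector of codewords.
#' @param path output file path.
#' @param format `"text"` or `"fasta"`.
#' @param digits write the integer digit form instead of bases (text only).
#' @return `path`, invisibly.
#' @export
write_codewords <- function(x, path, format = c("text", "fasta"),
                            digits = FALSE) {
  format <- match.arg(format)
  words <- if (inherits(x, "code_set")) x$words else as_codewords(x)
  if (format == "fasta") {
    if (digits) stop("the digit form is only available for text output")
    seqs <- Biostrings::DNAStringSet(words)
    names(seqs) <- sprintf("cw_%04d", seq_along(words))
    Biostrings::writeXStringSet(seqs, path, width = 60L)
  } else {
    out <- if (digits) chartr("TCGA", "0123", words) else words
    writeLines(out, path)
  }
  invisible(path)
}

#' Read a flat key: value run configuration
#'
#' One `key: value` pair per line; `#` starts a comment. Values are coerced
#' to logical (`true`/`false`) or numeric where possible, else kept as
#' strings. Keys mirror the CLI flags (`n`, `d`, `w`, `nrl`, `pop_size`,
#' `t_max`, `budget`, `batch`, `seed`, ...).
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key: value'): ", ln)
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    out[[key]] <- coerce_config_value(val)
  }
  out
}

coerce_config_value <- function(val) {
  low <- tolower(val)
  if (low %in% c("true", "yes", "on")) return(TRUE)
  if (low %in% c("false", "no", "off")) return(FALSE)
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

#' Write a JSON run summary
#'
#' Records the profile, set sizes before and after augmentation, budgets and
#' seeds of a search run, so a run is fully reconstructible from its summary.
#'
#' @param S the final `code_set` from [eors_search()].
#' @param path output JSON path.
#' @param extra optional named list merged into the summary.
#' @return the summary list, invisibly.
#' @export
write_run_summary <- function(S, path, extra = list()) {
  stopifnot(inherits(S, "code_set"))
  p <- S$profile
  summary <- c(list(
    profile = list(n = p$n, d = p$d, w = p$w, nrl = p$nrl),
    size_eo = as.integer(attr(S, "size_eo") %||% NA_integer_),
    size_final = length(S$words),
    coding_rate = coding_rate(max(1L, length(S$words)), p$n),
    seeds = as.list(attr(S, "seeds"))
  ), extra)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
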
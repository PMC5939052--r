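# Reading reaction-time files and serializing reports.

#' Read a reaction-time sample from a text file
#'
#' Plain text with one numeric observation per line (blank lines skipped),
#' or — when `column` is given — a delimited file from which that column
#' (by name or 1-based index) is taken. Values are reaction times in ms.
#'
#' @param path file path.
#' @param column optional column name or index for delimited input.
#' @return numeric vector in file order.
#' @examples
#' f <- tempfile(); writeLines(c("500", "620.5", "810"), f)
#' read_rt_file(f)
#' @export
read_rt_file <- function(path, column = NULL) {
  if (!file.exists(path)) exg_stop(paste0("no such file: ", path))
  if (is.null(column)) {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    if (length(keep) == 0L) exg_stop(paste0("empty file: ", path))
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    bad <- which(!is.finite(vals))
    if (length(bad) > 0L)
      exg_stop(sprintf("cannot parse '%s' at line %d of %s",
                       trimws(lines[keep[bad[1]]]), keep[bad[1]], path),
               class = "exg_parse_error")
    return(vals)
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) exg_stop(paste0("empty file: ", path))
  col <- if (suppressWarnings(!is.na(as.integer(column)))) {
    as.integer(column)
  } else {
    if (!(column %in% names(dt)))
      exg_stop(paste0("no column '", column, "' in ", path))
    column
  }
  vals <- suppressWarnings(as.numeric(dt[[col]]))
  bad <- which(!is.finite(vals))
  if (length(bad) > 0L)
    exg_stop(sprintf("cannot parse row %d of column '%s' in %s",
                     bad[1], as.character(column), path),
             class = "exg_parse_error")
  vals
}

report_list <- function(x) {
  if (inherits(x, "exg_fit")) {
    st <- pars_to_stats(x$mu, x$sigma, x$tau)
    out <- list(mu = x$mu, sigma = x$sigma, tau = x$tau,
                M = st[["M"]], S = st[["S"]], K = st[["K"]],
                method = x$method, converged = x$converged,
                n_iter = x$n_iter, grad_norm = x$grad_norm)
    if (!is.na(x$objective)) out$objective <- x$objective
    if (!is.null(x$nbins)) out$nbins <- x$nbins
    out
  } else if (inherits(x, "exg_gof")) {
    list(method = x$method, ks_D = x$ks_D, ks_scaled = x$ks_scaled,
         B = x$B, p = x$p, null_mean = x$null_mean, null_sd = x$null_sd,
         n_warn = x$n_warn, seed = x$seed, fit = report_list(x$fit))
  } else if (inherits(x, "exg_trim")) {
    out <- list(q = x$q, low_cut = x$low_cut, high_cut = x$high_cut,
                removed_low = x$removed_low, removed_high = x$removed_high,
                kept_n = length(x$kept))
    if (!is.null(x$prefit)) out$prefit <- report_list(x$prefit)
    out
  } else if (is.data.frame(x) || inherits(x, "exg_hist")) {
    x
  } else {
    exg_stop("cannot serialize this object")
  }
}

#' Write a report to JSON or TSV
#'
#' Fit, goodness-of-fit and trim reports serialize to JSON with stable field
#' names (`mu`, `sigma`, `tau`, `M`, `S`, `K`, `method`, `converged`,
#' `ks_D`, `ks_scaled`, `p`, `null_mean`, `null_sd`, `B`, `seed`,
#' `low_cut`, `high_cut`, `removed_low`, `removed_high`); numbers are kept at
#' full precision so a write/read round trip preserves them. Histograms and
#' bin-scan tables serialize to TSV (histogram columns: `bin_left`,
#' `bin_right`, `density`). `path = NULL` returns the serialized text
#' instead of writing.
#'
#' @param x an `exg_fit`, `exg_gof`, `exg_trim`, `exg_hist`, or data.frame.
#' @param path output file, or `NULL` to return the text.
#' @param format `"json"` or `"tsv"` (histograms and data frames only).
#' @return invisibly, the serialized text.
#' @export
write_report <- function(x, path = NULL, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- if (inherits(x, "exg_hist")) {
      data.frame(bin_left = x$edges[-length(x$edges)],
                 bin_right = x$edges[-1L], density = x$density)
    } else if (is.data.frame(x)) {
      x
    } else {
      exg_stop("TSV output is for histograms and scan tables; use json")
    }
    txt <- paste(c(paste(names(df), collapse = "\t"),
                   apply(df, 1L, function(r)
                     paste(formatC(as.numeric(r), digits = 15,
                                   format = "g"), collapse = "\t"))),
                 collapse = "\n")
  } else {
    obj <- report_list(x)
    txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, na = "null")
  }
  if (!is.null(path)) {
    ok <- tryCatch({ writeLines(txt, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) exg_stop(paste0("cannot write to ", path), class = "exg_io_error")
  }
  invisible(as.character(txt))
}
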
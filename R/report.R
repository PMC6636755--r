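#' Round to the nearest JPY, half away from zero
#'
#' All published table cells are reported to the nearest integer with halves
#' rounded away from zero (e.g. an internal 2,145,036.68 renders as
#' 2,145,037; a difference of -400,380.32 renders as -400,380). The model
#' carries exact unrounded values everywhere; this is the single rounding
#' function, applied only when rendering.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_jpy <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Render a results table
#'
#' Deterministic, byte-stable rendering of scenario or sensitivity-analysis
#' tables. CSV and markdown output carry integer-rounded values
#' ([round_jpy()]); JSON carries the exact unrounded values and round-trips
#' to identical internal numbers.
#'
#' @param result A `cma_results` or `cma_dsa` data.frame.
#' @param format `"csv"`, `"markdown"` or `"json"`.
#' @return A single character string.
#' @export
render_table <- function(result, format = c("csv", "markdown", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(result))
  df <- as.data.frame(result)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(df, dataframe = "rows",
                                         auto_unbox = TRUE, digits = NA)))
  }
  num <- vapply(df, is.numeric, logical(1))
  # parameter values (probabilities, days, hours) are not money; keep as-is
  num[names(df) %in% c("value")] <- FALSE
  df[num] <- lapply(df[num], round_jpy)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  cells <- rbind(names(df),
                 matrix(vapply(seq_along(df), function(j) {
                   format(df[[j]], trim = TRUE, scientific = FALSE,
                          big.mark = if (num[j]) "," else "")
                 }, character(nrow(df))), nrow = nrow(df)))
  widths <- apply(nchar(cells), 2, max)
  fmt_row <- function(r) {
    padded <- vapply(seq_along(r), function(i) {
      formatC(r[i], width = widths[i], flag = "-")
    }, character(1))
    paste0("| ", paste(padded, collapse = " | "), " |")
  }
  sep <- paste0("|", paste(strrep("-", widths + 2), collapse = "|"), "|")
  lines <- c(fmt_row(cells[1, ]), sep,
             vapply(seq_len(nrow(df)),
                    function(i) fmt_row(cells[i + 1, ]), character(1)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Box-and-whisker plot of PSA totals
#'
#' Mirrors the conventional PSA figure: one box per procedure showing the
#' median and interquartile range, with whiskers extending to the furthest
#' sample within 1.5 times the interquartile range of the box.
#'
#' @param result A `cma_psa` from [run_psa()].
#' @return A `ggplot` object.
#' @export
plot_psa <- function(result) {
  stopifnot(inherits(result, "cma_psa"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_psa requires the ggplot2 package", call. = FALSE)
  }
  s <- result$summary
  ggplot2::ggplot(s, ggplot2::aes(x = procedure)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = whisker_low, lower = q1,
                   middle = median, upper = q3, ymax = whisker_high),
      stat = "identity", width = 0.5, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "Cost per procedure (JPY)",
                  title = sprintf("Probabilistic sensitivity analysis (%d iterations)",
                                  result$iterations)) +
    ggplot2::scale_y_continuous(labels = function(x) {
      format(x, big.mark = ",", scientific = FALSE)
    }) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("procedure", "whisker_low", "q1", "median", "q3",
                         "whisker_high"))
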
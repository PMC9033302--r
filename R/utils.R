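#' @keywords internal
"_PACKAGE"

# Canonical factor levels used throughout the package.
LAND_USE_SYSTEMS <- c("rainforest", "jungle_rubber", "rubber", "oil_palm")
SAMPLE_LAYERS <- c("litter", "soil", "merged")

.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)

#' Log a message to stderr
#'
#' All pipeline logging goes through this function so that verbosity can be
#' controlled globally via `options(isofoodweb.verbosity = "DEBUG"|"INFO"|"WARN")`.
#'
#' @param ... parts of the message, pasted together.
#' @param level one of `"DEBUG"`, `"INFO"`, `"WARN"`.
#' @return `invisible(NULL)`; called for its side effect.
#' @export
iso_log <- function(..., level = "INFO") {
  level <- match.arg(level, names(.log_levels))
  threshold <- getOption("isofoodweb.verbosity", "INFO")
  if (.log_levels[[level]] >= .log_levels[[match.arg(threshold, names(.log_levels))]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.assert_numeric_column <- function(df, col, what) {
  if (!is.numeric(df[[col]])) {
    stop(sprintf("%s column '%s' contains non-numeric values", what, col),
         call. = FALSE)
  }
  invisible(TRUE)
}
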
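## internal helpers: classed conditions and small numeric utilities

abort_sf <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "spheroflux_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

warn_sf <- function(message, class) {
  warning(structure(
    class = c(class, "spheroflux_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

## %||% as in rlang, without the dependency
`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

## deterministic CSV writer: fixed column order, no quoting surprises,
## numbers at 6 significant digits unless signif = NA
write_sf_csv <- function(df, path, signif = NA) {
  out <- df
  if (!is.na(signif)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) signif(x, signif))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
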
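`%||%` <- function(x, y) if (is.null(x)) y else x

# split a pipe-delimited field into a trimmed character vector; "" -> character(0)
split_pipes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  out <- trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

join_pipes <- function(x) paste(x, collapse = "|")

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
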
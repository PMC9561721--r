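#' @keywords internal
"_PACKAGE"

# Structured logging channel. Events are emitted as single-line JSON through
# message() when option `sigportrait.verbose` is TRUE (the pipeline turns it
# on); counts that matter to callers are also attached to return values as
# attributes so nothing depends on parsing log text.
sp_log <- function(event, ...) {
  rec <- c(list(event = event), list(...))
  if (isTRUE(getOption("sigportrait.verbose", FALSE))) {
    message(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }
  invisible(rec)
}

# -log10 with a floor on p to keep scores finite; p_floor = 1e-320 by default
# downstream because observed p-values of exactly 0 must not become Inf.
neg_log10 <- function(p, p_floor) {
  -log10(pmax(p, p_floor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize a gene-symbol vector: strip whitespace, upper-case.
norm_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}
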
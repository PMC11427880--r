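#' @keywords internal
"_PACKAGE"

# package-level cache for lazily loaded lexical resources
.hq_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

hq_stop <- function(..., class = "healthqq_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

hq_assert <- function(cond, ...) {
  if (!isTRUE(cond)) hq_stop(...)
}

# trimmed, collapsed whitespace; used for duplicate-text detection
hq_squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

hq_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "healthqq")
  hq_assert(nzchar(path), "packaged resource not found: ",
            paste(c(...), collapse = "/"))
  path
}
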
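#' @keywords internal
"_PACKAGE"

# shared internal helpers

xtrd_msg <- function(...) message("[xtrd] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable short polynomial hash of a configuration list (over its deparsed
# form); used only to stamp output tables so reruns are traceable
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
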
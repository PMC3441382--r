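# Internal string / RNG helpers shared across modules.

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

collapse <- function(x) paste(x, collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hamming distance between two equal-length strings (or char vectors).
hamming <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- chars(a)
  if (is.character(b) && length(b) == 1L) b <- chars(b)
  stopifnot(length(a) == length(b))
  sum(a != b)
}

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# 1-based inclusive span helpers; a span is c(start, end), NULL when empty.
span_len <- function(span) {
  if (is.null(span) || any(is.na(span))) return(0L)
  as.integer(span[2] - span[1] + 1L)
}

span_str <- function(s, span) {
  if (span_len(span) == 0L) return("")
  substr(s, span[1], span[2])
}
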
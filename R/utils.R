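## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

bf_stop <- function(...) stop(..., call. = FALSE)

## Read lines from a path, "-" (standard input) or an in-memory `text`
## argument.  All readers funnel through here so that path and stdin
## inputs are byte-equivalent (stream neutrality).
stream_lines <- function(source = "-", text = NULL) {
  if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
      return(strsplit(text, "\n", fixed = TRUE)[[1L]])
    }
    return(as.character(text))
  }
  if (is.null(source) || identical(source, "-")) {
    return(readLines(file("stdin")))
  }
  if (!file.exists(source)) {
    bf_stop("cannot open input '", source, "': no such file")
  }
  readLines(source, warn = FALSE)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`;
## a NULL seed leaves the global RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

is_number_token <- function(x) {
  grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
}

fmt_num <- function(x, digits = 10L) {
  vapply(x, function(v) sprintf("%.*g", digits, v), character(1L))
}
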
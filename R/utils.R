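#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats coef lm optim rnorm runif sd setNames
#' @importFrom utils read.csv read.delim write.csv packageVersion
NULL

# classed conditions so callers (and the CLI) can distinguish user/config
# errors from stage failures
svt_stop <- function(msg, class = "seavote_error", call. = FALSE) {
  stop(structure(
    class = c(class, "seavote_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

svt_config_error <- function(msg) svt_stop(msg, class = "seavote_config_error")

# log to stderr; suppressible via option
svt_log <- function(...) {
  if (isTRUE(getOption("seavote.quiet", FALSE))) return(invisible(NULL))
  message("[seavote] ", ...)
}

# half-up decimal rounding (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run code under a fixed seed without disturbing the caller's RNG stream;
# RNG kind pinned so outputs are identical across platforms/sessions
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    svt_stop("seed must be a single finite number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# derive a child seed from a master seed, kept < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    svt_stop(sprintf("%s is missing required column(s): %s",
                     what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
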
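#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm rpois rgamma rnorm rexp rbinom runif rnorm
#'   median mad lm coef predict residuals sd setNames uniroot
#' @importFrom utils write.csv read.csv head
#' @importFrom graphics abline points plot legend
NULL

# Condition helpers: configuration errors (bad parameters / config files) and
# data errors (unreadable or inconsistent inputs) carry distinct classes so the
# command-line wrapper can map them to exit codes 2 and 3.
abort_config <- function(msg, call. = FALSE) {
  stop(structure(class = c("smi_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_data <- function(msg) {
  stop(structure(class = c("smi_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_num <- function(x, name, min = -Inf, max = Inf, len = 1L,
                      integer = FALSE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x))
    abort_config(sprintf("'%s' must be a numeric of length %d", name, len))
  if (any(x < min) || any(x > max))
    abort_config(sprintf("'%s' must lie in [%g, %g]", name, min, max))
  if (integer && any(x != floor(x)))
    abort_config(sprintf("'%s' must be integer-valued", name))
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic stream of per-region / per-sample seeds below 2^31.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483629L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
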
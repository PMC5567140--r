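#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-stream seed from a root seed and a stage label.
# Keeps every artifact on its own stream so adding a stage never perturbs
# draws made by earlier stages. Result is kept inside the 32-bit integer
# range R requires of set.seed().
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a single number in [0, 1]")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_config(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config(field, "must be a single positive number")
  x
}
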
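#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Named RNG streams hanging off one root seed, so adding a generator never
# perturbs the draws of another. Offsets are part of the package contract.
.stream_offsets <- c(
  expression = 1L, panel = 2L, dose = 3L, combination = 4L,
  mutation = 5L, qpcr = 6L, clonogenic = 7L
)

derive_seed <- function(seed, stream) {
  if (!stream %in% names(.stream_offsets)) {
    abort(paste0("unknown RNG stream '", stream, "'"))
  }
  off <- .stream_offsets[[stream]]
  # keep the derived seed a valid 32-bit integer
  as.integer((as.double(seed) * 7919 + off * 104729) %% 2147483629)
}

# evaluate `code` under a fixed seed, restoring the caller's RNG state;
# `salt` separates repeated calls into the same stream (e.g. one combination
# matrix per cell line and drug pair)
with_stream_seed <- function(seed, stream, code, salt = 0L) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer((as.double(derive_seed(seed, stream)) +
                         as.double(salt) * 7919) %% 2147483629))
  force(code)
}

# deterministic non-negative integer salt from labels
salt_from <- function(...) {
  s <- paste(..., collapse = "|")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000003L
}

assert_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
    abort(paste0("`", name, "` must be a single positive integer"))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", name, "` must lie in [0, 1]"))
  }
  invisible(x)
}
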
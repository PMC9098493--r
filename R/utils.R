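#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never disturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_with <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# scalar checks used by the constructors
check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_with("invalid_argument", "`%s` must be a single finite number", name)
  bad <- if (strict) x <= lower else x < lower
  if (bad)
    stop_with("invalid_argument", "`%s` must be %s %s", name,
              if (strict) ">" else ">=", format(lower))
  x
}

as_intensity_matrix <- function(frame) {
  m <- if (inherits(frame, "image_frame")) frame$data else frame
  if (!is.matrix(m) || !is.numeric(m))
    stop_with("invalid_frame", "frame must be a numeric matrix or image_frame")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop_with("invalid_frame", "frame must be at least 2x2 pixels")
  if (any(!is.finite(m)) || any(m < 0))
    stop_with("invalid_frame",
              "frame intensities must be finite and non-negative")
  m
}
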
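#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the session RNG, runs `code`, and restores the previous
#' `.Random.seed` afterwards so that library calls never disturb the
#' caller's random stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

#' Dense numeric matrix view of a possibly sparse matrix
#' @noRd
as_dense <- function(M) {
  if (inherits(M, "Matrix")) as.matrix(M) else as.matrix(M)
}
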
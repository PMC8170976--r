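# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' must be supplied", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Significance stars for a p-value
#'
#' Maps two-sided p-values onto the conventional star labels used throughout
#' the package's comparison tables: `***` for p <= 0.001, `**` for p <= 0.01,
#' `*` for p <= 0.05 and `ns` otherwise.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return character vector of the same length.
#' @export
p_stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] <= 0.001, "***",
             ifelse(p[ok] <= 0.01,  "**",
             ifelse(p[ok] <= 0.05,  "*", "ns")))
  out
}
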
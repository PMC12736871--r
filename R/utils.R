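#' @keywords internal
"_PACKAGE"

# Small shared helpers: argument checks and seed substreams.

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop_invalid("%s contains non-finite values", what)
  invisible(x)
}

as_nchw <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, 1L, dim(x)))
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  if (length(dim(x)) != 4L) stop_invalid("expected an array with dims (B, C, H, W)")
  x
}

#' Derive a reproducible sub-seed from a run seed
#'
#' All randomness in the package flows from one run seed through named
#' sub-streams (weight initialisation, splitting, augmentation, sampling,
#' dropout), so that two runs with the same seed are bit-identical while the
#' streams stay decoupled from each other.
#'
#' @param seed integer run seed.
#' @param stream character name of the sub-stream.
#' @return an integer seed in `[0, 2^31)`.
#' @export
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# He-style initialisation for a convolution weight (Cout, Cin, k, k).
he_init <- function(cout, cin, k) {
  fan_in <- cin * k * k
  array(stats::rnorm(cout * cin * k * k, sd = sqrt(2 / fan_in)),
        c(cout, cin, k, k))
}
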
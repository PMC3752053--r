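#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data :=
#' @importFrom stats quantile glm quasibinomial predict p.adjust rnorm runif
#'   rlnorm rpois rbinom sd weighted.mean qlnorm plnorm coef setNames
#' @importFrom utils head tail read.csv write.csv
NULL

utils::globalVariables(c(".w", "sampling_weight", "season", "gender",
                         "meets_guideline", "is_transit"))

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so seeded helpers do not perturb
# surrounding simulations.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
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
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Derive a child-specific stream seed from a master seed; kept < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

assert_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (positive && x <= 0)) {
    abort(sprintf("`%s` must be a single %s number.", name,
                  if (positive) "positive" else "finite"),
          class = "accel_argument_error")
  }
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
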
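#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor p.adjust pnorm pt rbinom rnbinom rnorm runif sd
#'   t.test wilcox.test aov anova median var quantile setNames rlnorm
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Map a p-value to the significance-star convention
#'
#' Stars follow the convention used throughout the package's group
#' comparisons: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of star labels.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
         ifelse(p < 1e-2, "**",
         ifelse(p < 0.05, "*", "ns"))))
  out[is.na(p)] <- NA_character_
  out
}

## shared argument checks --------------------------------------------------

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

## deterministic seed derivation: offsets a user seed for independent
## stages while keeping the result a valid 32-bit integer
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}
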
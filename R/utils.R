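#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform `%||%` `:=`
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols rename distinct n
#'   row_number across all_of pull slice
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map2 pmap imap map_chr keep
#' @importFrom stats median quantile sd var cor wilcox.test p.adjust rnorm
#'   runif rbinom rpois rweibull pchisq glm binomial predict setNames
#'   complete.cases na.omit
#' @importFrom utils head tail
NULL

# Stable polynomial string hash (mod 2^31 - 1), used to derive per-patient RNG
# substreams from one base seed so simulations do not depend on the order in
# which patients are generated. Exact in double arithmetic (31 * h < 2^53).
str_hash32 <- function(x) {
  vapply(x, function(s) {
    h <- 17
    for (b in utf8ToInt(paste0("x", s))) h <- (h * 31 + b) %% 2147483647
    h
  }, numeric(1))
}

# Derive a valid set.seed() integer (< 2^31) from a base seed and a label.
derive_seed <- function(base_seed, label) {
  as.integer(((as.numeric(base_seed) %% 2147483647) * 48271 +
                str_hash32(label)) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_that <- function(ok, msg, class = "radgen_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# population (biased) central moments, used by kurtosis/skewness definitions
pop_moment <- function(x, k) mean((x - mean(x))^k)
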
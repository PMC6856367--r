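#' @importFrom rlang abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join inner_join n row_number across all_of desc first
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap
#' @importFrom stats prcomp dnbinom dbinom rnbinom rpois rhyper p.adjust
#'   runif var setNames rbinom
#' @importFrom rlang .data
#' @importFrom methods is
#' @importFrom tidyr pivot_longer
NULL

# stop with a consistent error class so callers can distinguish user error
stop_input <- function(msg) {
  rlang::abort(msg, class = "medipdmr_input_error")
}

check_number <- function(x, name, min = -Inf, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) != 1L) || anyNA(x)) {
    stop_input(sprintf("`%s` must be a non-missing number.", name))
  }
  if (any(x < min)) {
    stop_input(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  invisible(x)
}

check_df_cols <- function(df, cols, name) {
  if (!is.data.frame(df)) {
    stop_input(sprintf("`%s` must be a data frame.", name))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# run `expr` under a local RNG state seeded with `seed`; NULL leaves the
# global stream untouched
with_seed_local <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  check_number(seed, "seed")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# deterministic child seeds below 2^31 for nested stochastic stages
derive_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.double(seed) * 48271 + offset) %% 2147483647
}
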
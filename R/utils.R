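#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rexp runif rbinom quantile sd pnorm qnorm optim
#'   median aggregate setNames complete.cases
#' @importFrom utils write.csv read.csv
NULL

# Deterministic per-stage seed derivation: keeps every stage's RNG stream
# independent of the others while remaining a pure function of the master
# seed. Kept below 2^31 - 1 so the result is a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- (as.numeric(seed) * 48271 + sum(utf8ToInt(as.character(stage)) * 131)) %%
    2147483629
  as.integer(h)
}

# Evaluate code under a local RNG state so library functions that seed
# internally do not disturb the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Columns of a trial table that are not baseline covariates.
.reserved_cols <- c("id", "site_id", "arm", "event_time", "event_indicator")

covariate_columns <- function(table) {
  setdiff(names(table), .reserved_cols)
}
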
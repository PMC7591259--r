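# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so simulators and permutation tests are reproducible
#' without clobbering the session's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("osccfitness_format_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("osccfitness_config_error", "error")))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x > 0
}

#' Largest-remainder apportionment of n items to proportions
#'
#' Deterministic: floors the quotas, then hands the remaining items to the
#' largest fractional remainders (ties broken by position). Guarantees the
#' sizes sum to `n` exactly.
#' @noRd
largest_remainder <- function(proportions, n) {
  if (abs(sum(proportions) - 1) > 1e-8)
    stop_config("group proportions must sum to 1, got ", sum(proportions))
  quota <- proportions * n
  sizes <- floor(quota)
  left  <- n - sum(sizes)
  if (left > 0) {
    ord <- order(quota - sizes, decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1L
  }
  as.integer(sizes)
}

# Uppercase + trim gene symbols; the convention applied on every ingest path.
clean_symbols <- function(x) toupper(trimws(as.character(x)))

rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
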
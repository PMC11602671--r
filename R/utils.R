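# Internal helpers shared across modules.

#' Largest-remainder apportionment of `n` units to fractional shares
#'
#' Deterministic: floors each share, then distributes the remaining units to
#' the largest fractional remainders (ties broken by position).
#'
#' @param n integer total to apportion.
#' @param props numeric vector of non-negative fractions summing to 1.
#' @return integer vector summing to `n`, same length as `props`.
#' @keywords internal
largest_remainder <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0))
  if (abs(sum(props) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", format(sum(props)), ")")
  }
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Sub-seeding rule: each generator derives its own stream from the config seed
# and a fixed purpose tag, so generators can be called in any order (or alone)
# and still reproduce. seed' = (seed * 1009 + 101 * index(purpose)) mod 2^31-1.
.seed_purposes <- c("pool", "survey", "kd490", "pit", "funnel", "pipeline")

derive_seed <- function(seed, purpose) {
  stopifnot(length(seed) == 1, is.finite(seed))
  idx <- match(purpose, .seed_purposes)
  if (is.na(idx)) stop("unknown seed purpose: ", purpose)
  as.integer((as.numeric(seed) * 1009 + 101 * idx) %% (2^31 - 1))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
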
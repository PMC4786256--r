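#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores whatever state was in place before the call, so simulation
#' helpers are deterministic without clobbering the caller's RNG stream.
#'
#' @param seed Integer seed (< 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
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
  set.seed(as.integer(seed))
  expr
}

# pH strips read in 0.5 increments; TRUE when x sits on that grid
on_ph_grid <- function(x) {
  is.finite(x) & x >= 2 & x <= 9 & abs(x * 2 - round(x * 2)) < 1e-8
}

#' Replace zeros by half the smallest positive value
#'
#' Standard pseudo-value used before log10 transformation of label-free
#' intensities, applied per vector (per protein, or per taxon within a
#' cohort). A vector with no positive entries is returned unchanged.
#'
#' @param x Nonnegative numeric vector.
#' @return `x` with exact zeros replaced by `min(x[x > 0]) / 2`.
#' @export
replace_zeros_half_min <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0, na.rm = TRUE))
  pos <- x[x > 0 & is.finite(x)]
  if (length(pos) == 0) {
    return(x)
  }
  x[x == 0] <- min(pos) / 2
  x
}

#' Significance stars at conventional thresholds
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# stop() with a stage tag so pipeline errors name the failing stage
stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
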
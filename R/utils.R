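#' @importFrom methods new validObject is slot slotNames show
#' @importFrom stats sd mad median rnorm rbinom rlnorm rpois runif aov
#'   t.test wilcox.test pchisq pnorm qnorm approx complete.cases
#' @importFrom utils head tail packageVersion
NULL

# classed error helper: every validation failure carries a specific
# condition class so callers (and the CLI) can react programmatically
stopc <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "optomapError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assertThat <- function(cond, class, fmt, ...) {
  if (!isTRUE(cond)) stopc(class, fmt, ...)
  invisible(TRUE)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so seeded simulations never perturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# time axis (ms) for an n-sample trace; sample i sits at (i-1)*dt
timesMs <- function(n, dt) (seq_len(n) - 1) * dt

# half-open window [from, to) in ms -> sample indices; errors if empty
windowIdx <- function(n, dt, from, to, class = "optomap_range_error") {
  i0 <- ceiling(from / dt - 1e-9) + 1
  i1 <- ceiling(to / dt - 1e-9)        # last index with t < to
  i0 <- max(1L, as.integer(i0))
  i1 <- min(n, as.integer(i1))
  assertThat(i1 >= i0, class,
             "analysis window [%g, %g) ms selects no samples of a %d-sample trace",
             from, to, n)
  i0:i1
}

# scalar checks
isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

msg_info <- function(quiet, fmt, ...) {
  if (!isTRUE(quiet)) message(sprintf(fmt, ...))
}

# rbind a list of data.frames; NULL-safe and empty-safe
rbindList <- function(lst) {
  lst <- lst[!vapply(lst, is.null, TRUE)]
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, make.row.names = FALSE))
}
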
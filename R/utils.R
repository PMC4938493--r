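#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-stream seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' global seed plus a short stage tag, so that stages are individually
#' reproducible and inserting a new stage does not shift the streams of the
#' others.
#'
#' @param seed integer global seed.
#' @param tag character stage tag, e.g. `"expression"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (cc in utf8ToInt(tag)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# positive scalar count check
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  bad <- !is.numeric(x) || anyNA(x) || any(x < lo) ||
    (if (open_hi) any(x >= hi) else any(x > hi))
  if (bad) stop(sprintf("`%s` must lie in [%g,%g%s", name, lo, hi,
                        if (open_hi) ")" else "]"), call. = FALSE)
  x
}

#' Benjamini-Hochberg / Bonferroni adjustment
#'
#' Thin wrapper with input validation; `bonferroni` is `min(1, m p)`, `bh`
#' the monotone step-up procedure.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_p <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
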
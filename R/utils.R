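#' @useDynLib trialemulate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pt plogis qnorm rbinom rnorm rpois runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible sub-seed from a master seed and a stream name, so
# adding a generator field does not reshuffle the draws of the others.
# FNV-style fold of the name bytes, kept inside the 32-bit signed range.
substream_seed <- function(seed, name) {
  h <- 2166136261
  for (b in utf8ToInt(name)) {
    h <- (h * 16777619 + b) %% 2147483647
  }
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Truncated normal by rejection (renormalized density, no mass piling at the
# bounds). Bounds are in SD units away only rarely, so rejection is cheap.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

as_date <- function(x) as.Date(x, origin = "1970-01-01")

# Stable zero-padded identifiers: pt00001, pt00002, ...
make_ids <- function(prefix, n) {
  sprintf("%s%05d", prefix, seq_len(n))
}
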
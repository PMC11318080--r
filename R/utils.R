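#' @include AllClasses.R
NULL

# Named seed substreams: every stochastic component derives its own 31-bit
# seed from (root seed, stream tag), so any single stage can be reproduced in
# isolation.
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

withSeed <- function(seed, tag, code) {
  withr::with_seed(deriveSeed(seed, tag), code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# rowsum() over group ids 1..ngroups that returns a row for empty groups too.
groupSum <- function(x, group, ngroups) {
  out <- matrix(0, ngroups, ncol(x))
  s <- rowsum(x, group)
  out[as.integer(rownames(s)), ] <- s
  out
}

# group-wise max of a vector (groups 1..ngroups); -Inf for empty groups
groupMax <- function(x, group, ngroups) {
  out <- rep(-Inf, ngroups)
  o <- order(group, x)  # within each group, max is the last element
  out[group[o]] <- x[o]
  out
}
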
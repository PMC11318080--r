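#' @include utils.R
NULL

# Elementwise map over a nested parameter list (numeric leaves).
paramMap <- function(f, ...) {
  trees <- list(...)
  first <- trees[[1L]]
  if (is.list(first)) {
    out <- lapply(seq_along(first), function(i) {
      do.call(paramMap, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(first)
    out
  } else {
    do.call(f, trees)
  }
}

paramZeroLike <- function(p) paramMap(function(x) x * 0, p)

paramL2 <- function(p) {
  tot <- 0
  rec <- function(x) {
    if (is.list(x)) lapply(x, rec) else tot <<- tot + sum(x^2)
    invisible(NULL)
  }
  rec(p)
  sqrt(tot)
}

paramFinite <- function(p) {
  ok <- TRUE
  rec <- function(x) {
    if (is.list(x)) lapply(x, rec) else if (!all(is.finite(x))) ok <<- FALSE
    invisible(NULL)
  }
  rec(p)
  ok
}

adamInit <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(m = paramZeroLike(params), v = paramZeroLike(params), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adamStep <- function(state, params, grads) {
  state$t <- state$t + 1L
  state$m <- paramMap(function(m, g) state$beta1 * m + (1 - state$beta1) * g,
                      state$m, grads)
  state$v <- paramMap(function(v, g) state$beta2 * v + (1 - state$beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  params <- paramMap(function(p, m, v) {
    p - state$lr * (m / c1) / (sqrt(v / c2) + state$eps)
  }, params, state$m, state$v)
  list(state = state, params = params)
}
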
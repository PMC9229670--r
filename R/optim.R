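## Optimizers over parameter trees.
##
## Both optimizers carry their moment estimates in trees parallel to the
## parameter tree, so one recursive walk performs an update.

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}

rmsprop_init <- function(params) {
  list(v = tree_zeros_like(params), mom = tree_zeros_like(params))
}

rmsprop_step <- function(params, grads, state, lr, rho = 0.9, momentum = 0.9,
                         eps = 1e-8) {
  state$v <- tree_map2(function(v, g) rho * v + (1 - rho) * g * g, state$v, grads)
  state$mom <- tree_map2(function(mo, gv) momentum * mo + gv,
                         state$mom,
                         tree_map2(function(g, v) lr * g / (sqrt(v) + eps),
                                   grads, state$v))
  list(params = tree_map2(`-`, params, state$mom), state = state)
}
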
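# Independent oracles, coded without reference to the package internals.

# Scalar evaluation of the generalized logical update rule, written as an
# explicit loop over signals so it shares no code path with update_node().
oracle_update <- function(x, d, act, inh, clamp = TRUE) {
  prod_act <- 1
  for (a in act) prod_act <- prod_act * (1 - a)
  prod_inh <- 1
  for (b in inh) prod_inh <- prod_inh * (1 - b)
  val <- (1 - d) * x +
    (1 - prod_act) * prod_inh * (1 - x) -
    prod_act * (1 - prod_inh) * x
  if (clamp) val <- max(0, min(1, val))
  val
}

# The synchronous Boolean rule induced in the binary, unit-weight, d = 0
# limit: an active activator and no active inhibitor switches the node on; no
# active activator and an active inhibitor switches it off; otherwise hold.
oracle_boolean_step <- function(net, state) {
  out <- state
  for (nd in net$nodes) {
    inc <- net$edges[net$edges$target == nd, , drop = FALSE]
    act_on <- any(inc$sign == "+" & state[inc$source] == 1)
    inh_on <- any(inc$sign == "-" & state[inc$source] == 1)
    if (act_on && !inh_on) out[nd] <- 1
    else if (!act_on && inh_on) out[nd] <- 0
  }
  out
}
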
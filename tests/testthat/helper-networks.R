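# Fixture networks built in code.

toy_network_path <- function() {
  system.file("extdata", "toy_network.tsv", package = "glogsim")
}

toy_network <- function() read_network(toy_network_path())

# Minimal one-receptor chain: R -> M -> E.
chain_network <- function(w = 0.7) {
  signaling_network(
    edges = data.frame(source = c("R", "M"), target = c("M", "E"),
                       sign = "+", weight = w),
    input_nodes = "R")
}

single_node_network <- function(name = "R") {
  signaling_network(nodes = name, input_nodes = name)
}
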
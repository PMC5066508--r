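# Shared fixtures: ancestral building blocks and random generators used
# by the property tests.

anc <- minihelix::ancestral_sequences()

ancestral_minihelices <- function() {
  lapply(anc[c("d_microhelix", "ac_microhelix", "t_microhelix")],
         minihelix::build_minihelix,
         acc5 = anc[["acc5"]], acc3 = anc[["acc3"]])
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# microhelix with a perfectly paired 5-bp stem and random loop
random_microhelix <- function() {
  stem5 <- random_seq(5)
  minihelix::microhelix(stem5, random_seq(7),
                        minihelix::reverse_complement(stem5))
}

# minihelix with perfectly paired acceptor stem and microhelix stem
random_minihelix <- function() {
  acc5 <- random_seq(7)
  minihelix::build_minihelix(random_microhelix(), acc5,
                             minihelix::reverse_complement(acc5))
}

# three minihelices sharing one acceptor stem pair, as in the model's
# sequence construction: the assembled core then has a paired acceptor
# stem (AS5 from mh1 against AS3 from mh3)
random_minihelix_triple <- function() {
  acc5 <- random_seq(7)
  acc3 <- minihelix::reverse_complement(acc5)
  lapply(1:3, function(i) {
    minihelix::build_minihelix(random_microhelix(), acc5, acc3)
  })
}
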
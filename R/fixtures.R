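#' Clade-level backbone species tree
#'
#' A six-leaf rooted tree `(((((A,B),C),D),E),OUT)` with the five in-phylum
#' clades A--E as leaves plus an outgroup. This is a transcribed clade-level
#' topology shipped for worked examples and scenario reconstruction at
#' clade resolution; it is not measured data, and branch lengths are
#' nominal.
#'
#' @return A `phylo` object.
#' @examples
#' clade_backbone_tree()$tip.label
#' @export
clade_backbone_tree <- function() {
  read_newick(system.file("extdata", "clade_backbone.nwk",
                          package = "pathtracer", mustWork = TRUE))
}
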
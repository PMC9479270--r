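#' Core mRNAs: reversal mRNAs present in the co-expression network
#'
#' Plain set intersection of the reversal mRNA ids with the network's mRNA
#' nodes -- the Venn step that reduces a large co-expression network to the
#' mRNAs whose expression the treatment actually reversed.
#'
#' @param reversal_mrna_ids character vector of reversal mRNA ids.
#' @param network a `coexpression_network`.
#' @return Sorted character vector.
#' @export
core_mrnas <- function(reversal_mrna_ids, network) {
  sort(intersect(unique(reversal_mrna_ids), network$mrna_nodes))
}

#' Induced key sub-network over a core mRNA set
#'
#' Keeps exactly the edges of the parent network whose mRNA endpoint lies in
#' `core`; lncRNA nodes left without any edge are dropped, lncRNA nodes are
#' never filtered by the core set themselves. Core ids that are not mRNA
#' nodes of the network are ignored with a warning.
#'
#' @param network a `coexpression_network`.
#' @param core character vector of core mRNA ids.
#' @return A list of class `sub_network` (also a `coexpression_network`):
#'   the filtered `edges`, `lncrna_nodes`, `mrna_nodes`, plus `core_mrnas`.
#' @export
induced_subnetwork <- function(network, core) {
  core <- unique(core)
  stray <- setdiff(core, network$mrna_nodes)
  if (length(stray))
    warning("ignoring ", length(stray),
            " core id(s) not present in the network", call. = FALSE)
  keep <- network$edges$mrna_id %in% core
  edges <- network$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         lncrna_nodes = sort(unique(edges$lncrna_id)),
         mrna_nodes = sort(unique(edges$mrna_id)),
         core_mrnas = sort(intersect(core, network$mrna_nodes)),
         thresholds = network$thresholds),
    class = c("sub_network", "coexpression_network"))
}
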
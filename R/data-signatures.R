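# packaged cell-cycle signature sets (42 G1/S + 54 G2/M human gene symbols,
# the replication/mitosis signatures widely used for single-cell cycle
# scoring); user-overridable by passing any GMT to read_gmt()

#' Packaged G1/S and G2/M signature sets
#'
#' @return A `ctc_gene_sets` collection with sets `G1S` (42 genes) and
#'   `G2M` (54 genes).
#' @export
cycle_signature_sets <- function() {
  read_gmt(system.file("extdata", "cycle_signatures.gmt",
                       package = "ctcflow", mustWork = TRUE))
}
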
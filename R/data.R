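#' Worked cis-NAT regulon examples
#'
#' Fold changes of cold-induced cis-NAT gene pairs (sense and antisense
#' transcript, with the pair's siRNA cluster significantly upregulated)
#' reported at the 6 h and 2 d time points of a cold-acclimation
#' expression profiling experiment in *Arabidopsis thaliana*. The siRNA
#' fold change and all adjusted p values are encoded at their reported
#' significance bounds (fold change >= 2, BH-adjusted p <= 0.05). Used as
#' the worked input for [detect_classical_regulon()].
#'
#' @return data frame with columns time, gene1, fc1, gene2, fc2, padj1,
#'   padj2, sirna_fc, sirna_padj.
#' @export
cis_nat_regulon_examples <- function() {
  path <- system.file("extdata", "cis_nat_regulon_examples.tsv",
                      package = "coldsrna", mustWork = TRUE)
  read_tsv_file(path)
}
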
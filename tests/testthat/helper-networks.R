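## Shared fixtures: networks are loaded once per test run; the expensive
## multiscale baseline equilibration is memoised.

apo_net <- function() {
  if (is.null(.fixtures$apo)) .fixtures$apo <- apoptosis_network()
  .fixtures$apo
}
cc_net <- function() {
  if (is.null(.fixtures$cc)) .fixtures$cc <- cellcycle_network()
  .fixtures$cc
}
ms_net <- function() {
  if (is.null(.fixtures$ms)) .fixtures$ms <- multiscale_network()
  .fixtures$ms
}
ms_baseline <- function() {
  if (is.null(.fixtures$ms_eq)) {
    .fixtures$ms_eq <- multiscale_equilibrate(ms_net())
  }
  .fixtures$ms_eq
}
.fixtures <- new.env()

## tiny genomics tables used across patient-pipeline tests
toy_mutations <- function() {
  data.frame(
    sample_id = c("S1", "S1", "S2", "S3", "S4", "S5"),
    hugo_symbol = c("MYD88", "CD79B", "BCL2", "MYC", "UNKNOWNGENE", "TP53"),
    alteration = c("SNV_GOF", "SNV_GOF", "SNV_GOF", "SNV_GOF", "SNV_GOF",
                   "SNV_LOF"),
    oncogenic = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
}
toy_cna <- function() {
  data.frame(sample_id = c("S2", "S6"),
             gene_or_arm = c("BCL2", "1q"),
             copy_state = c(1, 1))
}
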
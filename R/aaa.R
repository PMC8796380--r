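# Mutator function vocabulary. CDS mutators require reading-frame information
# from transcript annotation; basic mutators operate on raw nucleotides.
BASIC_MUTATORS <- c("snv", "1del", "2del0", "2del1")
CDS_MUTATORS <- c("snvre", "inframe", "ala", "stop", "aa")
ALL_MUTATORS <- c(BASIC_MUTATORS, CDS_MUTATORS)

DNA_BASES <- c("A", "C", "G", "T")

input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("sgedesign_input_error", "error")))
}

is_cds_mutator <- function(x) x %in% CDS_MUTATORS
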
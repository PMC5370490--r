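# Partition level codes, nuclear and mitochondrial. Sourced first.
NUCLEAR_LEVELS <- c("gen", "chr", "arm", "cyt", "win")
MITO_LEVELS    <- c("mtg", "mst", "mgn")
ALL_LEVELS     <- c(NUCLEAR_LEVELS, MITO_LEVELS)
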
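# Shared constants (this file loads first).
DNA_BASES <- c("A", "C", "G", "T")
GENE_CATEGORIES <- c("non_structural", "structural", "adsorption",
                     "other_unknown")
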
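# Regular expressions matching histone gene symbols (HGNC current and legacy
# nomenclature). One pattern per line; lines starting with '#' are ignored.
# H1 linker histones (H1-1 .. H1-10)
^H1-[0-9]
# Core histone families, current cluster/variant symbols (H2AC*, H2AZ1,
# H2BC*, H3C*, H3-3A/B, H4C*, ...)
^H2A
^H2B
^H3
^H4
# Legacy HIST1/2/3/4 cluster symbols (HIST1H2BK, ...)
^HIST
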
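>trna_iMet synthetic tRNA 3' terminus (last 40 nt, CCA end)
TGGCGCAGCGGAAGCGTGCTGGGCCCATAACCCAGAGCCA
>trna_Lys synthetic tRNA 3' terminus (last 40 nt, CCA end)
GAGCGCCTGATCAAGAGGTCATACGGGAGATCTGAATCCA
>trna_Trp synthetic tRNA 3' terminus (last 40 nt, CCA end)
CACGTTCGATTCCGGTTCGGAATCGAGACCTTAGTAGCCA
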
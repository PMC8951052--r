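name: "621.5"
snp_id: PPR621.5
allele_fam: G
allele_hex: C
primer_fam: GAAGGTGACCAAGTTCATGCTACCAGTAATCTCCACATGAACATTG
primer_hex: GAAGGTCGGAGTCAACGGATTACCAGTAATCTCCACATGAACATTC
primer_common: GCGATAAAGAAGCGGGAGATTA
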
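>ITS2_flank_left synthetic consensus of the 5.8S rDNA tail bordering ITS2
TCGCATCGATGAAGAACGTAGCGAAATGCGATACTTGGTG
>ITS2_flank_right synthetic consensus of the 28S rDNA head bordering ITS2
CTTATCGCACGGACTCCTGGGCGTCACGCATCGCGTCGCC
>psbA-trnH_flank_left synthetic consensus of the psbA gene 3' end
AGTTATGCATGAACGTAATGCTCATAACTTCCCTCTAGAC
>psbA-trnH_flank_right synthetic consensus of the trnH-GUG gene edge
GAACGACGGGAATTGAACCCGCGCATGGTGGATTCACAAT
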
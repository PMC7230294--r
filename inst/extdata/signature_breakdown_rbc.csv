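class,n_selected
PC_aa,17
PC_ae,25
sphingomyelin,4
lysoPC,9
acylcarnitine,2
amino_acid,2
biogenic_amine,2
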
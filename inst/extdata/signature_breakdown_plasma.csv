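class,n_selected
free_carnitine,1
acylcarnitine,2
amino_acid,13
biogenic_amine,6
sphingomyelin,1
lysoPC,5
PC_aa,12
PC_ae,22
hexose,1
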
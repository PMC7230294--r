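metabolite_id,class,lloq,uloq,acyl_carbons
C0,free_carnitine,0.537,268,NA
C2,acylcarnitine,0.0127,15.9,NA
C3,acylcarnitine,0.0194,24.3,NA
C3:1,acylcarnitine,0.0209,26.2,NA
C3-OH,acylcarnitine,0.0102,12.8,NA
C3-DC,acylcarnitine,0.015,18.8,NA
C4,acylcarnitine,0.0174,21.8,NA
C4:1,acylcarnitine,0.0196,24.6,NA
C4-OH,acylcarnitine,0.0205,25.6,NA
C5,acylcarnitine,0.0243,30.4,NA
C5:1,acylcarnitine,0.0116,14.5,NA
C5:1-DC,acylcarnitine,0.0289,36.1,NA
C5-OH,acylcarnitine,0.0242,30.2,NA
C5-DC,acylcarnitine,0.013,16.2,NA
C5-M-DC,acylcarnitine,0.0178,22.3,NA
C6,acylcarnitine,0.0318,39.8,NA
C6:1,acylcarnitine,0.0268,33.5,NA
C7-DC,acylcarnitine,0.0133,16.6,NA
C8,acylcarnitine,0.0123,15.4,NA
C9,acylcarnitine,0.0166,20.7,NA
C10,acylcarnitine,0.0244,30.5,NA
C10:1,acylcarnitine,0.0289,36.1,NA
C10:2,acylcarnitine,0.0304,38,NA
C12,acylcarnitine,0.011,13.7,NA
C12:1,acylcarnitine,0.0186,23.3,NA
C12-DC,acylcarnitine,0.025,31.2,NA
C14,acylcarnitine,0.0135,16.9,NA
C14:1,acylcarnitine,0.0105,13.1,NA
C14:1-OH,acylcarnitine,0.0355,44.4,NA
C14:2,acylcarnitine,0.0161,20.2,NA
C14:2-OH,acylcarnitine,0.014,17.4,NA
C16,acylcarnitine,0.028,35,NA
C16:1,acylcarnitine,0.0169,21.1,NA
C16:1-OH,acylcarnitine,0.0179,22.4,NA
C16:2,acylcarnitine,0.0395,49.3,NA
C16:2-OH,acylcarnitine,0.0144,18,NA
C16-OH,acylcarnitine,0.034,42.4,NA
C18,acylcarnitine,0.0324,40.4,NA
C18:1,acylcarnitine,0.0154,19.3,NA
C18:2,acylcarnitine,0.0145,18.1,NA
H1,hexose,67.4,33700,NA
Ala,amino_acid,1.09,821,NA
Arg,amino_acid,1.14,856,NA
Asn,amino_acid,1.84,1380,NA
Asp,amino_acid,1.27,951,NA
Cit,amino_acid,3.61,2710,NA
Gln,amino_acid,3.18,2390,NA
Glu,amino_acid,1.67,1250,NA
Gly,amino_acid,2.38,1790,NA
His,amino_acid,1.77,1330,NA
Ile,amino_acid,3.61,2710,NA
Leu,amino_acid,1.63,1220,NA
Lys,amino_acid,1.55,1160,NA
Met,amino_acid,3.96,2970,NA
Orn,amino_acid,3.62,2710,NA
Phe,amino_acid,1.17,874,NA
Pro,amino_acid,1.86,1400,NA
Ser,amino_acid,1.26,948,NA
Thr,amino_acid,2.28,1710,NA
Trp,amino_acid,1.66,1240,NA
Tyr,amino_acid,2.95,2210,NA
Val,amino_acid,3,2250,NA
Ac-Orn,biogenic_amine,0.0733,220,NA
ADMA,biogenic_amine,0.03,90,NA
SDMA,biogenic_amine,0.0336,101,NA
total DMA,biogenic_amine,0.0341,102,NA
alpha-AAA,biogenic_amine,0.0622,186,NA
Carnosine,biogenic_amine,0.0626,188,NA
Creatinine,biogenic_amine,0.0724,217,NA
DOPA,biogenic_amine,0.0428,129,NA
Dopamine,biogenic_amine,0.0729,219,NA
Histamine,biogenic_amine,0.033,98.9,NA
Kynurenine,biogenic_amine,0.0328,98.4,NA
Met-SO,biogenic_amine,0.0607,182,NA
Nitro-Tyr,biogenic_amine,0.0356,107,NA
c4-OH-Pro,biogenic_amine,0.0344,103,NA
t4-OH-Pro,biogenic_amine,0.0924,277,NA
PEA,biogenic_amine,0.0786,236,NA
Putrescine,biogenic_amine,0.0636,191,NA
Sarcosine,biogenic_amine,0.0292,87.8,NA
Serotonin,biogenic_amine,0.0936,281,NA
Spermidine,biogenic_amine,0.0884,265,NA
Spermine,biogenic_amine,0.0611,183,NA
lysoPC a C14:0,lysoPC,0.0884,354,14
lysoPC a C16:0,lysoPC,0.0939,376,16
lysoPC a C16:1,lysoPC,0.185,740,16
lysoPC a C17:0,lysoPC,0.118,473,17
lysoPC a C18:0,lysoPC,0.0734,294,18
lysoPC a C18:1,lysoPC,0.074,296,18
lysoPC a C18:2,lysoPC,0.0844,338,18
lysoPC a C20:3,lysoPC,0.146,583,20
lysoPC a C20:4,lysoPC,0.0605,242,20
lysoPC a C24:0,lysoPC,0.184,737,24
lysoPC a C26:0,lysoPC,0.0996,398,26
lysoPC a C26:1,lysoPC,0.111,444,26
lysoPC a C28:0,lysoPC,0.0512,205,28
lysoPC a C28:1,lysoPC,0.0852,341,28
PC aa C24:0,PC_aa,0.0311,373,NA
PC aa C26:0,PC_aa,0.0254,305,NA
PC aa C28:1,PC_aa,0.0298,358,NA
PC aa C30:0,PC_aa,0.0566,679,NA
PC aa C30:2,PC_aa,0.089,1070,NA
PC aa C32:0,PC_aa,0.0308,370,NA
PC aa C32:1,PC_aa,0.059,709,NA
PC aa C32:2,PC_aa,0.0332,399,NA
PC aa C32:3,PC_aa,0.0582,698,NA
PC aa C34:1,PC_aa,0.0332,398,NA
PC aa C34:2,PC_aa,0.0831,997,NA
PC aa C34:3,PC_aa,0.0498,598,NA
PC aa C34:4,PC_aa,0.0607,728,NA
PC aa C36:0,PC_aa,0.0281,337,NA
PC aa C36:1,PC_aa,0.0431,517,NA
PC aa C36:2,PC_aa,0.041,492,NA
PC aa C36:3,PC_aa,0.0312,375,NA
PC aa C36:4,PC_aa,0.0712,854,NA
PC aa C36:5,PC_aa,0.0664,797,NA
PC aa C36:6,PC_aa,0.0483,580,NA
PC aa C38:0,PC_aa,0.0719,863,NA
PC aa C38:1,PC_aa,0.0329,395,NA
PC aa C38:3,PC_aa,0.0256,307,NA
PC aa C38:4,PC_aa,0.0292,350,NA
PC aa C38:5,PC_aa,0.059,709,NA
PC aa C38:6,PC_aa,0.0739,886,NA
PC aa C40:1,PC_aa,0.06,720,NA
PC aa C40:2,PC_aa,0.0273,328,NA
PC aa C40:3,PC_aa,0.0894,1070,NA
PC aa C40:4,PC_aa,0.0264,317,NA
PC aa C40:5,PC_aa,0.0801,961,NA
PC aa C40:6,PC_aa,0.0288,346,NA
PC aa C42:0,PC_aa,0.0902,1080,NA
PC aa C42:1,PC_aa,0.0287,344,NA
PC aa C42:2,PC_aa,0.0952,1140,NA
PC aa C42:4,PC_aa,0.0856,1030,NA
PC aa C42:5,PC_aa,0.0363,436,NA
PC aa C42:6,PC_aa,0.0776,931,NA
PC ae C30:0,PC_ae,0.029,435,NA
PC ae C30:1,PC_ae,0.0274,411,NA
PC ae C30:2,PC_ae,0.0103,154,NA
PC ae C32:1,PC_ae,0.0245,367,NA
PC ae C32:2,PC_ae,0.0113,170,NA
PC ae C34:0,PC_ae,0.0363,544,NA
PC ae C34:1,PC_ae,0.0243,365,NA
PC ae C34:2,PC_ae,0.0388,582,NA
PC ae C34:3,PC_ae,0.0292,438,NA
PC ae C36:0,PC_ae,0.0131,196,NA
PC ae C36:1,PC_ae,0.0373,559,NA
PC ae C36:2,PC_ae,0.029,435,NA
PC ae C36:3,PC_ae,0.0111,167,NA
PC ae C36:4,PC_ae,0.0128,192,NA
PC ae C36:5,PC_ae,0.0145,218,NA
PC ae C38:0,PC_ae,0.039,585,NA
PC ae C38:1,PC_ae,0.0246,369,NA
PC ae C38:2,PC_ae,0.0339,508,NA
PC ae C38:3,PC_ae,0.0267,400,NA
PC ae C38:4,PC_ae,0.0166,250,NA
PC ae C38:5,PC_ae,0.0102,153,NA
PC ae C38:6,PC_ae,0.0304,456,NA
PC ae C40:1,PC_ae,0.0176,263,NA
PC ae C40:2,PC_ae,0.0124,186,NA
PC ae C40:3,PC_ae,0.021,315,NA
PC ae C40:4,PC_ae,0.0105,157,NA
PC ae C40:5,PC_ae,0.0147,220,NA
PC ae C40:6,PC_ae,0.0199,298,NA
PC ae C42:0,PC_ae,0.0218,327,NA
PC ae C42:1,PC_ae,0.0363,544,NA
PC ae C42:2,PC_ae,0.0218,327,NA
PC ae C42:3,PC_ae,0.0286,429,NA
PC ae C42:4,PC_ae,0.0232,348,NA
PC ae C42:5,PC_ae,0.013,194,NA
PC ae C44:3,PC_ae,0.0126,189,NA
PC ae C44:4,PC_ae,0.016,241,NA
PC ae C44:5,PC_ae,0.0334,501,NA
PC ae C44:6,PC_ae,0.0248,373,NA
SM C16:0,sphingomyelin,0.0548,438,NA
SM C16:1,sphingomyelin,0.068,544,NA
SM C18:0,sphingomyelin,0.0344,275,NA
SM C18:1,sphingomyelin,0.0512,410,NA
SM C20:2,sphingomyelin,0.0729,583,NA
SM C22:3,sphingomyelin,0.0804,643,NA
SM C24:0,sphingomyelin,0.0634,508,NA
SM C24:1,sphingomyelin,0.0288,231,NA
SM C26:0,sphingomyelin,0.0425,340,NA
SM C26:1,sphingomyelin,0.0904,723,NA
SM (OH) C14:1,sphingomyelin,0.0263,210,NA
SM (OH) C16:1,sphingomyelin,0.029,232,NA
SM (OH) C22:1,sphingomyelin,0.0342,274,NA
SM (OH) C22:2,sphingomyelin,0.0982,786,NA
SM (OH) C24:1,sphingomyelin,0.0276,221,NA
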
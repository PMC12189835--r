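>TRDV1_synthetic|V
ACAGCGGACTCAGCCACCTACTTCTGTGCCCTGGGGGAA
>TRDD1_synthetic|D
GAAATAGT
>TRDD2_synthetic|D
CCTTCCTAC
>TRDD3_synthetic|D
ACTGGGGGATACG
>TRDD4_synthetic|D
TGGGGGATACGC
>TRDD5_synthetic|D
GGGTACACCGATAC
>TRDD6_synthetic|D
CCGGAGGATACAAC
>TRDJ4_synthetic|J
ACCGACAAGCTCATCTTTGGAAGCGGGACAAAACTCATCGTA
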
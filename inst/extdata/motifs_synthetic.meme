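MEME version 4

ALPHABET= ACGT

strands: +

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF GATA
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.700 0.100 0.100 0.100
 0.050 0.050 0.850 0.050
 0.900 0.030 0.040 0.030
 0.030 0.030 0.030 0.910
 0.920 0.030 0.020 0.030
 0.800 0.060 0.060 0.080
 0.100 0.100 0.700 0.100

MOTIF TAL1
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.650 0.120 0.120 0.110
 0.700 0.100 0.100 0.100
 0.080 0.760 0.080 0.080
 0.880 0.040 0.040 0.040
 0.040 0.040 0.880 0.040
 0.850 0.050 0.050 0.050
 0.050 0.050 0.050 0.850
 0.100 0.080 0.740 0.080

MOTIF SOX2
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.120 0.640 0.120 0.120
 0.800 0.070 0.060 0.070
 0.050 0.050 0.050 0.850
 0.040 0.040 0.040 0.880
 0.060 0.060 0.820 0.060
 0.080 0.070 0.070 0.780
 0.120 0.100 0.100 0.680
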
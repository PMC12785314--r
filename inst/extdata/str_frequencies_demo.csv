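locus,allele,frequency
FGA,18,0.030
FGA,18.2,0.008
FGA,19,0.056
FGA,20,0.128
FGA,20.2,0.004
FGA,21,0.172
FGA,21.2,0.006
FGA,22,0.188
FGA,22.2,0.010
FGA,23,0.134
FGA,23.2,0.006
FGA,24,0.137
FGA,25,0.072
FGA,26,0.028
FGA,27,0.013
FGA,28,0.008
SE33,14,0.022
SE33,15,0.030
SE33,16,0.041
SE33,17,0.066
SE33,18,0.077
SE33,19,0.090
SE33,20,0.062
SE33,20.2,0.022
SE33,21,0.040
SE33,21.2,0.030
SE33,22.2,0.030
SE33,23.2,0.038
SE33,24.2,0.040
SE33,25.2,0.050
SE33,26.2,0.058
SE33,27.2,0.062
SE33,28.2,0.070
SE33,29.2,0.052
SE33,30.2,0.040
SE33,31.2,0.030
SE33,32.2,0.022
SE33,33.2,0.014
SE33,34.2,0.008
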
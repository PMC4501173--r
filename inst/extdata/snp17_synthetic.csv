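snp_id,locus,maf,or_per_allele
rs3814113,9p22.2,0.32,1.23979
rs2072590,2q31,0.28,1.158553
rs2665390,3q25,0.08,1.199013
rs10088218,8q24.21,0.13,1.158553
rs10098821,8q24.21,0.2,1.131758
rs8170,19p13.11,0.19,1.145138
rs2363956,19p13.11,0.45,1.105109
rs11782652,8q21,0.07,1.158553
rs1243180,10p12.31,0.31,1.118415
rs757210,17q12,0.38,1.131758
rs1695,11q13,0.26,1.091839
rs2046210,6q25.1,0.34,1.078606
rs9303542,17q21,0.27,1.105109
rs635634,9q34.2,0.18,1.091839
rs10069690,5p15.33,0.26,1.118415
rs555025,2q13,0.42,1.078606
rs1400482,12q24,0.22,1.09183948547322
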
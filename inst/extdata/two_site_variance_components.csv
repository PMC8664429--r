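trait,year,component,variance,proportion,H2
FL,2017,genotype,4.92,0.11,0.25
FL,2017,gxs_PAL,0,0,NA
FL,2017,gxs_SRO,26.44,0.62,NA
FL,2017,block,0.93,0.02,NA
FL,2017,residual_PAL,5.59,0.13,NA
FL,2017,residual_SRO,4.93,0.12,NA
FL,2018,genotype,7.86,0.22,0.57
FL,2018,gxs_PAL,0,0,NA
FL,2018,gxs_SRO,4.49,0.13,NA
FL,2018,block,1.89,0.05,NA
FL,2018,residual_PAL,9.23,0.26,NA
FL,2018,residual_SRO,12.4,0.35,NA
PH,2017,genotype,21.87,0.17,0.50
PH,2017,gxs_PAL,7.93,0.06,NA
PH,2017,gxs_SRO,7.95,0.06,NA
PH,2017,block,5.67,0.05,NA
PH,2017,residual_PAL,57.48,0.46,NA
PH,2017,residual_SRO,24.16,0.19,NA
PH,2018,genotype,22.25,0.26,0.62
PH,2018,gxs_PAL,6.8,0.08,NA
PH,2018,gxs_SRO,3.14,0.04,NA
PH,2018,block,4.35,0.05,NA
PH,2018,residual_PAL,29.9,0.34,NA
PH,2018,residual_SRO,20.36,0.23,NA
YLD,2017,genotype,1796.61,0.05,0.19
YLD,2017,gxs_PAL,4148.64,0.12,NA
YLD,2017,gxs_SRO,3919.93,0.12,NA
YLD,2017,block,1732.23,0.05,NA
YLD,2017,residual_PAL,16676.45,0.49,NA
YLD,2017,residual_SRO,5768.75,0.17,NA
YLD,2018,genotype,498.32,0.03,0.11
YLD,2018,gxs_PAL,3220.8,0.19,NA
YLD,2018,gxs_SRO,540.88,0.03,NA
YLD,2018,block,1160.68,0.07,NA
YLD,2018,residual_PAL,9301.29,0.53,NA
YLD,2018,residual_SRO,2674.47,0.15,NA
ZN,2017,genotype,1.49,0.14,0.38
ZN,2017,gxs_PAL,0.16,0.02,NA
ZN,2017,gxs_SRO,3.05,0.29,NA
ZN,2017,block,0.61,0.06,NA
ZN,2017,residual_PAL,2.02,0.19,NA
ZN,2017,residual_SRO,3.11,0.30,NA
ZN,2018,genotype,1.31,0.16,0.40
ZN,2018,gxs_PAL,0.27,0.03,NA
ZN,2018,gxs_SRO,2.28,0.27,NA
ZN,2018,block,0.44,0.05,NA
ZN,2018,residual_PAL,1.62,0.19,NA
ZN,2018,residual_SRO,2.53,0.30,NA
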
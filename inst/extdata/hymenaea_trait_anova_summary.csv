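trait,label,QMg,QMr,mean,h2_printed,cvg_cve_printed,cv_printed
FL,fruit length (mm),837.33,25.52,91.12,96.95,2.82,5.54
FWi,fruit width (mm),184.07,10.14,43.67,94.49,2.07,7.29
FT,fruit thickness (mm),99.76,4.65,28.61,95.34,2.26,7.53
FWe,fruit weight (g),1487.68,93.24,61.84,93.73,1.93,15.61
NSF,seeds per fruit,5.55,0.33,3.40,94.06,1.99,17.08
SL,seed length (mm),41.07,0.62,24.76,98.47,4.01,3.23
SWi,seed width (mm),8.89,0.62,19.01,92.95,1.81,4.15
ST,seed thickness (mm),10.84,3.07,13.93,71.66,0.79,12.51
SWe,seed weight (g),6.33,0.11,4.89,98.29,3.80,6.57
WCS,seed water content (%),15.07,2.27,11.13,84.91,1.19,13.49
FEC,first emergence count (%),2579.24,125.08,42.00,95.15,2.21,26.61
EP,emergence percentage (%),1775.88,144.89,59.00,91.84,1.67,20.48
ESI,emergence speed index,0.29,0.02,0.65,93.72,0.97,20.50
MET,mean emergence time (days),32.55,1.00,23.00,96.92,2.80,4.28
LAP,shoot length (cm),61.09,3.81,17.73,93.75,1.93,11.02
LRS,root system length (cm),39.28,5.82,14.96,85.17,1.19,16.12
DMAP,shoot dry mass (g),7.84,0.05,1.01,87.24,1.31,26.28
RDM,root dry mass (g),0.08,0.009,0.32,87.99,1.35,29.81
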
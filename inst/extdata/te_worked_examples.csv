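analyte,device,matrix,n,cv_pct,bias_pct,te_obs_pct
glucose,BHBCheck,whole_blood,22,2.4,3188.2,3193
glucose,BHBCheck,plasma,22,2.7,3127.4,3132.8
glucose,PrecisionXtra,whole_blood,28,11,3316.8,3338.8
glucose,PrecisionXtra,plasma,28,4.9,3289.1,3298.9
glucose,NovaVet,whole_blood,28,0,3371.4,3371.4
glucose,NovaVet,plasma,28,0,3359.1,3359.1
bhb,BHBCheck,whole_blood,28,12.4,103,127.8
bhb,BHBCheck,plasma,28,0,88.4,88.4
bhb,PrecisionXtra,whole_blood,28,0,103,103
bhb,PrecisionXtra,plasma,28,0,65.8,65.8
bhb,NovaVet,whole_blood,28,0,37.9,37.9
bhb,NovaVet,plasma,28,0,80.3,80.3
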
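analyte,device,matrix,bias,loa_lower,loa_upper
glucose,BHBCheck,whole_blood,48,15,81
glucose,BHBCheck,plasma,69,31,107
glucose,PrecisionXtra,whole_blood,0,-17,18
glucose,PrecisionXtra,plasma,10,-10,29
glucose,NovaVet,whole_blood,-18,-40,3
glucose,NovaVet,plasma,-14,-33,5
bhb,BHBCheck,whole_blood,0.2,-0.3,0.8
bhb,BHBCheck,plasma,0.1,-0.1,0.4
bhb,PrecisionXtra,whole_blood,0.2,-0.2,0.6
bhb,PrecisionXtra,plasma,0,-0.5,0.6
bhb,NovaVet,whole_blood,-0.1,-1.1,1
bhb,NovaVet,plasma,0.1,-0.8,1
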
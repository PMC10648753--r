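day,volume_mm3,area_mm2,porosity_pct,length_mm,width_mm,sample_volume_mL
1,7.89,19.53,23.5,3.25,1.65,165.33
2,9.73,22.04,24.9,3.16,1.60,144.96
3,10.68,23.66,25.2,3.39,1.66,140.53
4,18.13,34.00,28.4,3.75,1.68,138.56
5,18.10,35.31,28.8,3.98,1.71,126.37
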
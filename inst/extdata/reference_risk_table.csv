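scenario,sub_population,paf_urr_4.49,paf_urr_plus20,paf_urr_minus20,paf_urr_1.30,pif_urr_4.49,pif_urr_plus20,pif_urr_minus20,pif_urr_1.30
B-r,rural,3.63,4.07,3.09,0.64,NA,NA,NA,NA
SF-r,rural,3.61,4.05,3.08,0.63,0.01,0.01,0.01,0.00
Ex-80-r,rural,3.45,3.87,2.94,0.60,0.18,0.21,0.16,0.03
Ex-50-r,rural,3.18,3.57,2.71,0.56,0.46,0.51,0.39,0.08
CF-Hf-r,rural,2.99,3.36,2.55,0.52,0.65,0.73,0.55,0.11
Ex-20-r,rural,2.92,3.27,2.49,0.51,0.73,0.82,0.62,0.13
CF-All-r,rural,2.78,3.12,2.37,0.49,0.87,0.97,0.74,0.15
IC-r,rural,2.78,3.11,2.36,0.49,0.88,0.98,0.74,0.15
Atm-WHO-r,rural,1.19,1.33,1.01,0.21,2.47,2.77,2.10,0.43
B-u,urban,2.87,3.22,2.44,0.50,NA,NA,NA,NA
Ex-u,urban,2.85,3.19,2.42,0.50,0.02,0.03,0.02,0.00
SF-u,urban,2.82,3.17,2.40,0.49,0.05,0.05,0.04,0.01
IC-u,urban,1.77,1.99,1.51,0.31,1.11,1.25,0.95,0.19
Atm-Hf-u,urban,1.62,1.82,1.38,0.28,1.27,1.43,1.08,0.22
Atm-WHO-u,urban,0.48,0.54,0.41,0.08,2.40,2.69,2.04,0.42
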
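acd,label,bottom,top,steepness,ec50
gemcitabine,I6,34.33,80.39,4.30,0.0016
gemcitabine,I4,12.83,73.07,4.37,0.0018
gemcitabine,I2,-5.51,67.47,5.35,0.0022
gemcitabine,I0,-1.06,70.12,23.14,0.0026
fluorouracil,I6,33.22,63.24,2.77,0.36
fluorouracil,I4,13.42,56.05,2.90,0.20
fluorouracil,I2,-6.99,57.52,1.70,0.27
fluorouracil,I0,-0.47,57.80,2.19,0.28
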
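Country,Death Rate,Infection Rate,Vaccination Rate,Complete Vaccination Rate
USA,1.18,9.37,75.28,63.54
India,1.18,5.67,67.68,50.95
Brazil,2.48,37.86,79.59,70.06
UK,0.91,3.92,76.77,71.02
France,0.69,7.90,79.79,76.39
Russia,2.79,4.63,52.49,47.85
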
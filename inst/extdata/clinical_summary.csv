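characteristic,mean_patient,sd_patient,n_patient,mean_control,sd_control,n_control
age,48.39,10.66,24,53.70,9.34,19
abc_spontaneous,53.08,18.86,24,98.53,1.12,19
abc_auditory,76.00,18.24,24,99.95,0.23,19
abc_repetition,74.08,21.07,24,99.89,1.12,19
abc_naming,54.42,28.40,24,99.74,0.57,19
language_ability,64.39,19.20,24,99.53,0.42,19
mmse,14.42,6.86,24,29.21,0.98,19
moca,10.46,6.16,24,28.57,1.01,19
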
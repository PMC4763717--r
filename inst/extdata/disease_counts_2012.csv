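disease_id,rcount,vcount,correction_factor
acid_reflux_gerd,743,631,84.98
acne,6936,6027,86.89
add_adhd,2794,2660,95.19
arthritis,2524,2522,99.92
asthma,3952,3754,95.00
backache,3035,3028,99.77
cancer,110760,63647,57.46
congestive_heart_failure,928,313,33.76
heart_disease,2741,2410,87.91
copd,226,188,83.37
depression,14294,10459,73.17
diabetes,9202,8896,96.67
flu,10139,8810,86.90
genital_herpes,76,66,86.84
heart_attack,15027,2311,15.38
stroke,12852,1914,14.89
high_cholesterol,225,218,96.67
hpv,636,545,85.73
hypertension,1630,1491,91.49
migraine,5958,5615,94.24
hay_fever,481,473,98.27
osteoporosis,316,306,96.68
stomach_ulcers,80,73,91.25
uti,880,479,54.40
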
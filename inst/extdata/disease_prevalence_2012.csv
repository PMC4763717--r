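disease_id,prev_general,prev_platform,units
acid_reflux_gerd,32.4,2.40,millions
acne,11.2,2.00,millions
add_adhd,4.9,0.90,millions
arthritis,34.4,1.30,millions
asthma,12.4,1.00,millions
backache,42.0,2.60,millions
cancer,5.0,0.46,millions
chf_heart_disease,5.9,0.46,millions
copd,5.5,0.86,millions
depression,18.7,2.20,millions
diabetes,20.8,1.20,millions
flu,17.2,1.80,millions
genital_herpes,1.8,0.33,millions
heart_attack_stroke,3.0,0.11,millions
high_cholesterol,37.9,1.70,millions
hpv,1.5,0.12,millions
hypertension,43.5,1.50,millions
migraine,16.4,1.80,millions
hay_fever,18.2,1.30,millions
osteoporosis,6.0,0.13,millions
stomach_ulcers,3.3,0.03,millions
uti,10.0,1.00,millions
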
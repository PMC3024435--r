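name,row,col,diameter_mm
olfactory_L,12,57,0.5
olfactory_R,12,72,0.5
frontal_L,19,49,0.5
frontal_R,19,80,0.5
cingulate_L,24,59,0.5
cingulate_R,24,70,0.5
motor_L,35,45,0.5
motor_R,35,84,0.5
somatosensory_L,55,35,0.5
somatosensory_R,55,94,0.5
retrosplenial_L,74,56,0.5
retrosplenial_R,74,73,0.5
visual_L,93,43,0.5
visual_R,93,86,0.5
superior_colliculus_L,112,56,0.5
superior_colliculus_R,112,73,0.5
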